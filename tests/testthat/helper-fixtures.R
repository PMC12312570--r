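# Shared fixtures: all synthetic, generated in code at test time.

# reference cell and geometry used across tests (activated T-cell scale)
ref_cell <- function(...) cell_model(r_c = 3.3e-6, k_c = 8e-4, ...)

ref_config <- function(...) {
  args <- list(...)
  defaults <- list(v = 20e-6, k_p = 20e-3, frame_rate = 30, seed = 1L)
  do.call(experiment_config, utils::modifyList(defaults, args))
}

# small aggregate for fast simulator tests: ~21 chains x 3 springs
small_net <- function(cell = ref_cell()) {
  build_lattice_aggregate(R0 = 16.5e-6, L0 = 19.8e-6, cell)
}

# manual chain network: m disjoint chains of n springs of stiffness k
chain_net <- function(m, n, k = 8e-4, rest = 6.6e-6) {
  nodes <- NULL
  bonds <- NULL
  left <- integer(); right <- integer()
  for (c in seq_len(m)) {
    base <- (c - 1L) * (n + 1L)
    nodes <- rbind(nodes, cbind((0:n) * rest, (c - 1L) * rest, 0))
    bonds <- rbind(bonds, data.frame(i = base + 1:n, j = base + 2:(n + 1L),
                                     rest = rest, k = k, state = "elastic",
                                     chain = c))
    left <- c(left, base + 1L)
    right <- c(right, base + n + 1L)
  }
  spring_network(nodes, bonds, left, right,
                 cell = cell_model(r_c = rest / 2, k_c = k),
                 geometry = list(R0 = sqrt(m) * rest / 2, L0 = n * rest))
}

# trace-level recording from a simulation (no rendering)
sim_recording <- function(sim, cfg, noisy = TRUE) {
  cal <- cantilever_calibration(cfg$k_p, cfg$k_p_sd, 1, low_replication = FALSE)
  geo <- list(R0_mean = sim$truth$R0, R0_sd = 0,
              L0_mean = sim$truth$L0, L0_sd = 0)
  tr <- data.frame(t = sim$trace$t,
                   x = if (noisy) sim$trace$x else sim$trace$x_clean,
                   xs = sim$trace$xs)
  attr(tr, "ruptured_at") <- attr(sim$trace, "ruptured_at")
  stretch_recording(tr, cal, geo, v = cfg$v)
}
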