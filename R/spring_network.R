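#' Construct a spring network
#'
#' Low-level constructor for the spring-network substrate used by the lattice
#' builder, the stiffness oracle and the stretching simulator. Nodes carry 3-D
#' coordinates; bonds carry a rest length, a stiffness and a state
#' (`"elastic"`, `"yielded"` or `"broken"`; broken bonds transmit no force).
#' The two boundary sets are the node indices clamped to the pipette faces.
#'
#' @param nodes numeric matrix (n x 3) of node positions, m.
#' @param bonds data.frame with columns `i`, `j` (1-based node indices),
#'   `rest` (m), `k` (N/m) and optionally `state` and `chain` (chain id for
#'   axial-chain networks, `NA` for lateral bonds).
#' @param left,right integer vectors of boundary node indices (disjoint,
#'   non-empty).
#' @param cell optional [cell_model()] the network was built from.
#' @param geometry optional list with `R0`, `L0` (m).
#' @return object of class `spring_network`.
#' @export
spring_network <- function(nodes, bonds, left, right, cell = NULL,
                           geometry = NULL) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, nrow(nodes) >= 2)
  bonds <- as.data.frame(bonds)
  if (is.null(bonds$state)) bonds$state <- "elastic"
  if (is.null(bonds$chain)) bonds$chain <- NA_integer_
  if (any(bonds$i == bonds$j)) {
    stop_mfs("mfs_invalid_parameter", "a bond may not join a node to itself")
  }
  left <- as.integer(left); right <- as.integer(right)
  if (length(left) == 0L || length(right) == 0L) {
    stop_mfs("mfs_invalid_geometry", "boundary sets must be non-empty")
  }
  if (length(intersect(left, right)) > 0L) {
    stop_mfs("mfs_invalid_geometry", "boundary sets must be disjoint")
  }
  structure(list(nodes = nodes, bonds = bonds, left = left, right = right,
                 cell = cell, geometry = geometry),
            class = "spring_network")
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("<spring_network> %d nodes, %d bonds (%d broken), |left| = %d, |right| = %d\n",
              nrow(x$nodes), nrow(x$bonds), sum(x$bonds$state == "broken"),
              length(x$left), length(x$right)))
  if (!is.null(x$geometry)) {
    cat(sprintf("  cylinder R0 = %.3g um, L0 = %.3g um\n",
                m_to_um(x$geometry$R0), m_to_um(x$geometry$L0)))
  }
  invisible(x)
}

#' Build a cylindrical lattice aggregate
#'
#' Places cell centres on a simple-cubic lattice with spacing `2 r_c`,
#' retaining sites whose centres lie inside the cylinder of radius `R0` and
#' length `L0` (stretch axis = x). Nearest-neighbour axial bonds get stiffness
#' `k_c` and rest length `2 r_c`; each (y, z) lattice column is one force
#' chain. The first and last lattice planes form the clamped boundary sets.
#' Lateral bonds (between neighbouring chains within a plane) are off by
#' default: under axial load their contribution is assumed much smaller than
#' that of the axial bonds.
#'
#' @param R0 aggregate radius, m (>= `r_c`).
#' @param L0 aggregate length, m (>= `2 r_c`).
#' @param cell a [cell_model()].
#' @param lateral_bonds if `TRUE`, add lateral bonds with stiffness
#'   `lateral_factor * k_c`.
#' @param lateral_factor relative stiffness of lateral bonds.
#' @return a [spring_network()] whose bonds carry chain ids.
#' @examples
#' net <- build_lattice_aggregate(33e-6, 66e-6, cell_model())
#' @export
build_lattice_aggregate <- function(R0, L0, cell, lateral_bonds = FALSE,
                                    lateral_factor = 0.2) {
  stopifnot(inherits(cell, "cell_model"))
  check_positive(R0, "R0"); check_positive(L0, "L0")
  r_c <- cell$r_c
  spacing <- 2 * r_c
  ## number of lattice planes along x (allow tiny float slop on L0/2rc)
  n_planes <- floor(L0 / spacing + 1e-9) + 1L
  if (n_planes < 2L) {
    stop_mfs("mfs_invalid_geometry",
             "aggregate too short for two lattice planes (L0 = %g m, 2 r_c = %g m)",
             L0, spacing)
  }
  rmax <- R0 / spacing
  jmax <- floor(rmax + 1e-9)
  grid <- expand.grid(jy = -jmax:jmax, jz = -jmax:jmax)
  keep <- grid$jy^2 + grid$jz^2 <= rmax^2 + 1e-9
  cols <- grid[keep, , drop = FALSE]
  m <- nrow(cols)
  if (m < 1L) {
    stop_mfs("mfs_invalid_geometry", "aggregate too thin for one chain")
  }
  ## node id = (chain - 1) * n_planes + plane
  chain_idx <- rep(seq_len(m), each = n_planes)
  plane_idx <- rep(seq_len(n_planes), times = m)
  nodes <- cbind(
    x = (plane_idx - 1L) * spacing,
    y = cols$jy[chain_idx] * spacing,
    z = cols$jz[chain_idx] * spacing
  )
  ax_from <- which(plane_idx < n_planes)
  bonds <- data.frame(
    i = ax_from, j = ax_from + 1L,
    rest = spacing, k = cell$k_c,
    state = "elastic", chain = chain_idx[ax_from],
    stringsAsFactors = FALSE
  )
  if (lateral_bonds) {
    ## 4-neighbour lateral links within each plane
    key <- paste(cols$jy, cols$jz)
    lat <- list()
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- match(paste(cols$jy + d[1], cols$jz + d[2]), key)
      ok <- which(!is.na(nb))
      if (length(ok)) {
        for (p in seq_len(n_planes)) {
          lat[[length(lat) + 1L]] <- data.frame(
            i = (ok - 1L) * n_planes + p,
            j = (nb[ok] - 1L) * n_planes + p,
            rest = spacing, k = lateral_factor * cell$k_c,
            state = "elastic", chain = NA_integer_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    bonds <- rbind(bonds, do.call(rbind, lat))
  }
  spring_network(
    nodes = nodes, bonds = bonds,
    left = which(plane_idx == 1L), right = which(plane_idx == n_planes),
    cell = cell, geometry = list(R0 = R0, L0 = L0)
  )
}

#' Effective axial stiffness of a spring network
#'
#' Solves the scalar axial equilibrium of all unbroken springs with the left
#' boundary fixed and the right boundary displaced by a unit axial
#' displacement, and returns the reaction force per unit displacement
#' `K_eff = F / u`. For a single chain of `n` springs of stiffness `k` this is
#' `k / n`; for `m` identical chains in parallel, `m k / n`. A single axial
#' degree of freedom per node is used, appropriate for loading along the
#' stretch axis.
#'
#' If no elastic path connects the two boundary sets the network carries no
#' load: the function returns `0` with attribute `disconnected = TRUE` rather
#' than raising, so rupture sweeps terminate cleanly.
#'
#' @param net a [spring_network()].
#' @return effective stiffness, N/m, with logical attribute `disconnected`.
#' @examples
#' net <- build_lattice_aggregate(3.3e-6, 13.2e-6, cell_model())
#' network_stiffness(net) # single chain of 2 springs: k_c / 2
#' @export
network_stiffness <- function(net) {
  stopifnot(inherits(net, "spring_network"))
  n <- nrow(net$nodes)
  b <- net$bonds[net$bonds$state != "broken" & net$bonds$k > 0, , drop = FALSE]
  out <- function(K, disc) structure(K, disconnected = disc)
  if (nrow(b) == 0L) return(out(0, TRUE))

  g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  bridging <- intersect(unique(comp[net$left]), unique(comp[net$right]))
  if (length(bridging) == 0L) return(out(0, TRUE))

  keep_node <- comp %in% bridging
  ## boundary conditions: left u = 0, right u = 1
  u <- rep(NA_real_, n)
  u[net$left] <- 0
  u[net$right] <- 1
  free <- which(keep_node & is.na(u))
  keep_bond <- keep_node[b$i] # both ends share a component
  b <- b[keep_bond, , drop = FALSE]

  if (length(free) > 0L) {
    idx <- rep(NA_integer_, n)
    idx[free] <- seq_along(free)
    u <- solve_free(u, b, free, idx)
  }
  ## reaction force on the right boundary
  r_set <- rep(FALSE, n); r_set[net$right] <- TRUE
  one_end <- xor(r_set[b$i], r_set[b$j])
  if (!any(one_end)) return(out(0, TRUE))
  bi <- b[one_end, , drop = FALSE]
  ur <- ifelse(r_set[bi$i], u[bi$i], u[bi$j])
  uo <- ifelse(r_set[bi$i], u[bi$j], u[bi$i])
  F_total <- sum(bi$k * (ur - uo))
  out(F_total, FALSE)
}

## Solve the free-node equilibrium K_ff u_f = -K_fb u_b (axial scalar DOFs).
solve_free <- function(u, b, free, idx) {
  nf <- length(free)
  fixed_u <- u
  ii <- idx[b$i]; jj <- idx[b$j]
  both <- !is.na(ii) & !is.na(jj)
  i_only <- !is.na(ii) & is.na(jj)
  j_only <- is.na(ii) & !is.na(jj)
  trip_i <- c(ii[both], jj[both], ii[both], jj[both], ii[i_only], jj[j_only])
  trip_j <- c(jj[both], ii[both], ii[both], jj[both], ii[i_only], jj[j_only])
  trip_x <- c(-b$k[both], -b$k[both], b$k[both], b$k[both],
              b$k[i_only], b$k[j_only])
  K <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nf, nf), index1 = TRUE)
  rhs <- numeric(nf)
  if (any(i_only)) {
    add <- tapply(b$k[i_only] * fixed_u[b$j[i_only]], ii[i_only], sum)
    rhs[as.integer(names(add))] <- rhs[as.integer(names(add))] + add
  }
  if (any(j_only)) {
    add <- tapply(b$k[j_only] * fixed_u[b$i[j_only]], jj[j_only], sum)
    rhs[as.integer(names(add))] <- rhs[as.integer(names(add))] + add
  }
  uf <- as.numeric(Matrix::solve(K, rhs))
  u[free] <- uf
  u
}

#' Lattice realisation of the spring-chain scaling constant
#'
#' For cubic-lattice aggregates over a grid of geometries, computes
#' `c = K_eff * L0 / (pi R0^2) / (k_c / r_c)`, the geometric prefactor that
#' the scaling law leaves undetermined. Its coefficient of variation across
#' geometries quantifies how size-independent the lattice prefactor is.
#'
#' @param cell a [cell_model()].
#' @param R0_over_rc,L0_over_rc numeric vectors of geometry ratios.
#' @return data.frame with one row per geometry and columns `R0`, `L0`, `c`.
#' @export
lattice_scaling_constant <- function(cell = cell_model(),
                                     R0_over_rc = c(3, 5, 8),
                                     L0_over_rc = c(6, 10, 20)) {
  grid <- expand.grid(R0 = R0_over_rc * cell$r_c, L0 = L0_over_rc * cell$r_c)
  grid$c <- vapply(seq_len(nrow(grid)), function(i) {
    net <- build_lattice_aggregate(grid$R0[i], grid$L0[i], cell)
    K <- as.numeric(network_stiffness(net))
    E_net <- K * grid$L0[i] / (pi * grid$R0[i]^2)
    E_net / (cell$k_c / cell$r_c)
  }, numeric(1))
  grid
}

#' Export / import a spring network as JSON
#'
#' @param net a [spring_network()].
#' @param path file path.
#' @return `read_network_json` returns a [spring_network()];
#'   `write_network_json` returns `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "spring_network"))
  obj <- list(
    nodes = unname(as.matrix(net$nodes)),
    bonds = net$bonds,
    left = net$left, right = net$right,
    cell = if (!is.null(net$cell)) unclass(net$cell),
    geometry = net$geometry
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cell <- if (!is.null(obj$cell)) do.call(cell_model, as.list(obj$cell))
  spring_network(obj$nodes, obj$bonds, obj$left, obj$right,
                 cell = cell, geometry = obj$geometry)
}
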