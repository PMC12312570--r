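## End-to-end pipeline entry points: simulate | analyze | compare.
## These are thin compositions of the module functions with file I/O
## (CSV for tables and traces, JSON for configs/results, multi-page TIFF for
## frames), so a whole synthetic experiment can be round-tripped on disk.

write_run_log <- function(dir, cfg_list, seed) {
  log <- list(
    package = "mfstretch",
    version = as.character(utils::packageVersion("mfstretch")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg_list, digits = NA)))
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"), auto_unbox = TRUE)
}

#' Simulate a full stretching experiment to disk
#'
#' Builds a lattice aggregate, runs the quasi-static stretching simulation,
#' optionally renders the frame stack, and writes a self-contained recording
#' bundle: `config.json`, `trace.csv` (`t_s, xs_m, x_m, F_N`), `truth.json`,
#' `frames.tif` (when rendered) and a run log. Deterministic under the
#' config seed.
#'
#' @param outdir output directory (created if missing).
#' @param R0,L0 aggregate radius and length, m.
#' @param cell a [cell_model()].
#' @param cfg an [experiment_config()].
#' @param render render and write the TIFF stack.
#' @return invisibly, a list with the simulation output and file paths.
#' @export
run_simulate <- function(outdir, R0 = 30e-6, L0 = 60e-6,
                         cell = cell_model(), cfg = experiment_config(),
                         render = TRUE) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    message("created output directory ", outdir)
  }
  net <- build_lattice_aggregate(R0, L0, cell)
  sim <- simulate_stretch(net, cfg)
  tr <- sim$trace
  utils::write.csv(
    data.frame(t_s = tr$t, xs_m = tr$xs, x_m = tr$x, F_N = tr$F),
    file.path(outdir, "trace.csv"), row.names = FALSE
  )
  cfg_list <- c(unclass(cfg), list(R0_m = R0, L0_m = L0, cell = unclass(cell)))
  jsonlite::write_json(cfg_list, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(E_true_Pa = sim$truth$E_true, sigma_uts_true_Pa = sim$truth$sigma_uts_true,
         K_eff_N_per_m = sim$truth$K_eff, R0_m = R0, L0_m = L0,
         ruptured_at = attr(tr, "ruptured_at")),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  paths <- list(trace = file.path(outdir, "trace.csv"),
                config = file.path(outdir, "config.json"),
                truth = file.path(outdir, "truth.json"))
  if (render) {
    stack <- render_frames(tr, sim$truth, cfg)
    paths$frames <- file.path(outdir, "frames.tif")
    write_tiff(stack, paths$frames)
    sim$stack <- stack
  }
  write_run_log(outdir, cfg_list, cfg$seed)
  invisible(c(sim, list(paths = paths)))
}

#' Analyze a recording bundle
#'
#' Runs the measurement pipeline on a bundle written by [run_simulate()] (or
#' assembled from real data in the same layout): track the force-sensing tip
#' and measure geometry from `frames.tif` when present (otherwise fall back
#' to `trace.csv` with the geometry recorded in the bundle), then compute the
#' stress-strain curve, apply quality control, fit the Young's modulus and
#' extract the UTS. QC-invalid experiments appear in the output with
#' `valid = FALSE` rather than vanishing; a slip annotation withholds the UTS
#' but keeps the modulus.
#'
#' @param bundle_dir directory with `config.json` and `frames.tif` or
#'   `trace.csv`.
#' @param annotations operator QC annotations (e.g. `"slip"`, `"rotation"`).
#' @param use_frames prefer the rendered frames over the trace.
#' @param out results CSV path (default `results.csv` in the bundle).
#' @return invisibly, a list with the results `row` (data.frame), the
#'   `properties` and the `curve`.
#' @export
run_analyze <- function(bundle_dir, annotations = character(),
                        use_frames = TRUE,
                        out = file.path(bundle_dir, "results.csv")) {
  cfg_path <- file.path(bundle_dir, "config.json")
  if (!file.exists(cfg_path)) {
    stop_mfs("mfs_io_error", "no config.json in %s", bundle_dir)
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cal <- cantilever_calibration(k_p_mean = cfg$k_p,
                                k_p_sd = if (!is.null(cfg$k_p_sd)) cfg$k_p_sd else 0,
                                n_obs = 1L, low_replication = FALSE)
  frames_path <- file.path(bundle_dir, "frames.tif")
  if (use_frames && file.exists(frames_path)) {
    stack <- read_tiff(frames_path)
    stack$timestamps <- (seq_along(stack$frames) - 1) / cfg$frame_rate
    geo <- measure_geometry(stack)
    trk <- track_tip(stack)
    rec <- stretch_recording(trk, cal, geo, v = cfg$v)
  } else {
    tr_path <- file.path(bundle_dir, "trace.csv")
    if (!file.exists(tr_path)) {
      stop_mfs("mfs_io_error", "neither frames.tif nor trace.csv in %s", bundle_dir)
    }
    tr <- utils::read.csv(tr_path)
    truth_path <- file.path(bundle_dir, "truth.json")
    truth <- if (file.exists(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    } else {
      list(R0_m = cfg$R0_m, L0_m = cfg$L0_m)
    }
    geo <- list(R0_mean = truth$R0_m, R0_sd = 0, L0_mean = truth$L0_m, L0_sd = 0,
                V = pi * truth$R0_m^2 * truth$L0_m, V_tot = NA_real_)
    trace <- data.frame(t = tr$t_s, x = tr$x_m, xs = tr$xs_m)
    if (!is.null(truth$ruptured_at)) {
      attr(trace, "ruptured_at") <- truth$ruptured_at
    }
    rec <- stretch_recording(trace, cal, geo, v = cfg$v)
  }
  props <- analyze_recording(rec, annotations = annotations)
  row <- data.frame(
    E_Pa = props$E, E_err_Pa = props$E_err,
    sigma_uts_Pa = props$sigma_uts,
    qc_flags = paste(props$qc_flags, collapse = ";"),
    valid = props$valid,
    V_um3 = geo$V * 1e18,
    V_over_Vtot = if (is.finite(geo$V_tot %||% NA_real_)) geo$V / geo$V_tot else NA_real_,
    minutes_post_activation = NA_real_
  )
  utils::write.csv(row, out, row.names = FALSE)
  invisible(list(row = row, properties = props, curve = props$curve,
                 recording = rec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare groups of measured moduli
#'
#' Group-level reporting: Welch's t-test of every group against the reference
#' with significance stars, box summaries, same-mouse paired ratios (when a
#' `mouse_id` column is present) and covariate null checks for any of the
#' standard covariate columns. With a single group the comparison step is
#' skipped with a warning.
#'
#' @param results data.frame (or CSV path) with columns `group`, `E`, and
#'   optionally `mouse_id` and covariates.
#' @param reference reference group label (default: first group).
#' @param out_json optional path for a JSON report.
#' @param out_md optional path for a markdown summary.
#' @return invisibly, the report list.
#' @export
run_compare <- function(results, reference = NULL, out_json = NULL,
                        out_md = NULL) {
  if (is.character(results)) results <- utils::read.csv(results)
  results <- as.data.frame(results)
  stopifnot(all(c("group", "E") %in% names(results)))
  groups <- unique(results$group)
  if (is.null(reference)) reference <- groups[1]
  report <- list(reference = reference,
                 boxes = lapply(stats::setNames(groups, groups), function(g) {
                   box_summary(results$E[results$group == g])
                 }))
  if (length(groups) < 2) {
    warning("single group: comparison skipped", call. = FALSE)
  } else {
    others <- setdiff(groups, reference)
    report$welch <- lapply(stats::setNames(others, others), function(g) {
      w <- welch_test(results$E[results$group == g],
                      results$E[results$group == reference])
      unclass(w)
    })
    if ("mouse_id" %in% names(results)) {
      report$paired_ratios <- lapply(stats::setNames(others, others), function(g) {
        r <- paired_ratio(results, g, reference)
        r[c("mean_ratio", "sd_ratio", "n_mice")]
      })
    }
  }
  covs <- intersect(c("volume_um3", "v_over_vtot", "time_post_activation_h"),
                    names(results))
  if (nrow(results) >= 5 && length(covs)) {
    report$covariates <- lapply(stats::setNames(covs, covs), function(cv) {
      covariate_null_check(results, cv)
    })
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out_md)) {
    lines <- c("# Group comparison report", "",
               sprintf("Reference group: %s", reference), "")
    for (g in names(report$welch %||% list())) {
      w <- report$welch[[g]]
      lines <- c(lines, sprintf(
        "- %s vs %s: t = %.3f, df = %.1f, p = %.3g (%s)",
        g, reference, w$t_stat, w$df, w$p_value, w$stars))
    }
    for (g in names(report$paired_ratios %||% list())) {
      pr <- report$paired_ratios[[g]]
      lines <- c(lines, sprintf(
        "- same-mouse ratio %s / %s = %.2f +/- %.2f (n = %d mice)",
        g, reference, pr$mean_ratio, pr$sd_ratio, pr$n_mice))
    }
    writeLines(lines, out_md)
  }
  invisible(report)
}
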