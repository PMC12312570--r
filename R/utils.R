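#' @keywords internal
"_PACKAGE"

## Internal argument checking helpers. All user-facing errors are classed so
## tests can assert on condition class rather than message text.

stop_mfs <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mfs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_mfs("mfs_invalid_parameter", "`%s` must be a positive scalar", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_mfs("mfs_invalid_parameter", "`%s` must be a non-negative scalar", name)
  }
  invisible(x)
}

#' Unit conversions at the interface boundary
#'
#' Experimental practice quotes cantilever stiffness in nN per micrometre and
#' lengths in micrometres; all internal computation is SI (N per metre,
#' metres, pascals). 1 nN um^-1 = 1e-3 N m^-1.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @examples
#' nN_per_um_to_N_per_m(20) # 0.02 N/m
#' @export
nN_per_um_to_N_per_m <- function(x) x * 1e-3

#' @rdname nN_per_um_to_N_per_m
#' @export
N_per_m_to_nN_per_um <- function(x) x * 1e3

#' @rdname nN_per_um_to_N_per_m
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname nN_per_um_to_N_per_m
#' @export
m_to_um <- function(x) x * 1e6
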