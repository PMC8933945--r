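#' Uniform wavelength grid
#'
#' Constructs the shared wavelength axis every spectrum in a pipeline lives
#' on. The grid is strictly increasing and uniform; `stop_nm` must be
#' reachable from `start_nm` in an integer number of steps.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Sampling increment (nm), positive. The default 0.1 nm
#'   gives at least ten points per nominal band width for UV work.
#' @return An object of class `"wavelength_grid"` with elements `start_nm`,
#'   `stop_nm`, `step_nm` and the realised `wavelength` vector.
#' @examples
#' g <- wavelength_grid(200, 400, 0.1)
#' length(g$wavelength)
#' @export
wavelength_grid <- function(start_nm = 200, stop_nm = 400, step_nm = 0.1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) {
    stop("wavelength_grid: start_nm must be < stop_nm", call. = FALSE)
  }
  if (step_nm <= 0) {
    stop("wavelength_grid: step_nm must be > 0", call. = FALSE)
  }
  k <- (stop_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8) {
    stop("wavelength_grid: stop_nm must equal start_nm + k * step_nm ",
         "for integer k", call. = FALSE)
  }
  n <- round(k) + 1L
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         wavelength = start_nm + (seq_len(n) - 1) * step_nm),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$wavelength)))
  invisible(x)
}

grid_length <- function(grid) length(grid$wavelength)

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength) == length(b$wavelength) &&
    abs(a$start_nm - b$start_nm) < tol &&
    abs(a$step_nm - b$step_nm) < tol
}
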