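#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded helpers do not perturb an enclosing simulation.
#' With `seed = NULL` the current RNG stream is used unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Unit conversions used throughout the package
#'
#' Positions are carried in micrometres, spring constants in N/m, forces in
#' nanonewtons, areas in square micrometres and stresses in pascals.
#' 1 N/m x 1 um = 1000 nN and 1 nN / 1 um^2 = 1000 Pa, so
#' `force_nN = 1000 * k * deflection_um` and `sigma_Pa = 1000 * F_nN / A_um2`.
#'
#' @param k_N_per_m cantilever spring constant (N/m).
#' @param deflection_um cantilever deflection (um).
#' @name units
#' @keywords internal
NULL

#' @rdname units
#' @keywords internal
nN_from_deflection <- function(k_N_per_m, deflection_um) {
  1000 * k_N_per_m * deflection_um
}

#' @rdname units
#' @param force_nN force (nN).
#' @param area_um2 contact area (um^2).
#' @keywords internal
Pa_from_force <- function(force_nN, area_um2) {
  1000 * force_nN / area_um2
}

# stress (Pa) exerted across contact area A by a deflection delta:
# sigma = 1e6 * k * delta / A
Pa_from_deflection <- function(k_N_per_m, deflection_um, area_um2) {
  1e6 * k_N_per_m * deflection_um / area_um2
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
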