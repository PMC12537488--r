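#' Physical constants and magnetite material defaults
#'
#' `mag_constants()` returns the physical constants used throughout the
#' package; `magnetite_params()` returns a [material_params] object with the
#' room-temperature constants of magnetite.
#'
#' @return A named list with `mu0` (vacuum permeability, T m/A) and
#'   `k_B` (Boltzmann constant, J/K).
#' @export
mag_constants <- function() {
  list(mu0 = 4e-7 * pi, k_B = 1.380649e-23)
}

.mu0 <- 4e-7 * pi
.kB <- 1.380649e-23

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never disturb global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
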