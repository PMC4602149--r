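# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' `.Random.seed` afterwards, so seeded generators never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks; stop with the argument name in the message
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# unit vector for a direction in degrees (0 deg = +x, counterclockwise)
dir_unit <- function(deg) {
  th <- deg2rad(deg)
  cbind(cos(th), sin(th))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
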