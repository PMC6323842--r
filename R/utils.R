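#' Round to the nearest multiple, ties away from zero
#'
#' Displacements are binned to the phantom's 1-mm sample-image grid with
#' ties at +-0.5 mm rounded away from zero (so +7.5 -> +8, -7.5 -> -8),
#' keeping the binning symmetric about the reference position.
#'
#' @param x numeric vector.
#' @param unit bin width (default 1).
#' @return `x` rounded to the nearest multiple of `unit`.
#' @export
round_half_away <- function(x, unit = 1) {
  unit * sign(x) * floor(abs(x) / unit + 0.5)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
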