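# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state, so package randomness never disturbs the
#' user's stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed for a sub-stage; keeps every stage's stream a pure
# function of (root seed, stage index) and inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1664525 * as.double(k)) %% 2147483647)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_input("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

# Percentile with linear interpolation of the empirical CDF (quantile type 4):
# the p-th percentile of n ordered values is the (n * p / 100)-th order
# statistic, linearly interpolated. Used for control-cell gating thresholds.
percentile_lin <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 4, names = FALSE))
}

#' Channel names used throughout the package
#'
#' All image fields and crops carry three channels in this fixed order:
#' pan-cytokeratin (CK, epithelial/tumor marker), CD45 (pan-leukocyte marker),
#' and DAPI (nuclear stain).
#' @return Character vector `c("CK", "CD45", "DAPI")`.
#' @export
chc_channels <- function() c("CK", "CD45", "DAPI")
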