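#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft nextn approx spline lowess median mad quantile rnorm
#'   runif rexp rpois sd var coef lm p.adjust wilcox.test
#' @importFrom utils head tail modifyList write.table read.table packageVersion
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("oscphen_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

# Deterministic child seeds: fan one integer seed out per stage name so
# independent stages draw from independent streams (kept < 2^31).
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# runs of TRUE in a logical vector -> matrix [start, end] (inclusive, samples)
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}
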