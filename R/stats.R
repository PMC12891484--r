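#' Hierarchical cohort container
#'
#' Groups of subjects, each holding per-epoch items (log-power spectra,
#' phase-amplitude distributions, or flattened comodulograms) as a matrix
#' with one column per epoch, all on one shared element grid.
#'
#' @param groups named list: `groups[[g]][[s]]` is subject `s`'s item matrix
#'   (elements x epochs; a plain vector is taken as a single epoch).
#' @param grid optional element grid (e.g. frequencies, Hz).
#' @export
cohort_dataset <- function(groups, grid = NULL) {
  groups <- lapply(groups, function(g) lapply(g, function(m) {
    if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
    m
  }))
  nr <- unique(unlist(lapply(groups, function(g) vapply(g, nrow, 0L))))
  if (length(nr) != 1L) stop_invalid("subjects have mismatched item grids")
  if (!is.null(grid) && length(grid) != nr)
    stop_invalid("grid length does not match items")
  structure(list(groups = groups, grid = grid), class = "cohort_dataset")
}

#' Bootstrap configuration
#'
#' @param n_boot replicates (default 1000).
#' @param ci_level 95 or 99 (rank indices 25/975 or 5/995 at `n_boot`
#'   = 1000).
#' @param levels 1 (subjects only) or 2 (subjects then epochs).
#' @param matched reuse the same random index streams for both groups when
#'   their sizes (and epoch counts, where relevant) are equal.
#' @param seed RNG seed.
#' @export
bootstrap_config <- function(n_boot = 1000L, ci_level = 99, levels = 2L,
                             matched = FALSE, seed = 1L) {
  if (!ci_level %in% c(95, 99)) stop_invalid("ci_level must be 95 or 99")
  lo <- n_boot * (1 - ci_level / 100) / 2
  if (abs(lo - round(lo)) > 1e-9 || lo < 1)
    stop_invalid("rank indices not integral for n_boot = ", n_boot,
                 " at ci_level ", ci_level)
  if (!levels %in% c(1L, 2L)) stop_invalid("levels must be 1 or 2")
  list(n_boot = as.integer(n_boot), ci_level = ci_level,
       levels = as.integer(levels), matched = isTRUE(matched),
       seed = as.integer(seed), rank_lo = as.integer(round(lo)),
       rank_hi = as.integer(n_boot - round(lo)))
}

# one group-mean replicate: resample subjects, then (levels == 2) epochs
boot_group_mean <- function(subjects, cfg, sub_idx, epoch_draw) {
  acc <- 0
  for (i in sub_idx) {
    m <- subjects[[i]]
    if (cfg$levels == 2L && ncol(m) > 1L) {
      idx <- epoch_draw(ncol(m))
      acc <- acc + rowMeans(m[, idx, drop = FALSE])
    } else acc <- acc + rowMeans(m)
  }
  acc / length(sub_idx)
}

#' Hierarchical bootstrap of a group difference
#'
#' Per replicate: subjects are resampled with replacement within each group
#' (level 1), then each selected subject's epochs are resampled with
#' replacement (level 2), group means are formed and the difference
#' (`a - b`) stored. After `n_boot` replicates each element's differences
#' are rank-ordered; the median and the CI rank values (5th/995th for 99%,
#' 25th/975th for 95% at 1000 replicates) are returned with a significance
#' mask where the CI excludes zero. With `matched = TRUE` and equal group
#' sizes the same random index streams drive both groups' selections
#' (littermate-pair style matching).
#'
#' @param a,b lists of subject item matrices (elements x epochs), e.g. one
#'   group of a [cohort_dataset].
#' @param cfg a [bootstrap_config].
#' @param grid optional element grid carried into the result.
#' @return a `bootstrap_result`: `median`, `lower`, `upper`, `significant`.
#' @export
hier_bootstrap_diff <- function(a, b, cfg = bootstrap_config(), grid = NULL) {
  if (inherits(a, "cohort_dataset")) stop_invalid("pass one group, e.g. x$groups[[1]]")
  if (!length(a) || !length(b)) stop_invalid("empty group")
  a <- lapply(a, function(m) if (is.matrix(m)) m else matrix(m, ncol = 1L))
  b <- lapply(b, function(m) if (is.matrix(m)) m else matrix(m, ncol = 1L))
  na <- length(a); nb <- length(b)
  can_match <- cfg$matched && na == nb &&
    all(vapply(a, ncol, 0L) == vapply(b, ncol, 0L))
  nel <- nrow(a[[1L]])
  diffs <- matrix(0, nel, cfg$n_boot)
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_boot)) {
      ia <- sample.int(na, na, replace = TRUE)
      ea <- if (cfg$levels == 2L)
        lapply(ia, function(i) sample.int(ncol(a[[i]]), ncol(a[[i]]),
                                          replace = TRUE)) else NULL
      if (can_match) { ib <- ia; eb <- ea }
      else {
        ib <- sample.int(nb, nb, replace = TRUE)
        eb <- if (cfg$levels == 2L)
          lapply(ib, function(i) sample.int(ncol(b[[i]]), ncol(b[[i]]),
                                            replace = TRUE)) else NULL
      }
      ma <- 0
      for (j in seq_along(ia)) {
        m <- a[[ia[j]]]
        ma <- ma + if (is.null(ea)) rowMeans(m) else
          rowMeans(m[, ea[[j]], drop = FALSE])
      }
      mb <- 0
      for (j in seq_along(ib)) {
        m <- b[[ib[j]]]
        mb <- mb + if (is.null(eb)) rowMeans(m) else
          rowMeans(m[, eb[[j]], drop = FALSE])
      }
      diffs[, r] <- ma / na - mb / nb
    }
  })
  srt <- apply(diffs, 1L, sort)               # n_boot x nel
  lower <- srt[cfg$rank_lo, ]
  upper <- srt[cfg$rank_hi, ]
  med <- apply(diffs, 1L, median)
  structure(list(median = med, lower = lower, upper = upper,
                 significant = lower > 0 | upper < 0, grid = grid,
                 config = cfg),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d elements, %d significant (%g%% CI, %d reps)\n",
              length(x$median), sum(x$significant), x$config$ci_level,
              x$config$n_boot))
  invisible(x)
}

# epoch resample avoiding positional self-pairs with a reference draw
mismatched_draw <- function(n, ref) {
  idx <- sample.int(n, n, replace = TRUE)
  bad <- which(idx == ref)
  for (i in bad) idx[i] <- sample(seq_len(n)[-ref[i]], 1L)
  idx
}

#' Bootstrap noise-subtracted comodulogram
#'
#' Per replicate, subjects are resampled with replacement; for each selected
#' subject two epoch index lists of full length are drawn with replacement,
#' the second constrained so no position pairs an epoch with itself. The
#' first list averages the true comodulograms, the second the noise
#' comodulograms; the group-mean difference (true - noise) is stored. After
#' all replicates the per-cell median and CI are computed, and cells whose
#' CI includes zero are set to 0 in the masked median.
#'
#' @param true_items,noise_items lists (one per subject) of element x epoch
#'   matrices: per-epoch true and noise comodulograms (flattened).
#' @param cfg a [bootstrap_config].
#' @return list with `median`, `masked_median`, `lower`, `upper`,
#'   `significant` vectors over cells.
#' @export
hier_bootstrap_comod <- function(true_items, noise_items,
                                 cfg = bootstrap_config()) {
  if (length(true_items) != length(noise_items))
    stop_invalid("true and noise subject lists differ in length")
  true_items <- lapply(true_items, as.matrix)
  noise_items <- lapply(noise_items, as.matrix)
  ns <- length(true_items)
  if (any(vapply(true_items, ncol, 0L) < 2L))
    stop_invalid("every subject needs >= 2 epochs (mismatch constraint)")
  nel <- nrow(true_items[[1L]])
  diffs <- matrix(0, nel, cfg$n_boot)
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_boot)) {
      is_ <- sample.int(ns, ns, replace = TRUE)
      mt <- 0; mn <- 0
      for (i in is_) {
        ne <- ncol(true_items[[i]])
        e1 <- sample.int(ne, ne, replace = TRUE)
        e2 <- mismatched_draw(ne, e1)
        mt <- mt + rowMeans(true_items[[i]][, e1, drop = FALSE])
        mn <- mn + rowMeans(noise_items[[i]][, e2, drop = FALSE])
      }
      diffs[, r] <- (mt - mn) / ns
    }
  })
  srt <- apply(diffs, 1L, sort)
  lower <- srt[cfg$rank_lo, ]
  upper <- srt[cfg$rank_hi, ]
  med <- apply(diffs, 1L, median)
  sig <- lower > 0 | upper < 0
  list(median = med, masked_median = ifelse(sig, med, 0),
       lower = lower, upper = upper, significant = sig, config = cfg)
}

#' Cliff's delta effect size
#'
#' Unpaired: dominance over all pairs,
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`. Paired: within-pair
#' dominance `(#\{x_i > y_i\} - #\{x_i < y_i\}) / n`. Positive when `x`
#' tends larger; values at or beyond +/-0.3 are conventionally medium to
#' large.
#'
#' @param x,y numeric samples.
#' @param paired use the within-pair variant (requires equal lengths).
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y, paired = FALSE) {
  if (!length(x) || !length(y)) stop_invalid("empty sample")
  if (paired) {
    if (length(x) != length(y)) stop_invalid("paired samples must be equal length")
    d <- sign(x - y)
    return(mean(d))
  }
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (delegated to [stats::p.adjust]) with input
#' validation; order-preserving.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson r-squared from a least-squares line
#'
#' `r^2 = 1 - SS_res / SS_tot` from the fitted line; `r = sqrt(r^2)`.
#'
#' @param x,y numeric vectors, equal length >= 3; `y` non-constant.
#' @return list with `r2` and `r`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("need equal-length samples of size >= 3")
  if (sd(y) == 0) stop_invalid("constant y")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- var(y) * (length(y) - 1)
  r2 <- 1 - ss_res / ss_tot
  list(r2 = r2, r = sqrt(max(r2, 0)))
}

#' Wilcoxon comparison with effect size and reporting fields
#'
#' Thin wrapper over [stats::wilcox.test] (rank-sum for unpaired,
#' signed-rank for paired) bundling Cliff's delta; p-values across a family
#' of such comparisons should be adjusted with [bh_fdr].
#'
#' @param x,y numeric samples.
#' @param paired paired comparison?
#' @return list with `p_value`, `statistic`, `delta`, `paired`.
#' @export
wilcoxon_compare <- function(x, y, paired = FALSE) {
  wt <- wilcox.test(x, y, paired = paired, exact = FALSE, correct = TRUE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       delta = cliffs_delta(x, y, paired = paired), paired = paired)
}
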