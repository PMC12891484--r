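test_that("Cliff's delta matches exhaustive enumeration", {
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  brute <- 0
  for (xi in x) for (yj in y) brute <- brute + sign(xi - yj)
  expect_equal(cliffs_delta(x, y), brute / 16)
  # antisymmetry
  set.seed(fix_seed)
  a <- rnorm(15); b <- rnorm(12)
  expect_equal(cliffs_delta(a, b), -cliffs_delta(b, a))
  # paired variant counts within-pair dominance
  expect_equal(cliffs_delta(c(2, 2, 0), c(1, 1, 1), paired = TRUE), 1 / 3)
  expect_error(cliffs_delta(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("BH adjustment step-up rule", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order preserved
  p <- c(0.04, 0.001, 0.3)
  expect_equal(order(bh_fdr(p)), order(p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pearson_r2 equals squared correlation", {
  x <- 1:20
  expect_equal(pearson_r2(x, 2 * x - 3)$r2, 1)
  set.seed(fix_seed)
  y <- rnorm(20) + 0.3 * x
  got <- pearson_r2(x, y)
  expect_equal(got$r2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(got$r, abs(cor(x, y)), tolerance = 1e-12)
  y0 <- rnorm(500)
  expect_lt(pearson_r2(rnorm(500), y0)$r2, 0.05)
  expect_error(pearson_r2(x, rep(1, 20)), "constant")
})

test_that("wilcoxon wrapper reports test and effect size together", {
  set.seed(fix_seed)
  x <- rnorm(20, 1); y <- rnorm(20)
  out <- wilcoxon_compare(x, y)
  expect_equal(out$p_value,
               wilcox.test(x, y, exact = FALSE)$p.value)
  expect_equal(out$delta, cliffs_delta(x, y))
})

test_that("bootstrap config validates rank indices", {
  cfg <- bootstrap_config(1000, 99)
  expect_equal(cfg$rank_lo, 5L); expect_equal(cfg$rank_hi, 995L)
  cfg95 <- bootstrap_config(1000, 95)
  expect_equal(cfg95$rank_lo, 25L); expect_equal(cfg95$rank_hi, 975L)
  expect_error(bootstrap_config(1000, 90), "95 or 99")
  expect_error(bootstrap_config(150, 99), "rank")
})

test_that("hierarchical bootstrap: determinism, matching, degeneracy", {
  set.seed(fix_seed)
  mk_group <- function(n_sub, n_ep, shift = 0)
    lapply(seq_len(n_sub), function(i)
      matrix(rnorm(30 * n_ep, mean = shift), 30, n_ep))
  a <- mk_group(6, 5); b <- mk_group(6, 5)
  cfg <- bootstrap_config(200, 95, seed = 3)
  r1 <- hier_bootstrap_diff(a, b, cfg)
  r2 <- hier_bootstrap_diff(a, b, cfg)
  expect_identical(r1$median, r2$median)          # fixed seed reproduces
  expect_true(all(r1$lower <= r1$median & r1$median <= r1$upper))
  # matched resampling with identical groups: zero difference everywhere
  rm_ <- hier_bootstrap_diff(a, a, bootstrap_config(200, 95, matched = TRUE,
                                                    seed = 3))
  expect_equal(max(abs(rm_$median)), 0)
  expect_equal(max(abs(rm_$upper - rm_$lower)), 0)
  expect_false(any(rm_$significant))
  # degenerate cohort (1 epoch, sd 0 between items): median = observed diff
  a1 <- lapply(1:4, function(i) matrix(2, 5, 1))
  b1 <- lapply(1:4, function(i) matrix(1.25, 5, 1))
  rd <- hier_bootstrap_diff(a1, b1, bootstrap_config(200, 95, seed = 1))
  expect_equal(rd$median, rep(0.75, 5))
  expect_true(all(rd$significant))
  # a clear shift is detected
  rs <- hier_bootstrap_diff(mk_group(6, 5, shift = 2), b,
                            bootstrap_config(200, 99, seed = 2))
  expect_gt(mean(rs$significant), 0.95)
  expect_error(hier_bootstrap_diff(list(), b, cfg), "empty")
})

test_that("CI width shrinks with more subjects", {
  width <- function(n_sub, seed) {
    set.seed(seed)
    g <- function() lapply(seq_len(n_sub), function(i) matrix(rnorm(10, sd = 1),
                                                              10, 1))
    r <- hier_bootstrap_diff(g(), g(), bootstrap_config(200, 95, levels = 1,
                                                        seed = seed))
    mean(r$upper - r$lower)
  }
  w_small <- mean(sapply(1:5, function(s) width(4, s)))
  w_big <- mean(sapply(1:5, function(s) width(16, s)))
  expect_lt(w_big, w_small)
})

test_that("comodulogram bootstrap masks cells whose CI includes zero", {
  set.seed(fix_seed)
  n_cell <- 12
  mk_sub <- function(coupled) {
    ne <- 6
    m <- matrix(rexp(n_cell * ne, rate = 50), n_cell, ne)   # noise MI level
    if (coupled) m[3, ] <- m[3, ] + 0.1
    m
  }
  true_items <- lapply(1:5, function(i) mk_sub(TRUE))
  noise_items <- lapply(1:5, function(i) mk_sub(FALSE))
  out <- hier_bootstrap_comod(true_items, noise_items,
                              bootstrap_config(400, 99, seed = 2))
  expect_true(out$significant[3])
  expect_equal(out$masked_median[3], out$median[3])
  # masked values are either 0 or the unmasked median
  expect_true(all(out$masked_median == 0 |
                    out$masked_median == out$median))
  # null cells mostly masked out
  expect_lt(mean(out$significant[-3]), 0.2)
  # single-epoch subject violates the mismatch constraint
  expect_error(hier_bootstrap_comod(list(matrix(1, 4, 1)),
                                    list(matrix(1, 4, 1)),
                                    bootstrap_config(40, 95, seed = 1)),
               ">= 2")
})

test_that("cohort_dataset validates item grids", {
  g <- list(g1 = list(matrix(1, 5, 2), matrix(2, 5, 3)),
            g2 = list(matrix(0, 5, 2)))
  cd <- cohort_dataset(g, grid = 1:5)
  expect_length(cd$groups$g1, 2L)
  expect_error(cohort_dataset(list(list(matrix(1, 5, 2), matrix(1, 4, 2)))),
               "mismatch")
  expect_error(cohort_dataset(g, grid = 1:4), "grid")
})
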