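# Individual/crowd accuracy, bootstrap summaries, Friedman, Wilcoxon,
# folded-normal closed forms.

test_that("individual and crowd accuracy match hand computation", {
  truth <- make_truth("p1", height = 171)
  est <- make_estimates(rep("img1", 3), rep("p1", 3), c(170, 172, 180))
  ind <- individual_accuracy(est, truth, "height")
  expect_equal(ind$abs_error, 1)                       # median(|-1|,|1|,|9|)
  expect_equal(ind$pct_error, 1 / 171 * 100)
  crw <- crowd_accuracy(est, truth, "height")
  expect_equal(crw$abs_error, 1)                       # |172 - 171|
  # exact raters give zero error everywhere
  est0 <- make_estimates(c("a", "a", "b"), c("p1", "p1", "p1"),
                         c(171, 171, 171))
  expect_equal(individual_accuracy(est0, truth, "height")$abs_error, c(0, 0))
  expect_equal(crowd_accuracy(est0, truth, "height")$abs_error, c(0, 0))
  # a single rater: crowd equals individual exactly
  est1 <- make_estimates("img1", "p1", 166)
  expect_equal(crowd_accuracy(est1, truth, "height")$abs_error,
               individual_accuracy(est1, truth, "height")$abs_error)
})

test_that("many-rater limits: individual -> 0.6745 sigma, crowd -> 0", {
  set.seed(71)
  sigma <- 5
  truth <- make_truth("p1", height = 170)
  est <- make_estimates(rep("img1", 40000), rep("p1", 40000),
                        170 + rnorm(40000, 0, sigma))
  ind <- individual_accuracy(est, truth, "height")$abs_error
  crw <- crowd_accuracy(est, truth, "height")$abs_error
  expect_equal(ind, qnorm(0.75) * sigma, tolerance = 0.02)
  expect_lt(crw, 0.1)
})

test_that("missing estimates are dropped pairwise with coverage reporting", {
  truth <- make_truth(c("p1", "p2"), height = c(170, 180))
  est <- make_estimates(c("a", "a", "b"), c("p1", "p1", "p2"),
                        est_h = c(172, NA, NA))
  expect_warning(ind <- individual_accuracy(est, truth, "height"),
                 "excluded")
  expect_equal(ind$image_id, "a")
  expect_equal(unname(attr(ind, "coverage")["excluded"]), 1L)
})

test_that("summarize_errors: medians, degenerate and seeded bootstrap CIs", {
  truth <- make_truth(paste0("p", 1:5), height = rep(100, 5))
  errs <- c(1, 2, 3, 4, 100)
  est <- make_estimates(paste0("i", 1:5), paste0("p", 1:5), 100 + errs)
  smp <- individual_accuracy(est, truth, "height")
  s <- summarize_errors(smp, n_boot = 200, seed = 4)
  expect_equal(s$median_abs, 3)     # robust to the outlier
  expect_true(s$ci_abs_low <= s$median_abs && s$median_abs <= s$ci_abs_high)

  # constant errors: zero-width CI
  estc <- make_estimates(paste0("i", 1:5), paste0("p", 1:5), rep(107, 5))
  sc <- summarize_errors(individual_accuracy(estc, truth, "height"),
                         n_boot = 100, seed = 1)
  expect_equal(c(sc$ci_abs_low, sc$median_abs, sc$ci_abs_high), c(7, 7, 7))

  # seed determinism and row-order invariance
  s1 <- summarize_errors(smp, n_boot = 300, seed = 11)
  s2 <- summarize_errors(smp, n_boot = 300, seed = 11)
  expect_identical(s1, s2)
  shuffled <- smp[c(3, 1, 5, 2, 4), ]
  attributes(shuffled)[c("group", "attribute", "setting")] <-
    attributes(smp)[c("group", "attribute", "setting")]
  s3 <- summarize_errors(shuffled, n_boot = 300, seed = 11)
  expect_equal(s3$ci_abs_low, s1$ci_abs_low)
  expect_equal(s3$ci_abs_high, s1$ci_abs_high)

  one <- smp[1, ]
  attr(one, "group") <- "g"
  expect_warning(sdeg <- summarize_errors(one, n_boot = 10),
                 "degenerate")
  expect_equal(sdeg$ci_abs_low, sdeg$ci_abs_high)
})

test_that("friedman_errors matches first-principles statistic and handles
           degenerate input", {
  set.seed(91)
  m <- matrix(rexp(24), 8, 3, dimnames = list(paste0("i", 1:8), NULL))
  fr <- friedman_errors(m)
  expect_equal(fr$statistic, friedman_stat_oracle(m), tolerance = 1e-12)
  expect_equal(fr$p_value,
               pchisq(fr$statistic, df = 2, lower.tail = FALSE))
  # identical columns: no group effect by definition
  ident <- matrix(rep(rexp(6), 3), 6, 3)
  fr0 <- friedman_errors(ident)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)
  # one uniformly terrible group separates at any threshold
  n <- 80
  sep <- cbind(rexp(n), rexp(n), rexp(n) + 100)
  expect_lt(friedman_errors(sep)$p_value, 1e-10)
  # incomplete rows are dropped and reported
  m_na <- m; m_na[2, 1] <- NA
  fr_na <- friedman_errors(m_na)
  expect_equal(fr_na$n_images, 7L)
  expect_equal(fr_na$n_dropped, 1L)
})

test_that("friedman p agrees with the within-row permutation oracle", {
  set.seed(303)
  # the implementation's p is a chi-square approximation; its accuracy
  # improves with the number of groups, so small-n instances use k >= 4
  for (dims in list(c(8, 4), c(10, 4), c(9, 5))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    p_impl <- friedman_errors(m)$p_value
    p_perm <- friedman_perm_p(m, n_perm = 10000L)
    expect_lt(abs(p_impl - p_perm), 0.06)
  }
  # the rank statistic itself must match the oracle exactly on any instance
  for (dims in list(c(6, 3), c(5, 3), c(10, 5))) {
    m <- matrix(sample(1:4, prod(dims), TRUE), dims[1], dims[2])  # heavy ties
    if (all(apply(m, 1, function(r) length(unique(r)) == 1L))) next
    expect_equal(friedman_errors(m)$statistic, friedman_stat_oracle(m),
                 tolerance = 1e-12)
  }
})

test_that("pairwise_wilcoxon: Bonferroni bookkeeping and exact small-n p", {
  set.seed(404)
  m <- matrix(rexp(40), 8, 5,
              dimnames = list(NULL, c("ai", "expert", "crowd",
                                      "individual", "baseline")))
  pw <- pairwise_wilcoxon(m, alpha = 0.05)
  expect_equal(nrow(pw), 10L)                 # 5 groups -> 10 pairs
  expect_equal(unique(pw$threshold), 0.005)   # 0.05 / 10
  expect_true(all(pw$significant == (pw$p_value < 0.005)))
  expect_true(all(pw$significant_strict == (pw$p_value < 0.0005)))

  # n = 8 paired samples: p matches exhaustive sign enumeration
  for (trial in 1:6) {
    x <- rnorm(8); y <- rnorm(8)
    pw2 <- pairwise_wilcoxon(cbind(a = x, b = y))
    expect_equal(pw2$p_value, signed_rank_enum_p(x - y), tolerance = 1e-12)
  }

  # identical columns: degenerate pair, never significant
  ident <- cbind(g1 = 1:6, g2 = 1:6)
  pwi <- pairwise_wilcoxon(ident)
  expect_equal(pwi$p_value, 1)
  expect_true(pwi$degenerate)
  expect_false(pwi$significant)
})

test_that("wilcoxon normal-approximation path is sane for larger n", {
  set.seed(55)
  x <- rnorm(60); y <- rnorm(60, 1)
  pw <- pairwise_wilcoxon(cbind(a = x, b = y))
  expect_lt(pw$p_value, 1e-4)
  same <- rnorm(60)
  pw2 <- pairwise_wilcoxon(cbind(a = same, b = same + rnorm(60, 0, 1e-6)))
  expect_gt(pw2$p_value, 0.01)
})

test_that("folded-normal closed forms match direct quantities", {
  expect_equal(folded_normal_median(0, 1), qnorm(0.75), tolerance = 1e-9)
  expect_equal(folded_normal_median(3, 0), 3)
  expect_equal(folded_normal_median(-17.8, 0), 17.8)
  # simulation cross-check
  set.seed(12)
  x <- abs(rnorm(4e5, 2.5, 3))
  expect_equal(folded_normal_median(2.5, 3), median(x), tolerance = 0.01)
  # mixture: equal weights, symmetric components
  expect_equal(mixture_folded_median(c(0, 0), c(1, 1), c(1, 1)),
               qnorm(0.75), tolerance = 1e-9)
})

test_that("crowd beats individual under unbiased symmetric noise", {
  set.seed(777)
  wins <- 0L
  n_exp <- 120L
  for (e in seq_len(n_exp)) {
    truth <- make_truth(paste0("p", 1:30), height = runif(30, 150, 190))
    n_raters <- 9L
    est <- make_estimates(
      image_id = rep(paste0("i", 1:30), each = n_raters),
      participant_id = rep(paste0("p", 1:30), each = n_raters),
      est_h = rep(truth$true_height_cm, each = n_raters) +
        rnorm(30 * n_raters, 0, 6),
      estimator_id = rep(paste0("r", 1:n_raters), 30))
    ind <- median(individual_accuracy(est, truth, "height")$abs_error)
    crw <- median(crowd_accuracy(est, truth, "height")$abs_error)
    if (crw < ind) wins <- wins + 1L
  }
  expect_gte(wins / n_exp, 0.95)
})
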