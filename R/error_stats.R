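# Comparative error statistics: per-image individual and crowd median
# accuracies, percent-of-base errors, percentile-bootstrap CIs of medians,
# the Friedman omnibus, and Bonferroni-corrected pairwise Wilcoxon
# signed-rank tests.
#
# Aggregation is two-level throughout: a per-image statistic first, then
# the median across images. Images are the unit of analysis; groups that
# contribute one estimate per image (AI, experts, baseline) reduce to the
# same quantity under either reading.

new_error_sample <- function(df, group, attribute, setting) {
  structure(df, class = c("error_sample", "data.frame"),
            group = group, attribute = attribute, setting = setting)
}

join_truth <- function(estimates, truth, attribute) {
  col <- if (attribute == "height") "height_est_cm" else "weight_est_kg"
  tcol <- if (attribute == "height") "true_height_cm" else "true_weight_kg"
  tv <- stats::setNames(truth[[tcol]], truth$participant_id)
  bad <- setdiff(estimates$participant_id, truth$participant_id)
  if (length(bad) > 0L)
    stop_anthropix(paste0("estimate references unknown participant: ",
                          bad[1L]), "anthropix_config_error")
  data.frame(image_id = estimates$image_id,
             est = estimates[[col]],
             true = unname(tv[estimates$participant_id]),
             stringsAsFactors = FALSE)
}

#' Individual estimation accuracy per image
#'
#' For every image, the median over raters of the absolute estimation
#' error `|estimate - truth|`; the percent error is that median divided by
#' the image's true value, times 100. Records with a missing estimate are
#' dropped pairwise; images left with no raters are excluded with a
#' warning and counted in the `coverage` attribute.
#'
#' With `pooling = "pooled"` the per-rater absolute errors are returned
#' un-aggregated (one row per image-rater pair), the alternative reading
#' in which the across-image median pools all individual errors.
#'
#' @param estimates Estimate-record data frame.
#' @param truth Cohort data frame with ground truth.
#' @param attribute `"height"` or `"weight"`.
#' @param pooling `"per_image"` (default) or `"pooled"`.
#' @param setting Label stored on the result (informational).
#' @return An `error_sample` data frame with columns `image_id`,
#'   `abs_error`, `pct_error`.
#' @export
individual_accuracy <- function(estimates, truth,
                                attribute = c("height", "weight"),
                                pooling = c("per_image", "pooled"),
                                setting = NA_character_) {
  attribute <- match.arg(attribute)
  pooling <- match.arg(pooling)
  j <- join_truth(estimates, truth, attribute)
  dropped <- unique(j$image_id[is.na(j$est)])
  j <- j[!is.na(j$est), , drop = FALSE]
  dropped <- setdiff(dropped, j$image_id)
  if (length(dropped) > 0L)
    warning(sprintf("%d image(s) excluded: no raters after removing missing estimates",
                    length(dropped)))
  j$abs_err <- abs(j$est - j$true)
  if (pooling == "pooled") {
    out <- data.frame(image_id = j$image_id, abs_error = j$abs_err,
                      pct_error = j$abs_err / j$true * 100,
                      stringsAsFactors = FALSE)
  } else {
    med <- tapply(j$abs_err, j$image_id, stats::median)
    tru <- tapply(j$true, j$image_id, `[`, 1L)
    out <- data.frame(image_id = names(med),
                      abs_error = unname(as.vector(med)),
                      pct_error = unname(as.vector(med / tru * 100)),
                      stringsAsFactors = FALSE)
  }
  s <- new_error_sample(out, group = estimates$group[1L],
                        attribute = attribute, setting = setting)
  attr(s, "coverage") <- c(images = length(unique(out$image_id)),
                           excluded = length(dropped))
  s
}

#' Crowd estimation accuracy per image
#'
#' For every image, the absolute error of the median-aggregated crowd
#' estimate, `|median(estimates) - truth|` — the wisdom-of-crowds reading
#' in which raters are first pooled into one consensus guess. With a
#' single rater per image the crowd and individual accuracies coincide.
#'
#' @inheritParams individual_accuracy
#' @return An `error_sample` data frame.
#' @export
crowd_accuracy <- function(estimates, truth,
                           attribute = c("height", "weight"),
                           setting = NA_character_) {
  attribute <- match.arg(attribute)
  j <- join_truth(estimates, truth, attribute)
  dropped <- unique(j$image_id[is.na(j$est)])
  j <- j[!is.na(j$est), , drop = FALSE]
  dropped <- setdiff(dropped, j$image_id)
  if (length(dropped) > 0L)
    warning(sprintf("%d image(s) excluded: no raters after removing missing estimates",
                    length(dropped)))
  med_est <- tapply(j$est, j$image_id, stats::median)
  tru <- tapply(j$true, j$image_id, `[`, 1L)
  abs_err <- abs(med_est - tru)
  out <- data.frame(image_id = names(med_est),
                    abs_error = unname(as.vector(abs_err)),
                    pct_error = unname(as.vector(abs_err / tru * 100)),
                    stringsAsFactors = FALSE)
  s <- new_error_sample(out, group = estimates$group[1L],
                        attribute = attribute, setting = setting)
  attr(s, "coverage") <- c(images = nrow(out), excluded = length(dropped))
  s
}

#' Summarise an error sample with a bootstrap CI
#'
#' The across-image median of the per-image errors, with a percentile
#' bootstrap confidence interval obtained by resampling images with
#' replacement (default 1000 iterations, 95% level). The median is used
#' throughout because estimation errors are not normally distributed
#' within or across images.
#'
#' @param sample An `error_sample` from [individual_accuracy()] or
#'   [crowd_accuracy()].
#' @param n_boot Bootstrap iterations (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A one-row data frame: `group`, `attribute`, `setting`,
#'   `n_images`, `median_abs`, `ci_abs_low`, `ci_abs_high`, `median_pct`,
#'   `ci_pct_low`, `ci_pct_high`. With fewer than two images the CI
#'   degenerates to the median, with a warning.
#' @export
summarize_errors <- function(sample, n_boot = 1000L, level = 0.95,
                             seed = NULL) {
  if (nrow(sample) == 0L)
    stop_anthropix("cannot summarise an empty error sample",
                   "anthropix_config_error")
  # canonical image order so the bootstrap is invariant to input row order
  sample <- sample[order(sample$image_id), , drop = FALSE]
  n <- nrow(sample)
  med_abs <- stats::median(sample$abs_error)
  med_pct <- stats::median(sample$pct_error)
  if (n < 2L) {
    warning("fewer than 2 images: reporting a degenerate CI")
    ci_abs <- c(med_abs, med_abs)
    ci_pct <- c(med_pct, med_pct)
  } else {
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    boots <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      rbind(apply(idx, 2L, function(i) stats::median(sample$abs_error[i])),
            apply(idx, 2L, function(i) stats::median(sample$pct_error[i])))
    })
    ci_abs <- unname(stats::quantile(boots[1L, ], probs))
    ci_pct <- unname(stats::quantile(boots[2L, ], probs))
  }
  data.frame(group = attr(sample, "group"),
             attribute = attr(sample, "attribute"),
             setting = attr(sample, "setting"),
             n_images = n,
             median_abs = med_abs, ci_abs_low = ci_abs[1L],
             ci_abs_high = ci_abs[2L],
             median_pct = med_pct, ci_pct_low = ci_pct[1L],
             ci_pct_high = ci_pct[2L],
             stringsAsFactors = FALSE)
}

#' Assemble a per-image error matrix across groups
#'
#' Joins error samples on `image_id` into an images-by-groups matrix of
#' absolute (or percent) errors, the input shape of [friedman_errors()]
#' and [pairwise_wilcoxon()].
#'
#' @param samples Named list of `error_sample` objects (names become
#'   column names; unnamed lists use each sample's group).
#' @param value `"abs_error"` or `"pct_error"`.
#' @return A numeric matrix, rownames = image ids; images missing from a
#'   sample yield `NA` cells.
#' @export
error_matrix <- function(samples, value = c("abs_error", "pct_error")) {
  value <- match.arg(value)
  nms <- names(samples)
  if (is.null(nms) || any(nms == ""))
    nms <- vapply(samples, function(s) as.character(attr(s, "group")),
                  character(1L))
  ids <- sort(unique(unlist(lapply(samples, `[[`, "image_id"))))
  m <- sapply(samples, function(s)
    s[[value]][match(ids, s$image_id)])
  dimnames(m) <- list(ids, nms)
  m
}

complete_cases_matrix <- function(mat) {
  keep <- stats::complete.cases(mat)
  list(mat = mat[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Friedman omnibus test across estimator groups
#'
#' Nonparametric repeated-measures omnibus on the per-image error matrix:
#' errors are ranked within each image across the k groups (average ranks
#' for ties) and the tie-corrected Friedman chi-square is referred to a
#' chi-square distribution with k - 1 degrees of freedom. Images with a
#' missing cell are dropped (complete-case) and counted in the result.
#'
#' @param mat Images-by-groups error matrix from [error_matrix()].
#' @return A list: `statistic`, `p_value`, `df`, `n_images`,
#'   `n_dropped`.
#' @export
friedman_errors <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L)
    stop_anthropix("Friedman test needs at least 2 groups",
                   "anthropix_config_error")
  cc <- complete_cases_matrix(mat)
  if (nrow(cc$mat) < 2L)
    stop_anthropix("Friedman test needs at least 2 complete images",
                   "anthropix_config_error")
  # all rows fully tied (e.g. identical columns): no rank information,
  # the tie-corrected statistic is 0/0 -> define as no group effect
  if (all(apply(cc$mat, 1L, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, p_value = 1, df = ncol(mat) - 1L,
                n_images = nrow(cc$mat), n_dropped = cc$dropped))
  ft <- stats::friedman.test(cc$mat)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter), n_images = nrow(cc$mat),
       n_dropped = cc$dropped)
}

#' All-pairs Wilcoxon signed-rank tests with Bonferroni correction
#'
#' For k groups, all k(k-1)/2 two-sided Wilcoxon signed-rank tests on the
#' paired per-image error differences. Zero differences are dropped before
#' ranking (the classic Wilcoxon convention); the exact null distribution
#' is used for n <= 25 untied differences and the normal approximation
#' with tie correction otherwise. The family-wise significance threshold
#' is `alpha / n_pairs` (0.05 / 10 = 0.005 for five groups); a ten-fold
#' stricter flag is also reported.
#'
#' @param mat Images-by-groups error matrix (complete-case rows are used
#'   per pair).
#' @param alpha Family-wise level before correction (default 0.05).
#' @param zero_tol Absolute differences at or below this are treated as
#'   zeros and dropped (default 1e-9, the chain's geometric epsilon, so
#'   floating-point dust from exact channels never masquerades as signal).
#' @return A data frame with one row per pair: `group_a`, `group_b`,
#'   `n`, `statistic` (signed-rank V), `p_value`, `threshold`,
#'   `significant`, `significant_strict`, `degenerate` (all differences
#'   zero).
#' @export
pairwise_wilcoxon <- function(mat, alpha = 0.05, zero_tol = 1e-9) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2L)
    stop_anthropix("need at least 2 groups", "anthropix_config_error")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2L)
  thr <- alpha / ncol(pairs)
  rows <- apply(pairs, 2L, function(pr) {
    d <- mat[, pr[1L]] - mat[, pr[2L]]
    d <- d[!is.na(d)]
    nz <- d[abs(d) > zero_tol]
    if (length(nz) == 0L) {
      return(data.frame(group_a = colnames(mat)[pr[1L]],
                        group_b = colnames(mat)[pr[2L]],
                        n = 0L, statistic = NA_real_, p_value = 1,
                        threshold = thr, significant = FALSE,
                        significant_strict = FALSE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    data.frame(group_a = colnames(mat)[pr[1L]],
               group_b = colnames(mat)[pr[2L]],
               n = length(nz), statistic = unname(wt$statistic),
               p_value = min(wt$p.value, 1),
               threshold = thr,
               significant = wt$p.value < thr,
               significant_strict = wt$p.value < thr / 10,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median of a folded normal distribution
#'
#' The median of `|X|` for `X ~ Normal(mu, sigma)`: the root in `m` of
#' `P(-m < X < m) = 1/2`. This is the large-cohort limit of the median
#' absolute error of a constant estimator against a normal population.
#'
#' @param mu,sigma Mean and SD of the underlying normal; `sigma = 0` gives
#'   `|mu|`.
#' @return The median of the folded distribution.
#' @export
folded_normal_median <- function(mu, sigma) {
  if (sigma < 0)
    stop_anthropix("'sigma' must be non-negative", "anthropix_config_error")
  if (sigma == 0) return(abs(mu))
  f <- function(m) stats::pnorm((m - mu) / sigma) -
    stats::pnorm((-m - mu) / sigma) - 0.5
  stats::uniroot(f, c(0, abs(mu) + 10 * sigma), tol = 1e-12)$root
}

#' Median absolute error of a constant estimator against a normal mixture
#'
#' Closed-form pooled analogue of [folded_normal_median()] for a
#' population that mixes several normal components (e.g. the two genders
#' of a cohort): the root of the mixture CDF identity
#' `sum(w_g * P(|X_g| < m)) = 1/2`.
#'
#' @param mu,sigma Component means and SDs of the signed errors.
#' @param weight Mixture weights (normalised internally).
#' @return The pooled median absolute error.
#' @export
mixture_folded_median <- function(mu, sigma, weight) {
  weight <- weight / sum(weight)
  f <- function(m) sum(weight * (stats::pnorm((m - mu) / sigma) -
                                   stats::pnorm((-m - mu) / sigma))) - 0.5
  stats::uniroot(f, c(0, max(abs(mu)) + 10 * max(sigma)), tol = 1e-12)$root
}

#' Theoretical baseline median absolute error for a cohort
#'
#' The large-cohort closed form of the pooled median absolute error of the
#' gendered population-average baseline against a cohort drawn from
#' gendered normals: a two-component [mixture_folded_median()] with
#' component means `cohort mean - baseline norm` per gender and weights
#' proportional to the gender counts.
#'
#' @param attribute `"height"` or `"weight"`.
#' @param params A [cohort_params()] object.
#' @param norms A [population_norms()] object.
#' @return The theoretical pooled median absolute error (cm or kg).
#' @export
baseline_error_theory <- function(attribute = c("height", "weight"),
                                  params = cohort_params(),
                                  norms = population_norms()) {
  attribute <- match.arg(attribute)
  if (attribute == "height") {
    mu <- c(params$mean_height_f - norms$us_height_f,
            params$mean_height_m - norms$us_height_m)
    sg <- c(params$sd_height_f, params$sd_height_m)
  } else {
    mu <- c(params$mean_weight_f - norms$us_weight_f,
            params$mean_weight_m - norms$us_weight_m)
    sg <- c(params$sd_weight_f, params$sd_weight_m)
  }
  mixture_folded_median(mu, sg, c(params$n_female, params$n_male))
}
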