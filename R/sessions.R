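# Simulated rating sessions: each rater sees one set of images (one image
# per photographed participant, as in crowd-sourced study designs) plus
# four catch trials with known displayed answers.

#' Partition images into rater sets
#'
#' Splits an image table into sets in which each photographed participant
#' appears exactly once, separately per capture setting: replicate `k` of a
#' setting collects the `k`-th image of every participant. A cohort of 58
#' with the default design yields 14 no-reference studio sets, 1 reference
#' set and 5 wild sets of 58 images each.
#'
#' @param images Image table from [generate_design()].
#' @return A list of data frames (subsets of `images`), named
#'   `<setting>_set<k>`.
#' @export
partition_image_sets <- function(images) {
  if (nrow(images) == 0L) return(list())
  key <- paste(images$setting, sprintf("set%02d", images$pose_index),
               sep = "_")
  split(images, key)
}

#' Simulate rating sessions
#'
#' Each session is one rater working through one image set plus four catch
#' trials. Estimates are ground truth plus the rater model's bias and
#' noise (additive Gaussian or multiplicative lognormal), rejection-
#' resampled to stay positive. Catch-trial failure and study incompletion
#' can be probabilistic, or assigned deterministically via `exact_counts`
#' (first the catch failures, then the incompletions, in session order) to
#' reproduce exact exclusion arithmetic; the two buckets are disjoint in
#' that mode. Incomplete sessions carry a truncated response list.
#'
#' @param images Image table (one rater set, or a full design — each
#'   session is assigned one set from [partition_image_sets()] in
#'   round-robin order).
#' @param participants Cohort table with ground truth.
#' @param model A [rater_model()].
#' @param n_sessions Number of raters to simulate.
#' @param seed Integer seed.
#' @param catch_fail_prob Probability a session fails at least one catch
#'   trial.
#' @param incomplete_prob Probability a (catch-passing) session is
#'   abandoned before completion.
#' @param exact_counts Optional `c(catch_failed, incomplete)` integer
#'   counts overriding the probabilities.
#' @return A list of `rater_session` objects, each with `rater_id`,
#'   `group`, `responses` (an estimate table), `catch_results` (4
#'   logicals, `TRUE` = passed) and `completed`.
#' @export
simulate_sessions <- function(images, participants, model = rater_model(),
                              n_sessions = 325L, seed = NULL,
                              catch_fail_prob = 0, incomplete_prob = 0,
                              exact_counts = NULL) {
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 1L)
    stop_anthropix("'n_sessions' must be at least 1",
                   "anthropix_config_error")
  unknown <- setdiff(images$participant_id, participants$participant_id)
  if (length(unknown) > 0L)
    stop_anthropix(paste0("image references unknown participant: ",
                          unknown[1L]), "anthropix_config_error")
  sets <- partition_image_sets(images)
  if (length(sets) == 0L)
    stop_anthropix("no images to rate", "anthropix_config_error")

  truth_h <- stats::setNames(participants$true_height_cm,
                             participants$participant_id)
  truth_w <- stats::setNames(participants$true_weight_kg,
                             participants$participant_id)

  if (!is.null(exact_counts)) {
    nc <- as.integer(exact_counts[1L])
    ni <- as.integer(exact_counts[2L])
    if (nc + ni > n_sessions)
      stop_anthropix("exact_counts exceed n_sessions",
                     "anthropix_config_error")
    failed <- seq_len(n_sessions) <= nc
    incomplete <- !failed & seq_len(n_sessions) <= nc + ni
  }

  with_seed(seed, {
    if (is.null(exact_counts)) {
      failed <- stats::runif(n_sessions) < catch_fail_prob
      incomplete <- !failed & (stats::runif(n_sessions) < incomplete_prob)
    }
    lapply(seq_len(n_sessions), function(s) {
      set <- sets[[(s - 1L) %% length(sets) + 1L]]
      n_img <- nrow(set)
      n_resp <- if (incomplete[s]) sample.int(max(n_img - 1L, 1L), 1L)
                else n_img
      resp <- set[seq_len(n_resp), c("image_id", "participant_id"),
                  drop = FALSE]
      th <- truth_h[resp$participant_id]
      tw <- truth_w[resp$participant_id]
      if (model$noise == "gaussian") {
        h <- th + model$height_bias_cm
        w <- tw + model$weight_bias_kg
        if (model$height_sd_cm > 0) h <- rnorm_pos(n_resp, h, model$height_sd_cm)
        if (model$weight_sd_kg > 0) w <- rnorm_pos(n_resp, w, model$weight_sd_kg)
      } else {
        h <- th * exp(stats::rnorm(n_resp, model$height_bias_cm,
                                   model$height_sd_cm))
        w <- tw * exp(stats::rnorm(n_resp, model$weight_bias_kg,
                                   model$weight_sd_kg))
      }
      catch <- if (failed[s]) {
        res <- rep(TRUE, 4L)
        res[sample.int(4L, 1L)] <- FALSE
        res
      } else rep(TRUE, 4L)
      structure(list(
        rater_id = sprintf("R%04d", s),
        group = model$group,
        responses = data.frame(
          image_id = resp$image_id, participant_id = resp$participant_id,
          estimator_id = sprintf("R%04d", s), group = model$group,
          height_est_cm = unname(h), weight_est_kg = unname(w),
          stringsAsFactors = FALSE),
        catch_results = catch,
        completed = !incomplete[s]),
        class = "rater_session")
    })
  })
}
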