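# Estimate channels: the population-average baseline, the mesh-based AI
# channel, session flattening, and the catch-trial exclusion filter.
# All channels emit the same estimate-record schema:
# image_id, participant_id, estimator_id, group, height_est_cm,
# weight_est_kg (NA = estimate declined/absent).

#' Baseline population estimate
#'
#' The baseline estimator predicts the gender-specific average US adult
#' height and weight for every image, regardless of its content. Gender is
#' taken from ground truth.
#'
#' @param gender `"female"` or `"male"`.
#' @param norms A [population_norms()] object.
#' @return Named numeric vector `c(height_cm, weight_kg)`.
#' @examples
#' baseline_estimate("female")  # 161 cm, 78.7 kg
#' @export
baseline_estimate <- function(gender, norms = population_norms()) {
  check_gender(gender)
  if (gender == "female")
    c(height_cm = norms$us_height_f, weight_kg = norms$us_weight_f)
  else
    c(height_cm = norms$us_height_m, weight_kg = norms$us_weight_m)
}

#' Baseline estimate channel
#'
#' One baseline record per image; constant within gender by construction.
#'
#' @param images Image table from [generate_design()].
#' @param participants Cohort table (supplies gender).
#' @param norms A [population_norms()] object.
#' @return An estimate-record data frame with `group = "baseline"`.
#' @export
baseline_channel <- function(images, participants,
                             norms = population_norms()) {
  g <- stats::setNames(participants$gender, participants$participant_id)
  gender <- g[images$participant_id]
  data.frame(
    image_id = images$image_id,
    participant_id = images$participant_id,
    estimator_id = "baseline",
    group = "baseline",
    height_est_cm = ifelse(gender == "female", norms$us_height_f,
                           norms$us_height_m),
    weight_est_kg = ifelse(gender == "female", norms$us_weight_f,
                           norms$us_weight_m),
    stringsAsFactors = FALSE)
}

#' AI (mesh anthropometry) estimate channel
#'
#' Runs the full [measure()] chain on one mesh per image and emits one
#' estimate record per image with `group = "ai"`. A measurement failure is
#' re-raised tagged with the offending `image_id`.
#'
#' @param meshes A list of entries, each a list with `image_id`,
#'   `participant_id` and `mesh` (an [anthro_mesh()] in raw units).
#' @param participants Cohort table (supplies gender for the IPD scaling).
#' @param constants An [anthropometry_constants()] object.
#' @return An estimate-record data frame; empty input gives zero rows.
#' @export
ai_channel <- function(meshes, participants,
                       constants = anthropometry_constants()) {
  g <- stats::setNames(participants$gender, participants$participant_id)
  rows <- lapply(meshes, function(entry) {
    bm <- tryCatch(
      measure(entry$mesh, g[[entry$participant_id]], constants),
      error = function(e) stop_anthropix(
        sprintf("measurement failed for image %s: %s", entry$image_id,
                conditionMessage(e)), "anthropix_measurement_error"))
    data.frame(image_id = entry$image_id,
               participant_id = entry$participant_id,
               estimator_id = "ai", group = "ai",
               height_est_cm = bm$height_cm, weight_est_kg = bm$weight_kg,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(image_id = character(0), participant_id = character(0),
                      estimator_id = character(0), group = character(0),
                      height_est_cm = numeric(0), weight_est_kg = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Simulated baseline error across many cohorts
#'
#' The population-average baseline has an irreducible error set entirely by
#' the cohort's distribution. This helper repeats the cohort experiment:
#' it draws `n_cohorts` cohorts from `params`, applies the gendered
#' baseline to every member, takes each cohort's pooled median absolute
#' error, and returns the mean of those cohort-level medians. Its
#' large-cohort limit is [baseline_error_theory()].
#'
#' @param attribute `"height"` or `"weight"`.
#' @param params A [cohort_params()] object.
#' @param norms A [population_norms()] object.
#' @param n_cohorts Number of simulated cohorts (default 1000).
#' @param seed Master seed; cohort `i` uses `stage_seed(seed, i)`.
#' @return The mean across cohorts of the pooled median absolute error.
#' @export
baseline_error_simulated <- function(attribute = c("height", "weight"),
                                     params = cohort_params(),
                                     norms = population_norms(),
                                     n_cohorts = 1000L, seed = 1L) {
  attribute <- match.arg(attribute)
  tcol <- if (attribute == "height") "true_height_cm" else "true_weight_kg"
  bidx <- if (attribute == "height") "height_cm" else "weight_kg"
  meds <- vapply(seq_len(n_cohorts), function(i) {
    co <- generate_cohort(params, seed = stage_seed(seed, i))
    pred <- vapply(co$gender, function(g) baseline_estimate(g, norms)[[bidx]],
                   numeric(1L))
    stats::median(abs(co[[tcol]] - pred))
  }, numeric(1L))
  mean(meds)
}

#' Catch-trial exclusion filter
#'
#' Removes sessions that failed any of the four catch trials, then
#' sessions that did not complete the study. A session that both failed a
#' catch trial and is incomplete is counted once, in the catch-failed
#' bucket, so bucket counts always sum to the total.
#'
#' @param sessions List of sessions from [simulate_sessions()].
#' @return A list with `valid` (the surviving sessions) and `report`
#'   (counts: `total`, `catch_failed`, `incomplete`, `valid`).
#' @examples
#' # 325 raters, 65 catch failures, 24 incompletions -> 236 valid
#' @export
exclusion_filter <- function(sessions) {
  catch_failed <- vapply(sessions,
                         function(s) any(!s$catch_results), logical(1L))
  incomplete <- vapply(sessions, function(s) !isTRUE(s$completed),
                       logical(1L)) & !catch_failed
  keep <- !catch_failed & !incomplete
  list(valid = sessions[keep],
       report = c(total = length(sessions),
                  catch_failed = sum(catch_failed),
                  incomplete = sum(incomplete),
                  valid = sum(keep)))
}

#' Flatten sessions into an estimate table
#'
#' Binds the response tables of a list of (typically already filtered)
#' sessions into one estimate-record data frame.
#'
#' @param sessions List of sessions.
#' @return An estimate-record data frame.
#' @export
sessions_to_estimates <- function(sessions) {
  if (length(sessions) == 0L)
    return(data.frame(image_id = character(0), participant_id = character(0),
                      estimator_id = character(0), group = character(0),
                      height_est_cm = numeric(0), weight_est_kg = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(lapply(sessions, `[[`, "responses"),
                   list(make.row.names = FALSE)))
}
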