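# Synthetic cohorts and study designs.

#' Generate a synthetic cohort
#'
#' Draws a cohort of participants with gendered normally distributed heights
#' and weights. Non-positive draws (vanishingly rare at anthropometric
#' parameters) are rejection-resampled so the stated means are preserved.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; identical `(params, seed)` give identical
#'   cohorts.
#' @return A data frame of class `anthro_cohort` with columns
#'   `participant_id`, `gender`, `true_height_cm`, `true_weight_kg`.
#' @examples
#' cohort <- generate_cohort(cohort_params(), seed = 1)
#' table(cohort$gender)
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  if (!inherits(params, "cohort_params"))
    params <- do.call(cohort_params, as.list(params))
  nf <- params$n_female
  nm <- params$n_male
  with_seed(seed, {
    hf <- rnorm_pos(nf, params$mean_height_f, params$sd_height_f)
    wf <- rnorm_pos(nf, params$mean_weight_f, params$sd_weight_f)
    hm <- rnorm_pos(nm, params$mean_height_m, params$sd_height_m)
    wm <- rnorm_pos(nm, params$mean_weight_m, params$sd_weight_m)
    out <- data.frame(
      participant_id = sprintf("P%03d", seq_len(nf + nm)),
      gender = rep(c("female", "male"), c(nf, nm)),
      true_height_cm = c(hf, hm),
      true_weight_kg = c(wf, wm),
      stringsAsFactors = FALSE)
    class(out) <- c("anthro_cohort", "data.frame")
    out
  })
}

#' Enumerate the image set of a study design
#'
#' Deterministically expands a cohort and a per-participant pose design into
#' the full list of images, one row per photograph, tagged by capture
#' setting (`studio_noref`, `studio_ref`, `wild`) and pose class. With the
#' default design, 58 participants yield 812 no-reference studio, 58
#' reference studio and 290 in-the-wild images.
#'
#' @param participants A cohort data frame from [generate_cohort()] (only
#'   `participant_id` is used).
#' @param design A [study_design()] object.
#' @return A data frame with columns `image_id`, `participant_id`,
#'   `setting`, `pose_class`. Zero participants give zero rows.
#' @export
generate_design <- function(participants, design = study_design()) {
  if (!inherits(design, "study_design"))
    design <- do.call(study_design, as.list(design))
  ids <- participants$participant_id
  if (length(ids) == 0L)
    return(data.frame(image_id = character(0), participant_id = character(0),
                      setting = character(0), pose_class = character(0),
                      stringsAsFactors = FALSE))
  pose_tbl <- data.frame(
    setting = rep(c("studio_noref", "studio_noref", "studio_ref",
                    "wild", "wild"),
                  c(design$studio_neutral, design$studio_dynamic,
                    design$studio_reference, design$wild_static,
                    design$wild_dynamic)),
    pose_class = rep(c("neutral", "dynamic", "reference",
                       "static", "dynamic"),
                     c(design$studio_neutral, design$studio_dynamic,
                       design$studio_reference, design$wild_static,
                       design$wild_dynamic)),
    stringsAsFactors = FALSE)
  n_pose <- nrow(pose_tbl)
  if (n_pose == 0L)
    return(data.frame(image_id = character(0), participant_id = character(0),
                      setting = character(0), pose_class = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    participant_id = rep(ids, each = n_pose),
    setting = rep(pose_tbl$setting, length(ids)),
    pose_class = rep(pose_tbl$pose_class, length(ids)),
    stringsAsFactors = FALSE)
  # pose index within (participant, setting) -> replicate number used when
  # partitioning images into rater sets with one image per participant
  out$pose_index <- stats::ave(seq_len(nrow(out)),
                               out$participant_id, out$setting,
                               FUN = seq_along)
  out$image_id <- sprintf("%s_%s_%02d", out$participant_id,
                          out$setting, out$pose_index)
  out[, c("image_id", "participant_id", "setting", "pose_class",
          "pose_index")]
}
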