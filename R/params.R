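# Parameter objects: cohort distributions, study design, anthropometric
# constants, population norms, rater noise models. Defaults are the study
# constants; every field is overridable.

#' Cohort distribution parameters
#'
#' Gendered normal distributions for height and weight plus cohort
#' composition. Defaults describe a university cohort of 33 women and
#' 25 men: heights N(161.1, 5.3) / N(176.1, 8.3) cm and weights
#' N(60.9, 11.4) / N(78.4, 12.9) kg for women / men.
#'
#' @param mean_height_f,sd_height_f Female height mean / SD (cm).
#' @param mean_height_m,sd_height_m Male height mean / SD (cm).
#' @param mean_weight_f,sd_weight_f Female weight mean / SD (kg).
#' @param mean_weight_m,sd_weight_m Male weight mean / SD (kg).
#' @param n_female,n_male Cohort composition (counts, may be zero).
#' @return An object of class `cohort_params`.
#' @examples
#' cohort_params()
#' cohort_params(n_female = 100, n_male = 100)
#' @export
cohort_params <- function(mean_height_f = 161.1, sd_height_f = 5.3,
                          mean_height_m = 176.1, sd_height_m = 8.3,
                          mean_weight_f = 60.9, sd_weight_f = 11.4,
                          mean_weight_m = 78.4, sd_weight_m = 12.9,
                          n_female = 33L, n_male = 25L) {
  p <- list(mean_height_f = mean_height_f, sd_height_f = sd_height_f,
            mean_height_m = mean_height_m, sd_height_m = sd_height_m,
            mean_weight_f = mean_weight_f, sd_weight_f = sd_weight_f,
            mean_weight_m = mean_weight_m, sd_weight_m = sd_weight_m,
            n_female = as.integer(n_female), n_male = as.integer(n_male))
  for (nm in grep("^mean_", names(p), value = TRUE)) check_positive(p[[nm]], nm)
  for (nm in grep("^sd_", names(p), value = TRUE)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0)
      stop_anthropix(sprintf("'%s' must be non-negative", nm),
                     "anthropix_config_error")
  }
  if (p$n_female < 0L || p$n_male < 0L)
    stop_anthropix("cohort counts must be non-negative",
                   "anthropix_config_error")
  structure(p, class = "cohort_params")
}

#' Per-participant study design
#'
#' Pose counts per participant in each capture setting. The default design
#' photographs each participant in 8 neutral and 6 dynamic studio poses
#' without a reference object, once next to a reference object, and in
#' 2 static plus 3 dynamic in-the-wild (CCTV-like) poses, i.e. 14
#' no-reference studio, 1 reference studio and 5 wild images per person.
#'
#' @param studio_neutral,studio_dynamic No-reference studio pose counts.
#' @param studio_reference Reference-object studio pose count.
#' @param wild_static,wild_dynamic In-the-wild pose counts.
#' @return An object of class `study_design`.
#' @export
study_design <- function(studio_neutral = 8L, studio_dynamic = 6L,
                         studio_reference = 1L, wild_static = 2L,
                         wild_dynamic = 3L) {
  d <- list(studio_neutral = as.integer(studio_neutral),
            studio_dynamic = as.integer(studio_dynamic),
            studio_reference = as.integer(studio_reference),
            wild_static = as.integer(wild_static),
            wild_dynamic = as.integer(wild_dynamic))
  if (any(unlist(d) < 0L))
    stop_anthropix("pose counts must be non-negative",
                   "anthropix_config_error")
  structure(d, class = "study_design")
}

#' Anthropometric measurement constants
#'
#' Population constants used by the mesh measurement chain: gender-specific
#' average adult inter-pupillary distances (IPD) used as the metric ruler,
#' and the average body density converting enclosed mesh volume to mass.
#' The density of 1023 kg/m^3 corresponds to a gender-agnostic average body
#' fat of 34% (`body_fat_context` is documentation only and enters no
#' computation).
#'
#' @param ipd_mean_f,ipd_sd_f Female IPD mean / SD (cm); defaults 6.17 / 0.36.
#' @param ipd_mean_m,ipd_sd_m Male IPD mean / SD (cm); defaults 6.40 / 0.34.
#' @param body_density Body density (kg/m^3); default 1023.
#' @param body_fat_context Body-fat percentage the density corresponds to.
#' @return An object of class `anthro_constants`.
#' @export
anthropometry_constants <- function(ipd_mean_f = 6.17, ipd_sd_f = 0.36,
                                    ipd_mean_m = 6.40, ipd_sd_m = 0.34,
                                    body_density = 1023,
                                    body_fat_context = 34) {
  k <- list(ipd_mean_f = ipd_mean_f, ipd_sd_f = ipd_sd_f,
            ipd_mean_m = ipd_mean_m, ipd_sd_m = ipd_sd_m,
            body_density = body_density, body_fat_context = body_fat_context)
  for (nm in c("ipd_mean_f", "ipd_mean_m", "body_density"))
    check_positive(k[[nm]], nm)
  structure(k, class = "anthro_constants")
}

ipd_mean <- function(gender, constants) {
  check_gender(gender)
  if (gender == "female") constants$ipd_mean_f else constants$ipd_mean_m
}

#' US adult population norms
#'
#' Gender-specific average US adult height and weight, the constants behind
#' the baseline estimator that predicts the population average for every
#' image regardless of content.
#'
#' @param us_height_f,us_height_m Average heights (cm); defaults 161 / 175.
#' @param us_weight_f,us_weight_m Average weights (kg); defaults 78.7 / 90.8.
#' @return An object of class `population_norms`.
#' @export
population_norms <- function(us_height_f = 161, us_height_m = 175,
                             us_weight_f = 78.7, us_weight_m = 90.8) {
  n <- list(us_height_f = us_height_f, us_height_m = us_height_m,
            us_weight_f = us_weight_f, us_weight_m = us_weight_m)
  for (nm in names(n)) check_positive(n[[nm]], nm)
  structure(n, class = "population_norms")
}

#' Rater noise model
#'
#' Describes how a simulated human estimator (expert or non-expert) deviates
#' from ground truth. The default noise is additive Gaussian per attribute;
#' `noise = "lognormal"` switches to multiplicative lognormal errors, where
#' the bias and SD are interpreted on the log scale relative to truth.
#'
#' @param group `"expert"` or `"nonexpert"`.
#' @param height_bias_cm,height_sd_cm Height bias / SD (cm).
#' @param weight_bias_kg,weight_sd_kg Weight bias / SD (kg).
#' @param raters_per_image Average raters seeing each image (default 22 for
#'   non-experts, 1 for experts).
#' @param noise `"gaussian"` (additive) or `"lognormal"` (multiplicative).
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(group = c("nonexpert", "expert"),
                        height_bias_cm = 0, height_sd_cm = 6,
                        weight_bias_kg = 0, weight_sd_kg = 9,
                        raters_per_image = if (group[1L] == "expert") 1L else 22L,
                        noise = c("gaussian", "lognormal")) {
  group <- match.arg(group)
  noise <- match.arg(noise)
  if (height_sd_cm < 0 || weight_sd_kg < 0)
    stop_anthropix("noise SDs must be non-negative", "anthropix_config_error")
  raters_per_image <- as.integer(raters_per_image)
  if (raters_per_image < 1L)
    stop_anthropix("'raters_per_image' must be at least 1",
                   "anthropix_config_error")
  structure(list(group = group,
                 height_bias_cm = height_bias_cm,
                 height_sd_cm = height_sd_cm,
                 weight_bias_kg = weight_bias_kg,
                 weight_sd_kg = weight_sd_kg,
                 raters_per_image = raters_per_image,
                 noise = noise),
            class = "rater_model")
}
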