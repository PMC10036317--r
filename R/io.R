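# CSV interchange. Dialect: UTF-8, comma separator, '.' decimal, headers
# mandatory, no row names — chosen so identical runs produce byte-identical
# files.

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write ground-truth cohort tables
#'
#' Schema: `participant_id,gender,height_cm,weight_kg`.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param path File path.
#' @return The path (write) or a cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(participant_id = cohort$participant_id,
                    gender = cohort$gender,
                    height_cm = cohort$true_height_cm,
                    weight_kg = cohort$true_weight_kg)
  write_table_csv(out, path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(participant_id = as.character(df$participant_id),
                    gender = df$gender,
                    true_height_cm = df$height_cm,
                    true_weight_kg = df$weight_kg,
                    stringsAsFactors = FALSE)
  class(out) <- c("anthro_cohort", "data.frame")
  out
}

#' Read and write estimate tables
#'
#' Schema: `image_id,participant_id,estimator_id,group,height_est_cm,`
#' `weight_est_kg`; an empty field is an absent (declined) estimate.
#'
#' @param estimates An estimate-record data frame.
#' @param path File path.
#' @return The path (write) or an estimate-record data frame (read).
#' @export
write_estimates_csv <- function(estimates, path) {
  write_table_csv(estimates, path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character",
                                       participant_id = "character",
                                       estimator_id = "character"))
  df$height_est_cm <- as.numeric(df$height_est_cm)
  df$weight_est_kg <- as.numeric(df$weight_est_kg)
  df
}
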