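# End-to-end orchestration: simulate -> measure -> analyze -> report.

#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end comparison. The defaults emulate
#' the full study: a 33 + 25 cohort, the 14/1/5 pose design, 325
#' non-expert sessions with 65 catch failures and 24 incompletions (236
#' valid), one expert pass over the in-the-wild images, per-image meshes
#' with IPD jitter feeding the AI channel, 1000 bootstrap iterations and a
#' 0.05 family-wise alpha over all group pairs.
#'
#' @param seed Master seed; per-stage seeds derive via [stage_seed()].
#' @param cohort A [cohort_params()] object.
#' @param design A [study_design()] object.
#' @param nonexpert,expert [rater_model()] objects for the two human
#'   channels.
#' @param norms A [population_norms()] object.
#' @param constants An [anthropometry_constants()] object.
#' @param n_boot Bootstrap iterations for summary CIs.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @param n_sessions Non-expert sessions to simulate.
#' @param session_counts `c(catch_failed, incomplete)` deterministic counts
#'   (set `NULL` for probabilistic assignment via the two probabilities).
#' @param catch_fail_prob,incomplete_prob Probabilistic session outcomes
#'   (used when `session_counts` is `NULL`).
#' @param n_expert_sessions Expert sessions (each covers one wild set).
#' @param ipd_jitter_sd Per-subject IPD spread (cm) injected into the
#'   generated meshes; this is the AI channel's error source.
#' @param mesh_resolution Ring count of the generated meshes.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_params(),
                       design = study_design(),
                       nonexpert = rater_model("nonexpert"),
                       expert = rater_model("expert", height_sd_cm = 5,
                                            weight_sd_kg = 8),
                       norms = population_norms(),
                       constants = anthropometry_constants(),
                       n_boot = 1000L, alpha = 0.05,
                       n_sessions = 325L,
                       session_counts = c(65L, 24L),
                       catch_fail_prob = 0.2, incomplete_prob = 0.08,
                       n_expert_sessions = 5L,
                       ipd_jitter_sd = 0.25,
                       mesh_resolution = 32L) {
  if (n_boot < 1L)
    stop_anthropix("'n_boot' must be at least 1", "anthropix_config_error")
  if (alpha <= 0 || alpha >= 1)
    stop_anthropix("'alpha' must be in (0, 1)", "anthropix_config_error")
  structure(list(seed = as.integer(seed), cohort = cohort, design = design,
                 nonexpert = nonexpert, expert = expert, norms = norms,
                 constants = constants, n_boot = as.integer(n_boot),
                 alpha = alpha, n_sessions = as.integer(n_sessions),
                 session_counts = session_counts,
                 catch_fail_prob = catch_fail_prob,
                 incomplete_prob = incomplete_prob,
                 n_expert_sessions = as.integer(n_expert_sessions),
                 ipd_jitter_sd = ipd_jitter_sd,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "run_config")
}

#' Run the full simulate-measure-analyze pipeline
#'
#' Executes every stage under derived per-stage seeds: cohort generation,
#' design enumeration, per-image mesh generation plus AI measurement,
#' non-expert and expert session simulation with catch-trial filtering,
#' the baseline channel, per-group error summaries with bootstrap CIs, and
#' — on the in-the-wild complete-case image set across the five groups
#' (ai, expert, nonexpert crowd, nonexpert individual, baseline) — the
#' Friedman omnibus and all-pairs Wilcoxon tests per attribute. Re-running
#' with the same config writes byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return A list: `cohort`, `images`, `estimates`, `session_report`,
#'   `summaries`, `friedman`, `pairwise`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort, seed = stage_seed(config$seed, 1L))
  images <- generate_design(cohort, config$design)
  if (nrow(images) == 0L)
    stop_anthropix("pipeline aborted at stage 'design': empty image set",
                   "anthropix_pipeline_error")

  # AI channel: one mesh per image, IPD jitter per mesh
  meshes <- with_seed(stage_seed(config$seed, 2L),
    lapply(seq_len(nrow(images)), function(i) {
      row <- images[i, ]
      g <- cohort$gender[match(row$participant_id, cohort$participant_id)]
      t_h <- cohort$true_height_cm[match(row$participant_id,
                                         cohort$participant_id)]
      t_w <- cohort$true_weight_kg[match(row$participant_id,
                                         cohort$participant_id)]
      list(image_id = row$image_id, participant_id = row$participant_id,
           mesh = generate_body_mesh(t_h, t_w, g,
                                     resolution = config$mesh_resolution,
                                     ipd_jitter_sd = config$ipd_jitter_sd,
                                     constants = config$constants))
    }))
  est_ai <- ai_channel(meshes, cohort, config$constants)

  # non-expert sessions + catch-trial exclusion
  sessions <- simulate_sessions(images, cohort, config$nonexpert,
                                n_sessions = config$n_sessions,
                                seed = stage_seed(config$seed, 3L),
                                catch_fail_prob = config$catch_fail_prob,
                                incomplete_prob = config$incomplete_prob,
                                exact_counts = config$session_counts)
  filt <- exclusion_filter(sessions)
  est_ne <- sessions_to_estimates(filt$valid)

  # experts rate the in-the-wild images only
  wild <- images[images$setting == "wild", , drop = FALSE]
  est_ex <- if (nrow(wild) > 0L && config$n_expert_sessions > 0L) {
    ex_sessions <- simulate_sessions(wild, cohort, config$expert,
                                     n_sessions = config$n_expert_sessions,
                                     seed = stage_seed(config$seed, 4L))
    sessions_to_estimates(ex_sessions)
  } else est_ne[0L, ]
  if (nrow(est_ex) > 0L) est_ex$group <- "expert"

  est_base <- baseline_channel(images, cohort, config$norms)
  estimates <- rbind(est_ai, est_ex, est_ne, est_base)

  # per-(setting, attribute, group) samples and summaries
  settings <- unique(images$setting)
  seed_boot <- stage_seed(config$seed, 5L)
  summaries <- list()
  wild_samples <- list(height = list(), weight = list())
  for (setting in settings) {
    img_ids <- images$image_id[images$setting == setting]
    for (attribute in c("height", "weight")) {
      chans <- list(
        ai = list(est_ai, "individual"),
        expert = list(est_ex, "individual"),
        crowd = list(est_ne, "crowd"),
        individual = list(est_ne, "individual"),
        baseline = list(est_base, "individual"))
      for (nm in names(chans)) {
        est <- chans[[nm]][[1L]]
        est <- est[est$image_id %in% img_ids, , drop = FALSE]
        if (nrow(est) == 0L) next
        smp <- if (chans[[nm]][[2L]] == "crowd")
          crowd_accuracy(est, cohort, attribute, setting = setting)
        else individual_accuracy(est, cohort, attribute, setting = setting)
        smp2 <- smp
        attr(smp2, "group") <- nm
        summaries[[length(summaries) + 1L]] <-
          summarize_errors(smp2, n_boot = config$n_boot,
                           seed = stage_seed(seed_boot,
                                             length(summaries) + 1L))
        if (setting == "wild")
          wild_samples[[attribute]][[nm]] <- smp2
      }
    }
  }
  summaries <- do.call(rbind, summaries)

  # omnibus + pairwise on the wild complete-case set
  friedman <- list()
  pairwise <- list()
  for (attribute in c("height", "weight")) {
    smps <- wild_samples[[attribute]]
    if (length(smps) >= 2L) {
      m <- error_matrix(smps)
      cc <- complete_cases_matrix(m)
      if (nrow(cc$mat) >= 2L) {
        fr <- friedman_errors(m)
        friedman[[attribute]] <- data.frame(
          attribute = attribute, statistic = fr$statistic,
          df = fr$df, p_value = fr$p_value, n_images = fr$n_images,
          n_dropped = fr$n_dropped, stringsAsFactors = FALSE)
        pw <- pairwise_wilcoxon(cc$mat, alpha = config$alpha)
        pw <- cbind(attribute = attribute, pw)
        pairwise[[attribute]] <- pw
      }
    }
  }
  friedman <- if (length(friedman)) do.call(rbind, c(friedman,
                                                     list(make.row.names = FALSE)))
  pairwise <- if (length(pairwise)) do.call(rbind, c(pairwise,
                                                     list(make.row.names = FALSE)))

  result <- list(cohort = cohort, images = images, estimates = estimates,
                 session_report = filt$report, summaries = summaries,
                 friedman = friedman, pairwise = pairwise)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(cohort = "cohort.csv", images = "images.csv",
               estimates = "estimates.csv", summaries = "summaries.csv",
               friedman = "friedman.csv", pairwise = "pairwise.csv")
    write_cohort_csv(cohort, file.path(out_dir, files["cohort"]))
    write_table_csv(images, file.path(out_dir, files["images"]))
    write_estimates_csv(estimates, file.path(out_dir, files["estimates"]))
    write_table_csv(summaries, file.path(out_dir, files["summaries"]))
    if (!is.null(friedman))
      write_table_csv(friedman, file.path(out_dir, files["friedman"]))
    if (!is.null(pairwise))
      write_table_csv(pairwise, file.path(out_dir, files["pairwise"]))
    paths <- file.path(out_dir, files)
    paths <- paths[file.exists(paths)]
    manifest <- list(
      package = "anthropix",
      version = as.character(utils::packageVersion("anthropix")),
      seed = config$seed,
      session_report = as.list(filt$report),
      files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' Render a human-readable comparison report
#'
#' Formats the pipeline's outputs as Markdown: a per-group/per-setting
#' median-error table (absolute and percent, with bootstrap CIs) and, per
#' attribute, an upper-triangular significance matrix in which `*` marks a
#' pair below the Bonferroni-corrected threshold and `**` a pair ten-fold
#' below it.
#'
#' @param summaries Summary data frame from [run_pipeline()].
#' @param pairwise Pairwise-test data frame (or `NULL` to omit).
#' @return A character vector of Markdown lines.
#' @export
render_report <- function(summaries, pairwise = NULL) {
  lines <- c("# Height/weight estimation error report", "",
             "## Median errors by group and setting", "",
             "| group | setting | attribute | median (abs) | 95% CI | median (%) | 95% CI |",
             "|---|---|---|---|---|---|---|")
  unit <- ifelse(summaries$attribute == "height", "cm", "kg")
  lines <- c(lines, sprintf(
    "| %s | %s | %s | %.1f %s | [%.1f, %.1f] | %.1f%% | [%.1f, %.1f] |",
    summaries$group, summaries$setting, summaries$attribute,
    summaries$median_abs, unit, summaries$ci_abs_low, summaries$ci_abs_high,
    summaries$median_pct, summaries$ci_pct_low, summaries$ci_pct_high))
  if (!is.null(pairwise) && nrow(pairwise) > 0L) {
    for (attribute in unique(pairwise$attribute)) {
      pw <- pairwise[pairwise$attribute == attribute, , drop = FALSE]
      groups <- unique(c(pw$group_a, pw$group_b))
      lines <- c(lines, "", sprintf("## Pairwise significance (%s)",
                                    attribute), "",
                 paste0("| | ", paste(groups[-1L], collapse = " | "), " |"),
                 paste0("|", strrep("---|", length(groups))))
      star <- function(a, b) {
        r <- pw[(pw$group_a == a & pw$group_b == b) |
                  (pw$group_a == b & pw$group_b == a), , drop = FALSE]
        if (nrow(r) == 0L) ""
        else if (r$significant_strict[1L]) "**"
        else if (r$significant[1L]) "*"
        else ""
      }
      for (i in seq_len(length(groups) - 1L)) {
        cells <- vapply(seq_along(groups[-1L]), function(jj) {
          j <- jj + 1L
          if (j <= i) "" else star(groups[i], groups[j])
        }, character(1L))
        lines <- c(lines, paste0("| ", groups[i], " | ",
                                 paste(cells, collapse = " | "), " |"))
      }
      thr <- pw$threshold[1L]
      lines <- c(lines, "", sprintf(
        "`*` p < %.4g (Bonferroni-corrected), `**` p < %.4g.", thr, thr / 10))
    }
  }
  lines
}
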