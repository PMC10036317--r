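# Sessions, exclusion filter, baseline and AI channels.

small_study <- function(n_f = 3, n_m = 2, seed = 21) {
  co <- generate_cohort(cohort_params(n_female = n_f, n_male = n_m),
                        seed = seed)
  list(cohort = co, images = generate_design(co, study_design()))
}

test_that("noiseless raters reproduce ground truth exactly", {
  st <- small_study()
  model <- rater_model("nonexpert", height_sd_cm = 0, weight_sd_kg = 0)
  ses <- simulate_sessions(st$images, st$cohort, model, n_sessions = 4,
                           seed = 3)
  est <- sessions_to_estimates(ses)
  truth_h <- st$cohort$true_height_cm[match(est$participant_id,
                                            st$cohort$participant_id)]
  truth_w <- st$cohort$true_weight_kg[match(est$participant_id,
                                            st$cohort$participant_id)]
  expect_equal(est$height_est_cm, truth_h)
  expect_equal(est$weight_est_kg, truth_w)
})

test_that("session outcomes: probabilistic and deterministic assignment", {
  st <- small_study()
  # boundary probability: everyone fails a catch trial
  all_fail <- simulate_sessions(st$images, st$cohort, rater_model(),
                                n_sessions = 12, seed = 5,
                                catch_fail_prob = 1)
  expect_true(all(vapply(all_fail, function(s) any(!s$catch_results),
                         logical(1))))
  expect_equal(unname(exclusion_filter(all_fail)$report["valid"]), 0L)

  # the study's exclusion arithmetic: 325 - 65 - 24 = 236
  ses <- simulate_sessions(st$images, st$cohort, rater_model(),
                           n_sessions = 325, seed = 6,
                           exact_counts = c(65, 24))
  rep <- exclusion_filter(ses)$report
  expect_equal(unname(rep), c(325L, 65L, 24L, 236L))
  expect_equal(sum(rep[c("catch_failed", "incomplete", "valid")]),
               unname(rep["total"]))

  # every session carries exactly four catch outcomes
  expect_true(all(vapply(ses, function(s) length(s$catch_results) == 4L,
                         logical(1))))
})

test_that("exclusion_filter is idempotent, order-invariant, catch-first", {
  st <- small_study()
  ses <- simulate_sessions(st$images, st$cohort, rater_model(),
                           n_sessions = 30, seed = 8,
                           catch_fail_prob = 0.3, incomplete_prob = 0.2)
  f1 <- exclusion_filter(ses)
  f2 <- exclusion_filter(f1$valid)
  expect_identical(f2$valid, f1$valid)
  expect_equal(unname(f2$report["catch_failed"]), 0L)
  shuffled <- exclusion_filter(ses[sample(length(ses))])
  expect_equal(unname(shuffled$report), unname(f1$report))
  expect_equal(sum(f1$report[-1]), unname(f1$report["total"]))

  # a single failed catch trial voids the whole session
  one <- ses[[which(vapply(ses, function(s) all(s$catch_results),
                           logical(1)))[1]]]
  one$catch_results[4] <- FALSE
  expect_equal(unname(exclusion_filter(list(one))$report["valid"]), 0L)

  # empty input: zero counts, no sessions
  f0 <- exclusion_filter(list())
  expect_equal(unname(f0$report), c(0L, 0L, 0L, 0L))
})

test_that("baseline_estimate returns the gendered US averages", {
  expect_equal(unname(baseline_estimate("female")), c(161, 78.7))
  expect_equal(unname(baseline_estimate("male")), c(175, 90.8))
  expect_error(baseline_estimate("unknown"),
               class = "anthropix_config_error")
  # a 161 cm woman is matched exactly by the norm
  expect_equal(unname(baseline_estimate("female")["height_cm"]) - 161, 0)
})

test_that("baseline records are constant within gender across images", {
  st <- small_study()
  est <- baseline_channel(st$images, st$cohort)
  expect_equal(nrow(est), nrow(st$images))
  for (g in c("female", "male")) {
    ids <- st$cohort$participant_id[st$cohort$gender == g]
    sub <- est[est$participant_id %in% ids, ]
    expect_equal(length(unique(sub$height_est_cm)), 1L)
    expect_equal(length(unique(sub$weight_est_kg)), 1L)
  }
})

test_that("ai_channel round-trips jitter-free meshes almost exactly", {
  st <- small_study(n_f = 2, n_m = 2)
  imgs <- st$images[st$images$setting == "wild", ][1:4, ]
  meshes <- lapply(seq_len(nrow(imgs)), function(i) {
    pid <- imgs$participant_id[i]
    k <- match(pid, st$cohort$participant_id)
    list(image_id = imgs$image_id[i], participant_id = pid,
         mesh = generate_body_mesh(st$cohort$true_height_cm[k],
                                   st$cohort$true_weight_kg[k],
                                   st$cohort$gender[k], resolution = 20))
  })
  est <- ai_channel(meshes, st$cohort)
  expect_equal(nrow(est), 4L)
  expect_true(all(est$group == "ai"))
  truth_h <- st$cohort$true_height_cm[match(est$participant_id,
                                            st$cohort$participant_id)]
  truth_w <- st$cohort$true_weight_kg[match(est$participant_id,
                                            st$cohort$participant_id)]
  expect_true(all(abs(est$height_est_cm - truth_h) / truth_h < 0.005))
  expect_true(all(abs(est$weight_est_kg - truth_w) / truth_w < 0.005))
  expect_equal(nrow(ai_channel(list(), st$cohort)), 0L)
})

test_that("IPD jitter inflates AI errors through the scale factor", {
  st <- small_study(n_f = 0, n_m = 6, seed = 2)
  imgs <- st$images[st$images$pose_index == 1 &
                      st$images$setting == "studio_noref", ]
  meshes <- lapply(seq_len(nrow(imgs)), function(i) {
    pid <- imgs$participant_id[i]
    k <- match(pid, st$cohort$participant_id)
    list(image_id = imgs$image_id[i], participant_id = pid,
         mesh = generate_body_mesh(st$cohort$true_height_cm[k],
                                   st$cohort$true_weight_kg[k], "male",
                                   resolution = 16, seed = 1000 + i,
                                   ipd_jitter_sd = 0.34))
  })
  est <- ai_channel(meshes, st$cohort)
  truth_h <- st$cohort$true_height_cm[match(est$participant_id,
                                            st$cohort$participant_id)]
  rel <- est$height_est_cm / truth_h
  # each relative height error equals the IPD ratio 6.40 / ipd_true
  for (i in seq_along(meshes)) {
    ipd_true <- measure_ipd(meshes[[i]]$mesh) * meshes[[i]]$mesh$scale
    expect_equal(rel[i], 6.40 / ipd_true, tolerance = 1e-9)
  }
  expect_gt(stats::sd(rel), 0)
})
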