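# A minimal evoked_set built directly from a feature matrix: one sample,
# so timepoint 1 carries exactly the supplied features.
evoked_from_features <- function(x, ids) {
  arr <- array(0, dim = c(nrow(x), ncol(x), 1))
  arr[, , 1] <- x
  structure(list(subject_id = "synth", evoked = arr, stimulus_ids = ids,
                 times = 0, rate = 256), class = "evoked_set")
}

test_that("a separable two-class problem is classified perfectly", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, mean = 6), 10, 4),
             matrix(rnorm(40, mean = -6), 10, 4))
  ids <- sprintf("s%02d", 1:20)
  labels <- setNames(rep(c("a", "b"), each = 10), ids)
  ev <- evoked_from_features(x, ids)
  split <- list(train_ids = ids[c(1:7, 11:17)], test_ids = ids[c(8:10, 18:20)])
  expect_equal(train_eval_at_timepoint(ev, labels, split, 1), 1.0)
})

test_that("single-class training labels are a degenerate-label error", {
  set.seed(2)
  ids <- sprintf("s%02d", 1:6)
  ev <- evoked_from_features(matrix(rnorm(24), 6, 4), ids)
  labels <- setNames(rep("a", 6), ids)
  expect_error(
    train_eval_at_timepoint(ev, labels, list(train_ids = ids[1:4],
                                             test_ids = ids[5:6]), 1),
    "degenerate")
})

test_that("multiclass one-vs-rest recovers well-separated classes", {
  set.seed(3)
  centers <- diag(4) * 10
  x <- do.call(rbind, lapply(1:4, function(k)
    matrix(rnorm(8 * 4, mean = 0), 8, 4) +
      matrix(centers[k, ], 8, 4, byrow = TRUE)))
  ids <- sprintf("s%02d", 1:32)
  labels <- setNames(rep(letters[1:4], each = 8), ids)
  ev <- evoked_from_features(x, ids)
  test_idx <- c(7, 8, 15, 16, 23, 24, 31, 32)
  split <- list(train_ids = ids[-test_idx], test_ids = ids[test_idx])
  expect_equal(train_eval_at_timepoint(ev, labels, split, 1), 1.0)
})

test_that("accuracy is invariant to a common channel permutation", {
  ev <- fixture_evoked
  labels <- entityeeg:::labels_for_task(fixture_design, "coarse")
  cands <- enumerate_balanced_test_sets(fixture_design)
  split <- list(train_ids = setdiff(names(labels), cands[[1]]$stimulus_ids),
                test_ids = cands[[1]]$stimulus_ids)
  a1 <- train_eval_at_timepoint(ev, labels, split, 30)
  perm <- sample(dim(ev$evoked)[2])
  ev_p <- ev; ev_p$evoked <- ev$evoked[, perm, , drop = FALSE]
  a2 <- train_eval_at_timepoint(ev_p, labels, split, 30)
  expect_equal(a1, a2)
})

test_that("noiseless planted coarse signal gives perfect in-window accuracy
           and chance out-of-window", {
  cfg <- small_config(noise_sd = 0, sigma_fine = 0, sigma_entity = 0)
  ev <- preprocess_subject(
    generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-c"),
    fixture_design)
  cands <- enumerate_balanced_test_sets(fixture_design)
  plan <- select_confound_controlled(cands, fixture_design, n_select = 20)
  times <- ev$times
  idx_in <- window_indices(times, c(200, 700), 64)[1:3]
  tc_in <- time_resolved_classification(ev, fixture_design, "coarse", plan,
                                        timepoints = idx_in)
  expect_true(all(tc_in$accuracies == 1))
  expect_equal(tc_in$chance, 0.5)
  # pre-stimulus samples carry no signal: with zero noise every evoked
  # feature is identical there, so no better-than-chance structure exists
  idx_out <- which(times < 0)[1:2]
  cfg_n <- small_config(noise_sd = 2, sigma_fine = 0, sigma_entity = 0)
  ev_n <- preprocess_subject(
    generate_epoch_dataset(fixture_design, fixture_vectors, cfg_n, "sub-cn"),
    fixture_design)
  tc_out <- time_resolved_classification(ev_n, fixture_design, "coarse", plan,
                                         timepoints = idx_out)
  expect_lt(abs(mean(tc_out$accuracies) - 0.5), 0.2)
})

test_that("task chance levels and output geometry are as designed", {
  cands <- enumerate_within_coarse_test_sets(fixture_design, "person")
  plan <- select_confound_controlled(cands, fixture_design, n_select = 5)
  tc <- time_resolved_classification(fixture_evoked, fixture_design,
                                     "within_people", plan,
                                     timepoints = c(10, 40))
  expect_equal(tc$chance, 0.25)
  expect_equal(dim(tc$accuracies), c(1L, 2L))
  expect_equal(tc$times, fixture_evoked$times[c(10, 40)])
  expect_true(all(tc$accuracies >= 0 & tc$accuracies <= 1))
  expect_equal(entityeeg:::chance_for_task("fine"), 0.125)
})

test_that("transfer succeeds with shared noun templates and collapses to
           chance with decoupled templates", {
  v0 <- generate_entity_vectors(fixture_design, dim = 20, sigma_entity = 0,
                                noun_epsilon_weight = 0, seed = 4)
  cfg_share <- small_config(noise_sd = 0, noun_template_mixing = 1,
                            sigma_entity = 0)
  ev_share <- preprocess_subject(
    generate_epoch_dataset(fixture_design, v0, cfg_share, "sub-t1"),
    fixture_design)
  times <- ev_share$times
  idx_in <- window_indices(times, c(320, 430), 64)[1:2]
  tc <- transfer_classification(ev_share, fixture_design, "fine",
                                timepoints = idx_in)
  expect_true(all(tc$accuracies == 1))
  expect_equal(tc$chance, 0.125)
  expect_equal(tc$times, times[idx_in])

  cfg_split <- small_config(noise_sd = 1, noun_template_mixing = 0)
  ev_split <- preprocess_subject(
    generate_epoch_dataset(fixture_design, fixture_vectors, cfg_split, "sub-t0"),
    fixture_design)
  idx_many <- round(seq(5, length(times) - 2, length.out = 12))
  tc0 <- transfer_classification(ev_split, fixture_design, "fine",
                                 timepoints = idx_many)
  # independent noun templates: accuracy hovers at the 12.5% baseline
  expect_lt(mean(tc0$accuracies), 0.35)
})

test_that("chance calibration: permuted labels on pure-noise features give
           binomial-chance accuracy for binary, 8-class, and 4-class tasks", {
  # fresh noise features per draw keep evaluations independent, so the
  # 3-sd binomial band is the right yardstick; the structurally
  # imbalanced training sets (the held-out classes always have the fewest
  # remaining exemplars) are exactly the regime the squared-hinge
  # formulation must stay calibrated in
  set.seed(77)
  n_draws <- 200L
  run_task <- function(task, cands) {
    labels <- entityeeg:::labels_for_task(fixture_design, task)
    accs <- numeric(n_draws)
    for (i in seq_len(n_draws)) {
      perm_labels <- setNames(sample(unname(labels)), names(labels))
      ev <- evoked_from_features(matrix(rnorm(length(labels) * 128),
                                        length(labels), 128), names(labels))
      cand <- cands[[sample(length(cands), 1)]]
      split <- list(train_ids = setdiff(names(labels), cand$stimulus_ids),
                    test_ids = cand$stimulus_ids)
      accs[i] <- train_eval_at_timepoint(ev, perm_labels, split, 1)
    }
    accs
  }
  cands4 <- enumerate_balanced_test_sets(fixture_design)
  cands2 <- enumerate_within_coarse_test_sets(fixture_design, "person")
  for (setup in list(list(task = "coarse", cands = cands4, chance = 0.5, k = 4),
                     list(task = "fine", cands = cands4, chance = 0.125, k = 4),
                     list(task = "within_people", cands = cands2,
                          chance = 0.25, k = 2))) {
    accs <- run_task(setup$task, setup$cands)
    n_eval <- n_draws * setup$k
    band <- 3 * sqrt(setup$chance * (1 - setup$chance) / n_eval)
    expect_lt(abs(mean(accs) - setup$chance), band,
              label = paste("permuted-label accuracy for", setup$task))
  }
})

test_that("the squared-hinge classifier agrees with a classic-hinge SVM on
           balanced, well-separated data", {
  # dual-route check: on clearly separable balanced problems every sound
  # max-margin linear classifier reaches the same labels
  set.seed(88)
  for (rep in 1:10) {
    x <- rbind(matrix(rnorm(60, mean = 5), 10, 6),
               matrix(rnorm(60, mean = -5), 10, 6))
    y <- factor(rep(c("p", "q"), each = 10))
    xt <- rbind(matrix(rnorm(30, mean = 5), 5, 6),
                matrix(rnorm(30, mean = -5), 5, 6))
    ours <- entityeeg:::svm_predict_labels(x, y, xt, C = 1)
    ref <- as.character(predict(
      e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE), xt))
    expect_equal(ours, ref)
  }
})

test_that("timecourse CSV export is long-format", {
  cands <- enumerate_balanced_test_sets(fixture_design)
  plan <- select_confound_controlled(cands, fixture_design, n_select = 3)
  tc <- time_resolved_classification(fixture_evoked, fixture_design,
                                     "coarse", plan, timepoints = c(20, 30))
  f <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("subject", "time_ms", "accuracy", "task", "chance"))
  expect_equal(nrow(df), 2L)
})
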