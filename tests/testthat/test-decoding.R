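test_that("feature extraction geometry and bijectivity", {
  # 2 channels x 3 in-window samples -> 6 features, channel-major
  arr <- array(0, dim = c(1, 2, 5))
  arr[1, 1, ] <- 1:5
  arr[1, 2, ] <- 101:105
  times <- seq(0, 1000, length.out = 5)  # 250 ms spacing, rate 4 Hz
  ev <- structure(list(subject_id = "f", evoked = arr, stimulus_ids = "s1",
                       times = times, rate = 4), class = "evoked_set")
  sp <- decoder_spec(feature_window = c(250, 750))
  f <- features_from_evoked(ev, sp)
  expect_equal(dim(f), c(1L, 6L))
  expect_equal(unname(f[1, ]), c(2, 3, 4, 102, 103, 104))
  # un-flatten recovers the block
  expect_equal(matrix(f[1, ], nrow = 2, byrow = TRUE),
               arr[1, , 2:4])
})

test_that("default full-size geometry gives 36096 features", {
  times <- epoch_times(c(-100, 1200), 256)
  idx <- window_indices(times, c(100, 1200), 256)
  expect_length(idx, 282L)
  expect_equal(128L * length(idx), 36096L)
})

test_that("pairwise score follows the Spearman-sum inequality", {
  e1 <- c(0.3, 1.7, 0.2, 2.4, 1.1)
  e2 <- c(2.0, 0.1, 1.4, 0.6, 0.9)
  # perfect predictions win; swapped predictions lose
  expect_equal(pairwise_score(e1, e2, e1, e2)$accuracy, 1)
  expect_equal(pairwise_score(e1, e2, e2, e1)$accuracy, 0)
  # hand-computed ranks: matched 1 + 0.5 = 1.5 > mismatched -0.5 - 1
  out <- pairwise_score(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3), c(3, 1, 2))
  expect_equal(out$rho_matched, c(1, 0.5))
  expect_equal(out$rho_mismatched, c(-0.5, -1))
  expect_equal(out$accuracy, 1)
  # ties score one half
  tie <- pairwise_score(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$accuracy, 0.5)
  expect_error(pairwise_score(c(1, 1, 1), e2[1:3], e1[1:3], e2[1:3]),
               "degenerate")
  expect_error(pairwise_score(1:2, 1:2, 1:2, 1:2), ">= 3")
})

test_that("leave-two-out decoding is zero-shot and near-perfect on
           noiseless linear data", {
  cfg <- small_config(noise_sd = 0, sigma_coarse = 0, sigma_fine = 0,
                      sigma_entity = 1)
  ev <- preprocess_subject(
    generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-nl"),
    fixture_design)
  res <- leave_two_out_decoding(ev, fixture_vectors, fixture_design,
                                scope = "entities_only",
                                spec = decoder_spec(alpha = 1e-6))
  expect_equal(nrow(res$outcomes), choose(32, 2))
  expect_gte(res$accuracy, 0.99)
})

test_that("chance calibration: predictions independent of targets score 0.5", {
  set.seed(21)
  accs <- replicate(20, {
    Y <- matrix(rnorm(32 * 50), 32, 50)
    mean(apply(utils::combn(32, 2), 2, function(pr) {
      pairwise_score(Y[pr[1], ], Y[pr[2], ], rnorm(50), rnorm(50))$accuracy
    }))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})

test_that("decoding accuracy degrades monotonically with noise", {
  noise_ladder <- c(0, 1, 5, 20)
  accs <- vapply(noise_ladder, function(ns) {
    cfg <- small_config(sigma_coarse = 0, sigma_fine = 0, sigma_entity = 1,
                        noise_sd = ns)
    ev <- preprocess_subject(
      generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-nm"),
      fixture_design)
    leave_two_out_decoding(ev, fixture_vectors, fixture_design,
                           scope = "entities_only")$accuracy
  }, numeric(1))
  # non-increasing up to one tolerated violation of 0.02
  violations <- diff(accs) > 0.02
  expect_lte(sum(violations), 1L)
  expect_gt(accs[1], accs[length(accs)])
})

test_that("accuracy is invariant under a common permutation of vector
           dimensions", {
  ev <- fixture_evoked
  res1 <- leave_two_out_decoding(ev, fixture_vectors, fixture_design,
                                 scope = "entities_only")
  set.seed(9)
  perm <- sample(fixture_vectors$dim)
  v_perm <- make_vector_set(fixture_vectors$names,
                            fixture_vectors$vectors[, perm])
  res2 <- leave_two_out_decoding(ev, v_perm, fixture_design,
                                 scope = "entities_only")
  expect_equal(res1$accuracy, res2$accuracy)
  expect_equal(res1$outcomes$accuracy, res2$outcomes$accuracy)
})

test_that("pair-type breakdown bins have the combinatorial counts", {
  res <- leave_two_out_decoding(fixture_evoked, fixture_vectors,
                                fixture_design, scope = "all")
  expect_equal(nrow(res$outcomes), choose(40, 2))
  br <- breakdown_by_pair_type(res)
  expect_equal(sum(br$n_pairs), choose(40, 2))
  ee_people <- br$n_pairs[br$ontology == "entity-entity" &
                            br$coarse == "people"]
  expect_equal(ee_people, choose(16, 2))
  cc_mixed <- br$n_pairs[br$ontology == "category-category" &
                           br$coarse == "mixed"]
  expect_equal(cc_mixed, 4L * 4L)
  # per-subject accuracy is the mean of its outcomes
  expect_equal(res$accuracy, mean(res$outcomes$accuracy))
  # tags are symmetric in pair order
  tags_ab <- entityeeg:::pair_tags(fixture_design, "person_musician_1",
                                   "noun_city")
  tags_ba <- entityeeg:::pair_tags(fixture_design, "noun_city",
                                   "person_musician_1")
  expect_equal(tags_ab, tags_ba)
})

test_that("word-length/similarity confound check behaves at the extremes", {
  # cosine constructed to fall with the length gap -> rho = -1
  st <- fixture_design$stimuli
  ids <- st$id[1:10]
  lens <- 3:12
  angles <- (lens - min(lens)) / (max(lens) - min(lens) + 1) * pi / 3
  V <- cbind(cos(angles), sin(angles), matrix(0, 10, 3))
  v_mono <- make_vector_set(ids, V)
  d_sub <- fixture_design
  d_sub$stimuli <- st[1:10, ]
  d_sub$stimuli$word_length <- lens
  rho <- length_similarity_correlation(v_mono, d_sub)
  expect_lt(rho, -0.9)
  # vectors independent of lengths: |rho| small in most seeded replicates
  set.seed(33)
  rhos <- replicate(200, {
    vr <- make_vector_set(st$id, matrix(rnorm(40 * 50), 40, 50))
    length_similarity_correlation(vr, fixture_design)
  })
  expect_gte(mean(abs(rhos) < 0.3), 0.95)
  expect_true(all(rhos >= -1 & rhos <= 1))
})

test_that("decoding CSV export carries pair tags", {
  res <- leave_two_out_decoding(fixture_evoked, fixture_vectors,
                                fixture_design, scope = "entities_only")
  f <- withr::local_tempfile(fileext = ".csv")
  write_decoding_csv(res, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), choose(32, 2))
  expect_true(all(c("subject", "id1", "id2", "ontology", "coarse",
                    "accuracy") %in% names(df)))
})
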