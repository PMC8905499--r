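test_that("entity vectors cover the design with the requested dimension", {
  v <- fixture_vectors
  expect_equal(length(v$names), 40L)
  expect_equal(dim(v$vectors), c(40L, 20L))
  expect_setequal(v$names, fixture_design$stimuli$id)
  expect_error(generate_entity_vectors(fixture_design, dim = 1),
               "dimensionality")
})

test_that("zero entity noise collapses a fine category to one vector", {
  v <- generate_entity_vectors(fixture_design, dim = 10, sigma_entity = 0,
                               seed = 9)
  st <- fixture_design$stimuli
  ids <- st$id[st$fine == "musician" & st$is_entity]
  block <- v$vectors[ids, ]
  expect_true(all(abs(sweep(block, 2, block[1, ])) < 1e-12))
})

test_that("hierarchical scales order the within/between-category cosines", {
  v <- generate_entity_vectors(fixture_design, dim = 50, sigma_coarse = 4,
                               sigma_fine = 1, sigma_entity = 0.25, seed = 5)
  st <- fixture_design$stimuli
  ent <- st[st$is_entity, ]
  cos_groups <- c(within_fine = 0, within_coarse = 0, between = 0)
  counts <- c(0, 0, 0)
  for (i in seq_len(nrow(ent) - 1)) {
    for (j in (i + 1):nrow(ent)) {
      cs <- cosine_similarity(v$vectors[ent$id[i], ], v$vectors[ent$id[j], ])
      g <- if (ent$fine[i] == ent$fine[j]) 1
           else if (ent$coarse[i] == ent$coarse[j]) 2 else 3
      cos_groups[g] <- cos_groups[g] + cs
      counts[g] <- counts[g] + 1
    }
  }
  means <- cos_groups / counts
  expect_true(means["within_fine"] > means["within_coarse"])
  expect_true(means["within_coarse"] > means["between"])
})

test_that("epoch geometry follows the sample-count convention", {
  times <- epoch_times(c(-100, 1200), 256)
  expect_length(times, 333L)
  expect_equal(times[1], -100)
  expect_true(all(diff(times) > 0))
  expect_equal(diff(times)[1], 1000 / 256)

  ds <- generate_epoch_dataset(fixture_design, fixture_vectors,
                               small_config(), "sub-t")
  expect_equal(dim(ds$trials),
               c(40L * 6L, 16L, length(epoch_times(c(-100, 1200), 64))))
  expect_true(all(table(ds$stimulus_ids) == 6L))
  expect_setequal(unique(ds$stimulus_ids), fixture_design$stimuli$id)
})

test_that("zero-noise trials equal their noiseless template in-window", {
  cfg <- small_config(noise_sd = 0)
  tmpl <- make_cohort_templates(fixture_design, fixture_vectors$dim, cfg)
  ds <- generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-z",
                               templates = tmpl)
  times <- ds$times
  st <- fixture_design$stimuli
  sid <- st$id[st$is_entity][1]
  rows <- which(ds$stimulus_ids == sid)
  # all repetitions identical at zero noise
  for (r in rows[-1])
    expect_equal(ds$trials[r, , ], ds$trials[rows[1], , ])
  # inside the entity-only part of the window the trial equals
  # coarse template + entity projection (fine window ends earlier)
  idx_ent <- window_indices(times, cfg$entity_window, cfg$rate)
  idx_fine <- window_indices(times, cfg$fine_window, cfg$rate)
  idx_coarse <- window_indices(times, cfg$coarse_window, cfg$rate)
  probe <- setdiff(intersect(idx_ent, idx_coarse), idx_fine)[1]
  expected <- tmpl$coarse[[st$coarse[match(sid, st$id)]]] +
    drop(tmpl$A %*% fixture_vectors$vectors[sid, ])
  expect_equal(ds$trials[rows[1], , probe], expected, tolerance = 1e-12)
  # outside every window the signal is exactly zero
  pre <- which(times < 0)
  expect_true(all(ds$trials[rows[1], , pre] == 0))
})

test_that("generation is bit-identical under the same seeds", {
  cfg <- small_config()
  d1 <- generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-a")
  d2 <- generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-a")
  expect_identical(d1$trials, d2$trials)
  # a different subject id draws different noise from its derived seed
  d3 <- generate_epoch_dataset(fixture_design, fixture_vectors, cfg, "sub-b")
  expect_false(identical(d1$trials, d3$trials))
})

test_that("cohort subjects share templates up to the configured jitter", {
  cfg <- small_config(noise_sd = 0, subject_jitter_sd = 0)
  co <- generate_cohort(fixture_design, fixture_vectors, cfg, n_subjects = 2)
  # zero jitter + zero noise: identical signal across subjects
  expect_equal(co[[1]]$trials, co[[2]]$trials)
  cfg_j <- small_config(noise_sd = 0, subject_jitter_sd = 0.5)
  co_j <- generate_cohort(fixture_design, fixture_vectors, cfg_j, n_subjects = 2)
  expect_false(identical(co_j[[1]]$trials, co_j[[2]]$trials))
  # jitter perturbs but does not destroy the shared template: signals correlate
  i1 <- as.vector(co_j[[1]]$trials[1, , ]); i2 <- as.vector(co_j[[2]]$trials[1, , ])
  expect_gt(cor(i1, i2), 0.5)
})

test_that("window and dimension misuse are rejected", {
  expect_error(generator_config(fine_window = c(300, 1500)),
               "inside epoch_window")
  v_small <- make_vector_set(fixture_design$stimuli$id,
                             matrix(rnorm(40 * 5), 40, 5))
  tmpl <- make_cohort_templates(fixture_design, 20, small_config())
  expect_error(
    generate_epoch_dataset(fixture_design, v_small, small_config(),
                           templates = tmpl),
    "dimension")
})

test_that("epoch container and vector-set TSV round-trip", {
  dir <- withr::local_tempdir()
  ds <- generate_epoch_dataset(fixture_design, fixture_vectors,
                               small_config(n_repetitions = 2L), "sub-io")
  write_epoch_container(ds, file.path(dir, "epochs"))
  back <- read_epoch_container(file.path(dir, "epochs"))
  expect_equal(back$trials, ds$trials)
  expect_equal(back$stimulus_ids, ds$stimulus_ids)
  expect_equal(back$rate, ds$rate)

  ev <- preprocess_subject(ds, fixture_design)
  write_epoch_container(ev, file.path(dir, "evoked"))
  back_ev <- read_epoch_container(file.path(dir, "evoked"))
  expect_s3_class(back_ev, "evoked_set")
  expect_equal(back_ev$evoked, ev$evoked)

  f <- file.path(dir, "vec.tsv")
  write_vector_set_tsv(fixture_vectors, f)
  v2 <- read_vector_set_tsv(f)
  expect_equal(v2$names, fixture_vectors$names)
  expect_equal(unname(v2$vectors), unname(fixture_vectors$vectors),
               tolerance = 1e-12)
})
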