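# Shared small-scale fixtures, built once per test run. Reduced channel /
# rate / repetition counts keep the suite fast; the full-size defaults are
# exercised where a test is about the default geometry itself.

fixture_design <- build_design(seed = 42)

small_config <- function(...) {
  args <- list(n_channels = 16L, rate = 64, noise_sd = 2,
               n_repetitions = 6L, subject_jitter_sd = 0, seed = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

fixture_vectors <- generate_entity_vectors(fixture_design, dim = 20,
                                           seed = 2L)

# One preprocessed small subject shared by classification/decoding tests.
fixture_evoked <- preprocess_subject(
  generate_epoch_dataset(fixture_design, fixture_vectors, small_config(),
                         subject_id = "sub-01"),
  fixture_design)

# Brute-force adjusted Rand index by literal pair counting: over all item
# pairs, tabulate co-membership in each labeling, then apply the
# chance-corrected agreement formula.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  sum_a <- sum(same_a); sum_b <- sum(same_b)
  n_pairs <- ncol(pairs)
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  # degenerate denominator arises only for two identical trivial partitions
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Brute-force TFCE: for each point and each threshold on the ladder,
# find the run of adjacent suprathreshold points containing it by
# scanning outwards, and accumulate e^E * h^H * dh.
tfce_brute_force <- function(stat, E, H, dh, start, adjacency_ms, times) {
  n <- length(stat)
  out <- numeric(n)
  for (p in seq_len(n)) {
    h <- start + dh
    while (h <= stat[p] + 1e-12) {
      left <- p
      while (left > 1 && stat[left - 1] >= h &&
             times[left] - times[left - 1] <= adjacency_ms + 1e-9) left <- left - 1
      right <- p
      while (right < n && stat[right + 1] >= h &&
             times[right + 1] - times[right] <= adjacency_ms + 1e-9) right <- right + 1
      e <- right - left + 1
      out[p] <- out[p] + e^E * h^H * dh
      h <- h + dh
    }
  }
  out
}
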