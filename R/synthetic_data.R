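#' Synthetic entity vectors with hierarchical category structure
#'
#' Generates one vector per design stimulus as
#' `v(s) = mu_coarse(s) + mu_fine(s) + eps(s)`, where the coarse- and
#' fine-category means are drawn once per category from isotropic normals
#' with scales `sigma_coarse` and `sigma_fine`, and `eps` is a per-entity
#' isotropic normal with scale `sigma_entity`. Category-noun vectors are
#' the fine-category mean plus an independent `eps` scaled by
#' `noun_epsilon_weight`. With `sigma_coarse >> sigma_fine >> sigma_entity`
#' the vectors cluster by category: mean within-fine-category cosine >
#' mean within-coarse > mean between-coarse, emulating the categorical
#' structure that distributional word vectors of people and places exhibit.
#'
#' @param design a `stimulus_design`.
#' @param dim vector dimensionality (>= 2; default 50).
#' @param sigma_coarse,sigma_fine,sigma_entity effect scales (>= 0;
#'   defaults 1, 0.5, 0.25).
#' @param noun_epsilon_weight scale multiplier on the category nouns'
#'   independent noise component (default 1).
#' @param seed integer seed.
#' @return a `vector_set`: list with `names` (stimulus ids), `vectors`
#'   (n_stimuli x dim matrix with ids as rownames), `dim`.
#' @export
generate_entity_vectors <- function(design, dim = 50L, sigma_coarse = 1,
                                    sigma_fine = 0.5, sigma_entity = 0.25,
                                    noun_epsilon_weight = 1, seed = 1L) {
  validate_design(design)
  if (dim < 2L) stop("vector dimensionality must be >= 2")
  if (any(c(sigma_coarse, sigma_fine, sigma_entity) < 0))
    stop("effect scales must be >= 0")
  st <- design$stimuli
  vectors <- with_seed(seed, {
    mu_coarse <- lapply(stats::setNames(design$coarse_categories,
                                        design$coarse_categories),
                        function(co) stats::rnorm(dim, 0, sigma_coarse))
    all_fine <- unlist(design$fine_categories, use.names = FALSE)
    mu_fine <- lapply(stats::setNames(all_fine, all_fine),
                      function(fi) stats::rnorm(dim, 0, sigma_fine))
    v <- matrix(0, nrow(st), dim, dimnames = list(st$id, NULL))
    for (i in seq_len(nrow(st))) {
      eps_scale <- if (st$is_entity[i]) sigma_entity
                   else sigma_entity * noun_epsilon_weight
      v[i, ] <- mu_coarse[[st$coarse[i]]] + mu_fine[[st$fine[i]]] +
        stats::rnorm(dim, 0, eps_scale)
    }
    v
  })
  make_vector_set(st$id, vectors)
}

#' Construct a vector set
#' @param names stimulus ids (one per row of `vectors`).
#' @param vectors numeric matrix, n_stimuli x dim.
#' @return a `vector_set`.
#' @export
make_vector_set <- function(names, vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(length(names) == nrow(vectors))
  rownames(vectors) <- names
  structure(list(names = names, vectors = vectors, dim = ncol(vectors)),
            class = "vector_set")
}

#' Configuration for the synthetic evoked-response generator
#'
#' The defaults emulate the recording setup of a 128-channel EEG study
#' sampled at 256 Hz with epochs from -100 to 1200 ms around word onset and
#' 24 repetitions per stimulus. Signal windows (ms after onset) hold the
#' planted effects: a coarse-category component at 150-800 ms, a
#' fine-category component at 300-450 ms and an entity component (a linear
#' image of the stimulus's vector) at 300-1100 ms; all indicators are
#' boxcars. `noise_sd` is the sd of i.i.d. Gaussian sample noise on single
#' trials; the default 5 makes single-trial signal-to-noise low (as in raw
#' EEG) while 24-trial averaging recovers the planted effects.
#'
#' @param n_channels number of channels (default 128).
#' @param rate sampling rate in Hz (default 256).
#' @param epoch_window epoch in ms (default c(-100, 1200)).
#' @param coarse_window,fine_window,entity_window signal windows in ms.
#' @param sigma_coarse,sigma_fine template amplitude scales (defaults 1, 0.7).
#' @param sigma_entity scale of the entity forward map (default 0.5).
#' @param noise_sd trial noise sd (default 5).
#' @param n_repetitions trials per stimulus (default 24).
#' @param noun_template_mixing in \[0, 1\]: 1 means category nouns evoke the
#'   same category templates as entities; 0 gives nouns independent
#'   templates of the same scale (emulating representations that do not
#'   transfer between proper names and category nouns).
#' @param subject_jitter_sd sd of between-subject template jitter (default 0.2).
#' @param seed integer seed for cohort-level draws; subject-level noise uses
#'   seeds derived from it (documented in the methods vignette).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_channels = 128L, rate = 256, epoch_window = c(-100, 1200),
                             coarse_window = c(150, 800), fine_window = c(300, 450),
                             entity_window = c(300, 1100), sigma_coarse = 1,
                             sigma_fine = 0.7, sigma_entity = 0.5, noise_sd = 5,
                             n_repetitions = 24L, noun_template_mixing = 1,
                             subject_jitter_sd = 0.2, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), rate = rate,
              epoch_window = epoch_window, coarse_window = coarse_window,
              fine_window = fine_window, entity_window = entity_window,
              sigma_coarse = sigma_coarse, sigma_fine = sigma_fine,
              sigma_entity = sigma_entity, noise_sd = noise_sd,
              n_repetitions = as.integer(n_repetitions),
              noun_template_mixing = noun_template_mixing,
              subject_jitter_sd = subject_jitter_sd, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$rate <= 0) stop("rate must be > 0")
  if (cfg$n_repetitions < 1L) stop("n_repetitions must be >= 1")
  for (w in c("coarse_window", "fine_window", "entity_window")) {
    win <- cfg[[w]]
    if (win[1] < cfg$epoch_window[1] || win[2] > cfg$epoch_window[2])
      stop(w, " must lie inside epoch_window")
  }
  invisible(cfg)
}

#' Cohort-level forward model: category templates and the entity map
#'
#' Draws the deterministic part of the generative model shared by all
#' subjects of a cohort: one channel template per coarse category (scale
#' `sigma_coarse`), one per fine category (scale `sigma_fine`),
#' independent noun templates of the same scales (mixed in by
#' `1 - noun_template_mixing`), and the channels x dim forward map `A`
#' through which a stimulus's entity vector projects into channel space
#' (entries N(0, sigma_entity / sqrt(dim)), so the entity component's scale
#' is roughly `sigma_entity * |v|`).
#'
#' @param design a `stimulus_design`.
#' @param dim entity-vector dimensionality.
#' @param config a `generator_config`; templates are drawn with
#'   `config$seed`.
#' @return a `cohort_templates` list.
#' @export
make_cohort_templates <- function(design, dim, config) {
  validate_design(design)
  with_seed(child_seed(config$seed, 101L), {
    nc <- config$n_channels
    all_fine <- unlist(design$fine_categories, use.names = FALSE)
    tmpl <- list(
      coarse = lapply(stats::setNames(design$coarse_categories,
                                      design$coarse_categories),
                      function(co) stats::rnorm(nc, 0, config$sigma_coarse)),
      fine = lapply(stats::setNames(all_fine, all_fine),
                    function(fi) stats::rnorm(nc, 0, config$sigma_fine)),
      noun_coarse = lapply(stats::setNames(design$coarse_categories,
                                           design$coarse_categories),
                           function(co) stats::rnorm(nc, 0, config$sigma_coarse)),
      noun_fine = lapply(stats::setNames(all_fine, all_fine),
                         function(fi) stats::rnorm(nc, 0, config$sigma_fine)),
      A = matrix(stats::rnorm(nc * dim, 0, config$sigma_entity / sqrt(dim)),
                 nc, dim))
    class(tmpl) <- "cohort_templates"
    tmpl
  })
}

#' Generate one subject's synthetic epoch dataset
#'
#' Single-trial forward model: for stimulus s,
#' `trial(s) = T_coarse(s) * 1[coarse_window] + T_fine(s) * 1[fine_window]
#'  + (A v(s)) * 1[entity_window] + noise`, with boxcar window indicators
#' (see [window_indices()]) and i.i.d. Gaussian sample noise of sd
#' `config$noise_sd`. Category nouns use
#' `m * T_cat + (1 - m) * T_cat_independent` with
#' `m = config$noun_template_mixing` and their own (noun) vectors through
#' `A`. Each stimulus contributes `config$n_repetitions` trials.
#' Between-subject variability adds N(0, subject_jitter_sd) channel jitter
#' to each template, drawn from the subject's seed.
#'
#' @param design a `stimulus_design`.
#' @param vectors a `vector_set` covering all design stimuli.
#' @param config a `generator_config`.
#' @param subject_id subject label.
#' @param templates optional `cohort_templates` (made from `config$seed`
#'   when omitted) so several subjects can share one forward model.
#' @param subject_seed integer seed for this subject's jitter and noise;
#'   defaults to a seed derived from `config$seed` and the subject id.
#' @return an `epoch_dataset`: list with `subject_id`, `trials`
#'   (n_trials x n_channels x n_samples array), `times` (ms),
#'   `stimulus_ids` (per trial), `rate`.
#' @export
generate_epoch_dataset <- function(design, vectors, config,
                                   subject_id = "sub-01", templates = NULL,
                                   subject_seed = NULL) {
  validate_design(design)
  st <- design$stimuli
  if (!all(st$id %in% vectors$names))
    stop("vector set does not cover all design stimuli")
  if (is.null(templates)) templates <- make_cohort_templates(design, vectors$dim, config)
  if (ncol(templates$A) != vectors$dim)
    stop("forward map dimension (", ncol(templates$A),
         ") does not match vector dimension (", vectors$dim, ")")
  if (is.null(subject_seed))
    subject_seed <- child_seed(config$seed,
                               200L + sum(utf8ToInt(as.character(subject_id))))

  times <- epoch_times(config$epoch_window, config$rate)
  n_samp <- length(times)
  nc <- config$n_channels
  idx_coarse <- window_indices(times, config$coarse_window, config$rate)
  idx_fine <- window_indices(times, config$fine_window, config$rate)
  idx_entity <- window_indices(times, config$entity_window, config$rate)

  n_rep <- config$n_repetitions
  n_trials <- nrow(st) * n_rep
  stimulus_ids <- rep(st$id, each = n_rep)

  with_seed(subject_seed, {
    jitter <- function(v) v + stats::rnorm(length(v), 0, config$subject_jitter_sd)
    m <- config$noun_template_mixing
    # per-stimulus noiseless template, channels x samples
    stim_template <- lapply(seq_len(nrow(st)), function(i) {
      tc <- if (st$is_entity[i]) templates$coarse[[st$coarse[i]]]
            else m * templates$coarse[[st$coarse[i]]] +
                 (1 - m) * templates$noun_coarse[[st$coarse[i]]]
      tf <- if (st$is_entity[i]) templates$fine[[st$fine[i]]]
            else m * templates$fine[[st$fine[i]]] +
                 (1 - m) * templates$noun_fine[[st$fine[i]]]
      ent <- drop(templates$A %*% vectors$vectors[st$id[i], ])
      tmpl <- matrix(0, nc, n_samp)
      tmpl[, idx_coarse] <- tmpl[, idx_coarse] + jitter(tc)
      tmpl[, idx_fine] <- tmpl[, idx_fine] + jitter(tf)
      tmpl[, idx_entity] <- tmpl[, idx_entity] + jitter(ent)
      tmpl
    })
    trials <- array(stats::rnorm(n_trials * nc * n_samp, 0, config$noise_sd),
                    dim = c(n_trials, nc, n_samp))
    for (i in seq_len(nrow(st))) {
      rows <- (i - 1L) * n_rep + seq_len(n_rep)
      for (r in rows) trials[r, , ] <- trials[r, , ] + stim_template[[i]]
    }
    structure(list(subject_id = subject_id, trials = trials, times = times,
                   stimulus_ids = stimulus_ids, rate = config$rate),
              class = "epoch_dataset")
  })
}

#' Generate a cohort of subjects sharing one forward model
#'
#' Cohort-level objects (category templates and the entity forward map) are
#' drawn once from `config$seed`; each subject then gets its own template
#' jitter and trial noise from a derived per-subject seed, so repeated
#' calls are reproducible and subjects share signal structure up to the
#' configured jitter.
#'
#' @param design a `stimulus_design`.
#' @param vectors a `vector_set`.
#' @param config a `generator_config`.
#' @param n_subjects number of subjects.
#' @return list of `epoch_dataset`, one per subject.
#' @export
generate_cohort <- function(design, vectors, config, n_subjects = 10L) {
  templates <- make_cohort_templates(design, vectors$dim, config)
  lapply(seq_len(n_subjects), function(i) {
    generate_epoch_dataset(design, vectors, config,
                           subject_id = sprintf("sub-%02d", i),
                           templates = templates,
                           subject_seed = child_seed(config$seed, 1000L + i))
  })
}

#' Read / write epoch containers and vector sets
#'
#' Epoch datasets (and evoked sets) are stored as a documented on-disk
#' container: a directory holding `meta.json` (subject id, rate, times,
#' stimulus ids, array dimensions) and `trials.bin` / `evoked.bin`, the
#' data array as little-endian float64 in trial-major, then channel-major,
#' then sample order. Vector sets are TSV with an `id` column followed by
#' `d1 ... dk` dimension columns.
#'
#' @param dataset an `epoch_dataset` or `evoked_set`; `vs` a `vector_set`.
#' @param path directory (containers) or file path (TSV).
#' @name containers
NULL

#' @rdname containers
#' @export
write_epoch_container <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  is_evoked <- inherits(dataset, "evoked_set")
  arr <- if (is_evoked) dataset$evoked else dataset$trials
  meta <- list(kind = if (is_evoked) "evoked_set" else "epoch_dataset",
               subject_id = dataset$subject_id, rate = dataset$rate,
               times = dataset$times, stimulus_ids = dataset$stimulus_ids,
               dim = dim(arr))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, if (is_evoked) "evoked.bin" else "trials.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(arr, c(3, 2, 1))), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname containers
#' @export
read_epoch_container <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  bin <- file.path(path, if (meta$kind == "evoked_set") "evoked.bin" else "trials.bin")
  n <- prod(meta$dim)
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  arr <- aperm(array(x, dim = rev(meta$dim)), c(3, 2, 1))
  if (meta$kind == "evoked_set") {
    structure(list(subject_id = meta$subject_id, evoked = arr,
                   stimulus_ids = meta$stimulus_ids, times = meta$times,
                   rate = meta$rate), class = "evoked_set")
  } else {
    structure(list(subject_id = meta$subject_id, trials = arr,
                   times = meta$times, stimulus_ids = meta$stimulus_ids,
                   rate = meta$rate), class = "epoch_dataset")
  }
}

#' @rdname containers
#' @export
write_vector_set_tsv <- function(vs, path) {
  df <- data.frame(id = vs$names, vs$vectors, check.names = FALSE)
  names(df) <- c("id", paste0("d", seq_len(vs$dim)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname containers
#' @export
read_vector_set_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  make_vector_set(df$id, as.matrix(df[, -1, drop = FALSE]))
}

#' @export
print.epoch_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat("Epoch dataset ", x$subject_id, ": ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples (", x$rate, " Hz, ",
      round(x$times[1]), "...", round(x$times[length(x$times)]), " ms)\n", sep = "")
  invisible(x)
}
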