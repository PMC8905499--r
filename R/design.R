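#' Hierarchical stimulus design
#'
#' The stimulus set is organised symmetrically: 2 coarse categories (people
#' and places), 4 fine-grained categories nested under each, 4 individual
#' entities per fine-grained category, plus one category-noun stimulus per
#' fine-grained category — 40 stimuli in total, 32 proper names and 8 nouns.
#'
#' `build_design()` returns a `stimulus_design` object: a list with
#' `stimuli` (a data frame with one row per stimulus), `coarse_categories`
#' and `fine_categories`. Columns of `stimuli`:
#' `id`, `surface_form`, `coarse` ("person"/"place"), `fine`, `is_entity`,
#' `word_length` (characters), `familiarity` (1-5 scale, pass-through
#' metadata).
#'
#' When no stimulus list is supplied, placeholder surface forms are
#' synthesized as pronounceable random strings whose lengths are drawn from
#' per-coarse-category normal distributions (sd 2, truncated at 3
#' characters) around configurable means — by default 12 characters for
#' people and 9 for places, matching the average-length asymmetry between
#' people's full names and place names that the word-length confound
#' control exists to handle. Category nouns use their category name as
#' surface form.
#'
#' @param entity_names optional named list: for each fine category, a
#'   character vector of 4 entity surface forms. Names must be the 8 fine
#'   category names.
#' @param lengths optional named numeric, mean placeholder name length per
#'   coarse category (defaults `c(person = 12, place = 9)`).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return a `stimulus_design` object.
#' @export
build_design <- function(entity_names = NULL, lengths = NULL, seed = 1L) {
  coarse_categories <- c("person", "place")
  fine_categories <- list(
    person = c("politician", "musician", "writer", "actor"),
    place  = c("city", "country", "monument", "river")
  )
  mean_len <- c(person = 12, place = 9)
  if (!is.null(lengths)) {
    if (!all(coarse_categories %in% names(lengths)))
      stop("`lengths` must be named with both coarse categories")
    mean_len[names(lengths)] <- lengths
  }

  all_fine <- unlist(fine_categories, use.names = FALSE)
  if (!is.null(entity_names)) {
    if (!setequal(names(entity_names), all_fine))
      stop("`entity_names` must name exactly the 8 fine categories; got: ",
           paste(names(entity_names), collapse = ", "))
    bad <- names(entity_names)[vapply(entity_names, length, 1L) != 4L]
    if (length(bad))
      stop("`entity_names` must give exactly 4 entities per fine category; ",
           "violated for: ", paste(bad, collapse = ", "))
  }

  rows <- with_seed(seed, {
    out <- list()
    for (co in coarse_categories) {
      for (fi in fine_categories[[co]]) {
        forms <- if (!is.null(entity_names)) entity_names[[fi]]
                 else random_names(4L, mean_len[[co]])
        for (k in seq_len(4L)) {
          out[[length(out) + 1L]] <- data.frame(
            id = sprintf("%s_%s_%d", co, fi, k),
            surface_form = forms[k], coarse = co, fine = fi,
            is_entity = TRUE, word_length = nchar(forms[k]),
            familiarity = round(stats::runif(1, 3, 5), 2),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (co in coarse_categories) {
      for (fi in fine_categories[[co]]) {
        out[[length(out) + 1L]] <- data.frame(
          id = sprintf("noun_%s", fi), surface_form = fi, coarse = co,
          fine = fi, is_entity = FALSE, word_length = nchar(fi),
          familiarity = round(stats::runif(1, 3, 5), 2),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })

  design <- structure(
    list(stimuli = rows, coarse_categories = coarse_categories,
         fine_categories = fine_categories),
    class = "stimulus_design")
  validate_design(design)
  design
}

# Pronounceable placeholder strings: alternating consonant/vowel, lengths
# drawn normal(mean, sd = 2) truncated below at 3 characters.
random_names <- function(n, mean_length) {
  consonants <- strsplit("bcdfglmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- max(3L, round(stats::rnorm(1, mean_length, 2)))
    chars <- character(len)
    for (j in seq_len(len)) {
      chars[j] <- if (j %% 2 == 1) sample(consonants, 1) else sample(vowels, 1)
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Validate the structural invariants of a stimulus design
#'
#' Checks the 2 x 4 x 4 (+8 nouns) structure: 40 stimuli, 32 entities,
#' exactly 4 entities and 1 category noun per fine category, word lengths
#' >= 1, noun surface forms equal to their category name.
#'
#' @param design a `stimulus_design`.
#' @return `design`, invisibly; errors name the violated constraint.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "stimulus_design")) stop("not a stimulus_design")
  st <- design$stimuli
  if (nrow(st) != 40L) stop("design must contain exactly 40 stimuli, got ", nrow(st))
  if (anyDuplicated(st$id)) stop("stimulus ids must be distinct")
  if (sum(st$is_entity) != 32L)
    stop("design must contain exactly 32 entities, got ", sum(st$is_entity))
  for (fi in unlist(design$fine_categories)) {
    ne <- sum(st$fine == fi & st$is_entity)
    nn <- sum(st$fine == fi & !st$is_entity)
    if (ne != 4L) stop("fine category '", fi, "' must have 4 entities, got ", ne)
    if (nn != 1L) stop("fine category '", fi, "' must have 1 category noun, got ", nn)
  }
  if (any(st$word_length < 1L)) stop("word_length must be >= 1")
  nouns <- st[!st$is_entity, ]
  if (!all(nouns$surface_form == nouns$fine))
    stop("category-noun surface forms must equal their fine category name")
  invisible(design)
}

#' Randomized session schedule with balanced question types
#'
#' Builds a session of `n_runs` runs of 40 trials. In each run every
#' stimulus appears exactly once in randomized order, and each trial is
#' followed by a question: 16 coarse-level questions ("person or place?")
#' and 24 fine-level questions per run, of which 12 expect the answer
#' "correct" (the probed category is the stimulus's own) and 12 expect
#' "wrong" (a different fine category is probed). The question multiset is
#' fixed per run and assigned to trials by a uniform shuffle.
#'
#' @param design a `stimulus_design`.
#' @param n_runs number of runs (default 24, giving 24 evoked responses per
#'   stimulus over the session).
#' @param n_coarse_questions,n_fine_questions,n_fine_correct per-run
#'   question quotas (defaults 16, 24, 12).
#' @param seed integer seed.
#' @return a `trial_schedule`: list with `runs`, a list of data frames with
#'   columns `run, trial_index, stimulus_id, question_kind,
#'   probed_category, expected_answer`.
#' @export
generate_schedule <- function(design, n_runs = 24L, seed = 1L,
                              n_coarse_questions = 16L,
                              n_fine_questions = 24L,
                              n_fine_correct = 12L) {
  validate_design(design)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  n_trials <- nrow(design$stimuli)
  if (n_coarse_questions + n_fine_questions != n_trials)
    stop("question quotas infeasible: ", n_coarse_questions, " coarse + ",
         n_fine_questions, " fine != ", n_trials, " trials per run")
  if (n_fine_correct > n_fine_questions)
    stop("question quotas infeasible: more 'correct' fine questions than fine questions")

  st <- design$stimuli
  all_fine <- unlist(design$fine_categories, use.names = FALSE)
  runs <- with_seed(seed, lapply(seq_len(n_runs), function(r) {
    order_ids <- sample(st$id)
    kinds <- sample(c(rep("coarse", n_coarse_questions),
                      rep("fine_correct", n_fine_correct),
                      rep("fine_wrong", n_fine_questions - n_fine_correct)))
    probed <- character(n_trials); expected <- rep(NA_character_, n_trials)
    for (i in seq_len(n_trials)) {
      fine_i <- st$fine[match(order_ids[i], st$id)]
      if (kinds[i] == "coarse") {
        probed[i] <- NA_character_
      } else if (kinds[i] == "fine_correct") {
        probed[i] <- fine_i; expected[i] <- "correct"
      } else {
        probed[i] <- sample(setdiff(all_fine, fine_i), 1); expected[i] <- "wrong"
      }
    }
    data.frame(run = r, trial_index = seq_len(n_trials),
               stimulus_id = order_ids,
               question_kind = ifelse(kinds == "coarse", "coarse", "fine"),
               probed_category = probed, expected_answer = expected,
               stringsAsFactors = FALSE)
  }))
  sched <- structure(list(runs = runs, design = design), class = "trial_schedule")
  validate_schedule(sched)
  sched
}

#' Validate a trial schedule by re-counting all quotas
#'
#' Re-counts, per run: 40 trials, each stimulus exactly once, 16 coarse and
#' 24 fine questions of which 12 expect "correct"; and per session: one
#' presentation of every stimulus per run.
#'
#' @param schedule a `trial_schedule`.
#' @param n_coarse_questions,n_fine_questions,n_fine_correct expected quotas.
#' @return `schedule`, invisibly; errors name the violated count.
#' @export
validate_schedule <- function(schedule, n_coarse_questions = 16L,
                              n_fine_questions = 24L, n_fine_correct = 12L) {
  if (!inherits(schedule, "trial_schedule")) stop("not a trial_schedule")
  ids <- schedule$design$stimuli$id
  for (run in schedule$runs) {
    r <- run$run[1]
    if (!setequal(run$stimulus_id, ids) || nrow(run) != length(ids))
      stop("run ", r, ": each stimulus must appear exactly once")
    n_coarse <- sum(run$question_kind == "coarse")
    n_fine <- sum(run$question_kind == "fine")
    n_corr <- sum(run$expected_answer == "correct", na.rm = TRUE)
    if (n_coarse != n_coarse_questions)
      stop("run ", r, ": expected ", n_coarse_questions, " coarse questions, got ", n_coarse)
    if (n_fine != n_fine_questions)
      stop("run ", r, ": expected ", n_fine_questions, " fine questions, got ", n_fine)
    if (n_corr != n_fine_correct)
      stop("run ", r, ": expected ", n_fine_correct, " 'correct' fine questions, got ", n_corr)
  }
  invisible(schedule)
}

#' Flatten a schedule to one long data frame
#' @param schedule a `trial_schedule`.
#' @return data frame with one row per trial across all runs.
#' @export
schedule_table <- function(schedule) {
  do.call(rbind, schedule$runs)
}

#' Read / write stimulus tables and schedules as TSV
#'
#' The stimulus table format has columns
#' `id, surface_form, coarse, fine, is_entity, word_length, familiarity`;
#' the schedule export has columns
#' `run, trial_index, stimulus_id, question_kind, probed_category,
#' expected_answer`.
#'
#' @param design a `stimulus_design`; `schedule` a `trial_schedule`.
#' @param path file path.
#' @name design_io
NULL

#' @rdname design_io
#' @export
write_design_tsv <- function(design, path) {
  validate_design(design)
  utils::write.table(design$stimuli, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname design_io
#' @export
read_design_tsv <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "surface_form", "coarse", "fine", "is_entity", "word_length")
  missing_cols <- setdiff(need, names(st))
  if (length(missing_cols))
    stop("stimulus table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"familiarity" %in% names(st)) st$familiarity <- NA_real_
  st$is_entity <- as.logical(st$is_entity)
  coarse_categories <- sort(unique(st$coarse))
  fine_categories <- lapply(coarse_categories,
                            function(co) unique(st$fine[st$coarse == co]))
  names(fine_categories) <- coarse_categories
  design <- structure(
    list(stimuli = st, coarse_categories = coarse_categories,
         fine_categories = fine_categories),
    class = "stimulus_design")
  validate_design(design)
  design
}

#' @rdname design_io
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule_table(schedule), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("Stimulus design: ", nrow(x$stimuli), " stimuli (",
      sum(x$stimuli$is_entity), " entities, ",
      sum(!x$stimuli$is_entity), " category nouns)\n", sep = "")
  cat("Coarse categories:", paste(x$coarse_categories, collapse = ", "), "\n")
  for (co in x$coarse_categories)
    cat("  ", co, ": ", paste(x$fine_categories[[co]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.trial_schedule <- function(x, ...) {
  tab <- schedule_table(x)
  cat("Trial schedule: ", length(x$runs), " runs x ", nrow(x$runs[[1]]),
      " trials = ", nrow(tab), " trials\n", sep = "")
  invisible(x)
}
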