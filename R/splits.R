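#' Enumerate balanced leave-4-out candidate test sets
#'
#' All 4-entity subsets that are balanced across coarse categories (two
#' people, two places) and contain at most one exemplar per fine-grained
#' category. For the 2 x 4 x 4 design this gives
#' C(4,2) * 4^2 people-halves times the same for places = 96 * 96 = 9216
#' candidates, each leaving 28/32 = 87.5% of entities for training.
#' Candidates are returned in deterministic lexicographic order (by fine
#' category pair, then entity within category).
#'
#' @param design a `stimulus_design`.
#' @return list of candidate test sets, each a list with `stimulus_ids`
#'   (4 ids) and `rho` (NA until scored by [select_confound_controlled()]).
#' @export
enumerate_balanced_test_sets <- function(design) {
  validate_design(design)
  halves <- lapply(design$coarse_categories, function(co)
    within_coarse_pairs(design, co))
  out <- vector("list", length(halves[[1]]) * length(halves[[2]]))
  k <- 0L
  for (p in halves[[1]]) {
    for (q in halves[[2]]) {
      k <- k + 1L
      out[[k]] <- list(stimulus_ids = c(p, q), rho = NA_real_)
    }
  }
  out
}

# All 2-entity combinations within one coarse category whose members come
# from distinct fine categories, lexicographic by category pair then entity.
within_coarse_pairs <- function(design, coarse) {
  st <- design$stimuli
  fines <- design$fine_categories[[coarse]]
  ids_by_fine <- lapply(fines, function(fi)
    st$id[st$fine == fi & st$is_entity])
  out <- list()
  for (a in seq_along(fines)) {
    for (b in seq_along(fines)) {
      if (b <= a) next
      for (ia in ids_by_fine[[a]]) {
        for (ib in ids_by_fine[[b]]) {
          out[[length(out) + 1L]] <- c(ia, ib)
        }
      }
    }
  }
  out
}

#' Enumerate within-coarse leave-2-out candidate test sets
#'
#' All 2-element subsets of the 16 entities of one coarse category whose
#' members belong to different fine categories: C(4,2) * 4 * 4 = 96
#' candidates, each a 14/16 = 87.5% train - 12.5% test split.
#'
#' @param design a `stimulus_design`.
#' @param coarse `"person"` or `"place"`.
#' @return list of candidates as in [enumerate_balanced_test_sets()].
#' @export
enumerate_within_coarse_test_sets <- function(design, coarse) {
  validate_design(design)
  if (!coarse %in% design$coarse_categories)
    stop("unknown coarse category: ", coarse)
  lapply(within_coarse_pairs(design, coarse),
         function(p) list(stimulus_ids = p, rho = NA_real_))
}

#' Select confound-controlled splits by word-length correlation
#'
#' Implements word-length confound control over candidate test sets: each
#' test stimulus is encoded as its character length and its target label as
#' the mean character length of that label's entities; the Spearman
#' correlation rho between the two encodings quantifies how much word
#' length alone could drive classification on that test set. Candidates
#' are sorted ascending by |rho| (stable sort, ties broken by candidate
#' order; rho of a constant encoding is defined as 0) and the `n_select`
#' least-confounded become the final train/test splits, training on all
#' remaining eligible entities.
#'
#' @param candidates list of candidates from an enumerator.
#' @param design a `stimulus_design`.
#' @param n_select number of splits to retain (default 50).
#' @param label which target labels the classifier will use: `"fine"`
#'   (default) or `"coarse"`.
#' @param scope entity pool forming train = scope minus test. Defaults to
#'   all 32 entities; within-coarse enumerations restrict it automatically
#'   to the candidates' coarse category.
#' @return a `split_plan`: list with `scheme`, `splits` (each
#'   `list(train_ids, test_ids, rho)`), ordered by ascending |rho|.
#' @export
select_confound_controlled <- function(candidates, design, n_select = 50L,
                                       label = c("fine", "coarse"),
                                       scope = NULL) {
  label <- match.arg(label)
  if (n_select > length(candidates))
    stop("n_select (", n_select, ") exceeds number of candidates (",
         length(candidates), ")")
  st <- design$stimuli
  if (is.null(st$word_length)) stop("design lacks word lengths")
  ent <- st[st$is_entity, ]
  label_of <- stats::setNames(ent[[label]], ent$id)
  # label encoding: mean word length of the label's entities
  label_len <- tapply(ent$word_length, ent[[label]], mean)
  stim_len <- stats::setNames(st$word_length, st$id)

  rho <- vapply(candidates, function(cand) {
    ids <- cand$stimulus_ids
    spearman_rho(stim_len[ids], label_len[label_of[ids]])
  }, numeric(1))

  ord <- order(abs(rho))  # stable: ties keep canonical candidate order
  keep <- ord[seq_len(n_select)]

  if (is.null(scope)) {
    used_coarse <- unique(ent$coarse[match(
      unlist(lapply(candidates, `[[`, "stimulus_ids")), ent$id)])
    scope <- ent$id[ent$coarse %in% used_coarse]
  }
  splits <- lapply(keep, function(i) {
    test_ids <- candidates[[i]]$stimulus_ids
    list(train_ids = setdiff(scope, test_ids), test_ids = test_ids,
         rho = rho[i])
  })
  scheme <- if (length(candidates[[1]]$stimulus_ids) == 4L) "leave4_balanced"
            else "leave2_within_coarse"
  structure(list(scheme = scheme, splits = splits), class = "split_plan")
}

#' Export a split plan as JSON
#' @param plan a `split_plan`.
#' @param path output file.
#' @export
write_split_plan_json <- function(plan, path) {
  jsonlite::write_json(
    list(scheme = plan$scheme,
         splits = lapply(plan$splits, function(s)
           list(train_ids = s$train_ids, test_ids = s$test_ids, rho = s$rho))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.split_plan <- function(x, ...) {
  rhos <- vapply(x$splits, `[[`, numeric(1), "rho")
  cat("Split plan (", x$scheme, "): ", length(x$splits), " splits, max |rho| = ",
      signif(max(abs(rhos)), 3), "\n", sep = "")
  invisible(x)
}
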