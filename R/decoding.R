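#' Decoder specification for zero-shot ridge decoding
#'
#' Ridge regression with default regularization alpha = 1 maps whole-epoch
#' EEG features to entity-vector dimensions. Features are the channels x
#' in-window samples block of each evoked response, collapsed to one
#' vector; the default window 100-1200 ms drops the pre-stimulus and
#' earliest visual interval.
#'
#' @param alpha ridge penalty (> 0, default 1).
#' @param feature_window ms window collapsed into the feature vector
#'   (default c(100, 1200)).
#' @return a `decoder_spec`.
#' @export
decoder_spec <- function(alpha = 1.0, feature_window = c(100, 1200)) {
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(alpha = alpha, feature_window = feature_window),
            class = "decoder_spec")
}

#' Collapse evoked responses to whole-epoch feature vectors
#'
#' Per stimulus, the n_channels x n_inwindow_samples block is flattened
#' channel-major (all in-window samples of channel 1, then channel 2, ...).
#' With 128 channels and 282 in-window samples (100-1200 ms at 256 Hz
#' under the package's index convention, see [window_indices()]) the
#' feature length is 36096.
#'
#' @param evoked an `evoked_set`.
#' @param spec a `decoder_spec`.
#' @return numeric matrix n_stimuli x n_features, stimulus ids as rownames.
#' @export
features_from_evoked <- function(evoked, spec = decoder_spec()) {
  stopifnot(inherits(evoked, "evoked_set"))
  idx <- window_indices(evoked$times, spec$feature_window, evoked$rate)
  if (length(idx) == 0) stop("empty feature window")
  n_stim <- dim(evoked$evoked)[1]
  out <- t(vapply(seq_len(n_stim), function(s) {
    block <- evoked$evoked[s, , idx, drop = TRUE]  # channels x samples
    as.vector(t(block))                            # channel-major
  }, numeric(dim(evoked$evoked)[2] * length(idx))))
  rownames(out) <- evoked$stimulus_ids
  out
}

# Closed-form ridge with intercept via the dual (kernel) identity:
# predictions on centred data are K_test (K + alpha I)^{-1} Y_c + Y_bar.
# Exact for any n, cheap when n << p (here n <= 40, p ~ 36k).
ridge_fit_predict <- function(x_train, y_train, x_test, alpha) {
  xbar <- colMeans(x_train)
  ybar <- colMeans(y_train)
  xc <- sweep(x_train, 2, xbar)
  yc <- sweep(y_train, 2, ybar)
  K <- tcrossprod(xc)
  sol <- solve(K + alpha * diag(nrow(xc)), yc)
  kt <- sweep(x_test, 2, xbar) %*% t(xc)
  sweep(kt %*% sol, 2, ybar, `+`)
}

#' Score one held-out pair of predicted vectors
#'
#' The leave-two-out pairwise statistic: the pair is decoded correctly
#' (accuracy 1) when the summed Spearman correlations of matched
#' prediction-target pairs exceed the mismatched sum,
#' rho(e1, ehat1) + rho(e2, ehat2) > rho(e1, ehat2) + rho(e2, ehat1);
#' accuracy 0 when smaller, 0.5 on an exact tie.
#'
#' @param e1,e2 true vectors.
#' @param ehat1,ehat2 predicted vectors.
#' @return a `pairwise_outcome`: list with `rho_matched`, `rho_mismatched`,
#'   `accuracy`.
#' @export
pairwise_score <- function(e1, e2, ehat1, ehat2) {
  vs <- list(e1 = e1, e2 = e2, ehat1 = ehat1, ehat2 = ehat2)
  lens <- vapply(vs, length, integer(1))
  if (length(unique(lens)) != 1 || lens[1] < 3)
    stop("all four vectors must share one dimension >= 3")
  const <- names(vs)[vapply(vs, function(v) stats::sd(v) == 0, logical(1))]
  if (length(const))
    stop("degenerate constant vector(s): ", paste(const, collapse = ", "))
  rho_m <- c(spearman_rho(e1, ehat1), spearman_rho(e2, ehat2))
  rho_x <- c(spearman_rho(e1, ehat2), spearman_rho(e2, ehat1))
  acc <- if (sum(rho_m) > sum(rho_x)) 1 else if (sum(rho_m) < sum(rho_x)) 0 else 0.5
  structure(list(rho_matched = rho_m, rho_mismatched = rho_x, accuracy = acc),
            class = "pairwise_outcome")
}

# Pair-type tags for a pair of stimulus ids.
pair_tags <- function(design, id1, id2) {
  st <- design$stimuli
  i1 <- match(id1, st$id); i2 <- match(id2, st$id)
  onto <- if (st$is_entity[i1] && st$is_entity[i2]) "entity-entity"
          else if (!st$is_entity[i1] && !st$is_entity[i2]) "category-category"
          else "mixed"
  coarse <- if (st$coarse[i1] == st$coarse[i2]) {
    if (st$coarse[i1] == "person") "people" else "places"
  } else "mixed"
  c(ontology = onto, coarse = coarse)
}

#' Leave-two-out zero-shot decoding of entity vectors
#'
#' For every unordered pair of stimuli in scope, fits the ridge map from
#' whole-epoch features to entity vectors on all remaining stimuli (the
#' held-out two never contribute training rows — the zero-shot contract,
#' asserted internally), predicts the two held-out vectors, and scores the
#' pair with [pairwise_score()]. The subject's decoding accuracy is the
#' mean over all pairs; each outcome carries pair-type tags (ontology:
#' entity-entity / category-category / mixed; coarse: people / places /
#' mixed) for the breakdown analysis.
#'
#' @param evoked an `evoked_set`.
#' @param vectors a `vector_set` covering the scope.
#' @param design a `stimulus_design` (for scope and pair tags).
#' @param scope `"entities_only"` (496 pairs) or `"all"` (780 pairs).
#' @param spec a `decoder_spec`.
#' @return a `decoding_result`: list with `subject_id`, `accuracy`,
#'   `outcomes` (data frame: id1, id2, ontology, coarse, accuracy,
#'   rho_m1, rho_m2, rho_x1, rho_x2).
#' @export
leave_two_out_decoding <- function(evoked, vectors, design,
                                   scope = c("entities_only", "all"),
                                   spec = decoder_spec()) {
  scope <- match.arg(scope)
  st <- design$stimuli
  ids <- if (scope == "entities_only") st$id[st$is_entity] else st$id
  if (length(ids) < 4L) stop("need at least 4 stimuli in scope")
  if (!all(ids %in% vectors$names))
    stop("vector set does not cover scope stimuli")
  feats <- features_from_evoked(evoked, spec)
  if (!all(ids %in% rownames(feats)))
    stop("evoked set does not cover scope stimuli")
  X <- feats[ids, , drop = FALSE]
  Y <- vectors$vectors[ids, , drop = FALSE]

  pairs <- utils::combn(length(ids), 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    train <- setdiff(seq_along(ids), c(i, j))
    stopifnot(!(i %in% train), !(j %in% train))  # zero-shot audit
    pred <- ridge_fit_predict(X[train, , drop = FALSE],
                              Y[train, , drop = FALSE],
                              X[c(i, j), , drop = FALSE], spec$alpha)
    sc <- pairwise_score(Y[i, ], Y[j, ], pred[1, ], pred[2, ])
    tags <- pair_tags(design, ids[i], ids[j])
    rows[[k]] <- data.frame(
      id1 = ids[i], id2 = ids[j], ontology = tags[["ontology"]],
      coarse = tags[["coarse"]], accuracy = sc$accuracy,
      rho_m1 = sc$rho_matched[1], rho_m2 = sc$rho_matched[2],
      rho_x1 = sc$rho_mismatched[1], rho_x2 = sc$rho_mismatched[2],
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, rows)
  structure(list(subject_id = evoked$subject_id,
                 accuracy = mean(outcomes$accuracy), outcomes = outcomes),
            class = "decoding_result")
}

#' Mean pairwise accuracy per pair-type bin
#'
#' Crosses the ontology tag (entity-entity / category-category / mixed)
#' with the coarse tag (people / places / mixed) over one or more
#' subjects' decoding results. Empty bins are reported with NA accuracy
#' rather than dropped silently.
#'
#' @param results a `decoding_result` or list of them.
#' @return data frame: ontology, coarse, n_pairs, mean_accuracy.
#' @export
breakdown_by_pair_type <- function(results) {
  if (inherits(results, "decoding_result")) results <- list(results)
  outcomes <- do.call(rbind, lapply(results, `[[`, "outcomes"))
  bins <- expand.grid(
    ontology = c("entity-entity", "category-category", "mixed"),
    coarse = c("people", "places", "mixed"),
    stringsAsFactors = FALSE)
  bins$n_pairs <- NA_integer_; bins$mean_accuracy <- NA_real_
  for (b in seq_len(nrow(bins))) {
    sel <- outcomes$ontology == bins$ontology[b] &
      outcomes$coarse == bins$coarse[b]
    bins$n_pairs[b] <- sum(sel)
    if (any(sel)) bins$mean_accuracy[b] <- mean(outcomes$accuracy[sel])
  }
  bins
}

#' Word-length / vector-similarity confound check
#'
#' If word vectors encoded word length, pairwise similarity in vector
#' space would track pairwise length differences. Over all unordered
#' stimulus pairs, correlates (Spearman) the cosine similarity of the two
#' vectors with the absolute difference in character length; a value near
#' 0 indicates word length is not a confound for vector decoding.
#'
#' @param vectors a `vector_set`.
#' @param design a `stimulus_design` providing word lengths.
#' @return Spearman rho in \[-1, 1\].
#' @export
length_similarity_correlation <- function(vectors, design) {
  st <- design$stimuli
  ids <- intersect(st$id, vectors$names)
  if (length(ids) < 3L) stop("need at least 3 stimuli")
  len <- stats::setNames(st$word_length, st$id)[ids]
  V <- vectors$vectors[ids, , drop = FALSE]
  pairs <- utils::combn(length(ids), 2)
  sims <- numeric(ncol(pairs)); gaps <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sims[k] <- cosine_similarity(V[i, ], V[j, ])
    gaps[k] <- abs(len[i] - len[j])
  }
  spearman_rho(sims, gaps)
}

#' Export decoding outcomes as CSV
#' @param results a `decoding_result` or list of them.
#' @param path output file.
#' @export
write_decoding_csv <- function(results, path) {
  if (inherits(results, "decoding_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject_id,
               r$outcomes[, c("id1", "id2", "ontology", "coarse", "accuracy")],
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Zero-shot decoding ", x$subject_id, ": mean pairwise accuracy ",
      round(x$accuracy, 4), " over ", nrow(x$outcomes), " pairs\n", sep = "")
  invisible(x)
}
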