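#' Mention-level contextual vectors for one entity
#'
#' Contextualized language models yield one (layers x dim) block per
#' mention of an entity in text. A static entity vector is obtained by
#' averaging selected layers within each mention and then averaging across
#' mentions (up to the first `cap` mentions, in text order).
#'
#' @param entity_id entity identifier.
#' @param mentions list of numeric matrices (layers x dim), one per
#'   mention, in occurrence order.
#' @param cap maximum number of mentions retained (default 32).
#' @return a `mention_vectors` object.
#' @export
mention_vectors <- function(entity_id, mentions, cap = 32L) {
  stopifnot(length(mentions) >= 1)
  dims <- vapply(mentions, ncol, integer(1))
  if (length(unique(dims)) != 1)
    stop("inconsistent vector dimensionality across mentions")
  structure(list(entity_id = entity_id, mentions = mentions,
                 cap = as.integer(cap)),
            class = "mention_vectors")
}

#' Aggregate mention-level contextual vectors into one static vector
#'
#' Truncates to the first `cap` mentions, averages the selected layers
#' within each mention, then averages over mentions. Because both steps
#' are arithmetic means, layer-then-mention and mention-then-layer
#' averaging commute.
#'
#' @param mv a `mention_vectors`.
#' @param layers integer indices of the layers to average (e.g. the final
#'   layer, or the last four of a deep model).
#' @return a numeric vector of the model dimension.
#' @export
aggregate_contextual_vectors <- function(mv, layers) {
  stopifnot(inherits(mv, "mention_vectors"))
  if (length(layers) == 0) stop("layer set must be non-empty")
  n_layers <- nrow(mv$mentions[[1]])
  if (any(layers < 1 | layers > n_layers))
    stop("layer indices out of range 1..", n_layers)
  kept <- mv$mentions[seq_len(min(length(mv$mentions), mv$cap))]
  per_mention <- lapply(kept, function(m)
    colMeans(m[layers, , drop = FALSE]))
  colMeans(do.call(rbind, per_mention))
}

#' Spearman correlation with a similarity/relatedness benchmark
#'
#' Computes, for each benchmark pair resolvable against the vector set,
#' the cosine similarity of the two vectors, and returns the Spearman
#' correlation with the human judgments. Unresolvable pairs are dropped;
#' their count is attached as attribute `n_dropped`.
#'
#' @param vectors a `vector_set`.
#' @param bench data frame with columns `id1`, `id2`, `score`.
#' @return Spearman rho, with attribute `n_dropped`.
#' @export
similarity_benchmark_correlation <- function(vectors, bench) {
  stopifnot(all(c("id1", "id2", "score") %in% names(bench)))
  ok <- bench$id1 %in% vectors$names & bench$id2 %in% vectors$names
  n_dropped <- sum(!ok)
  bench <- bench[ok, , drop = FALSE]
  if (nrow(bench) < 3L)
    stop("fewer than 3 resolvable benchmark pairs (", n_dropped, " dropped)")
  sims <- mapply(function(a, b)
    cosine_similarity(vectors$vectors[a, ], vectors$vectors[b, ]),
    bench$id1, bench$id2)
  structure(spearman_rho(sims, bench$score), n_dropped = n_dropped)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' expectation 0 under independent labelings. Symmetric and invariant to
#' label renaming.
#'
#' @param a,b labelings of the same items.
#' @return the ARI (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ari <- mclust::adjustedRandIndex(a, b)
  if (is.nan(ari)) {
    # the denominator vanishes only when both partitions are trivial
    # (all singletons or one block) and hence identical
    return(1)
  }
  ari
}

#' Cluster vectors with K-means and score against reference labels
#'
#' Partitions the vectors into `k` clusters with K-means (seeded, best
#' inertia over `n_restarts` random restarts) and scores the partition
#' against the reference labeling with the adjusted Rand index. Used to
#' validate that entity vectors carry categorical structure: vectors that
#' cluster by coarse or fine category score well above 0.
#'
#' @param vectors a `vector_set`.
#' @param labels named vector of reference labels (names = stimulus ids),
#'   or an unnamed vector aligned with `vectors$names`.
#' @param k number of clusters; must equal the number of distinct labels.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @return a `clustering_evaluation`: list with `ari`, `cluster`,
#'   `labels`, `k`.
#' @export
cluster_and_score <- function(vectors, labels, k = NULL, seed = 1L,
                              n_restarts = 10L) {
  if (!is.null(names(labels))) {
    missing_ids <- setdiff(vectors$names, names(labels))
    if (length(missing_ids))
      stop("labels missing for: ", paste(missing_ids, collapse = ", "))
    labels <- labels[vectors$names]
  }
  if (length(labels) != nrow(vectors$vectors))
    stop("one label per vector required")
  if (is.null(k)) k <- length(unique(labels))
  if (k != length(unique(labels)))
    stop("k (", k, ") must equal the number of distinct labels (",
         length(unique(labels)), ")")
  if (k > nrow(vectors$vectors)) stop("k exceeds the number of vectors")
  km <- with_seed(seed,
    stats::kmeans(vectors$vectors, centers = k, nstart = n_restarts))
  structure(list(ari = adjusted_rand_index(km$cluster, labels),
                 cluster = km$cluster, labels = labels, k = k),
            class = "clustering_evaluation")
}

#' Synthetic mention vectors for hermetic testing
#'
#' Emulates per-mention contextual vectors: each mention block is the
#' entity's static vector repeated over layers plus independent Gaussian
#' noise, so aggregation recovers the static vector as noise or mention
#' count shrinks.
#'
#' @param vectors a `vector_set`.
#' @param n_mentions mentions per entity.
#' @param n_layers layers per mention.
#' @param noise_sd per-entry noise sd.
#' @param seed integer seed.
#' @param cap mention cap (default 32).
#' @return named list of `mention_vectors`.
#' @export
generate_mention_vectors <- function(vectors, n_mentions = 8L, n_layers = 4L,
                                     noise_sd = 0.1, seed = 1L, cap = 32L) {
  with_seed(seed, {
    out <- lapply(seq_along(vectors$names), function(i) {
      v <- vectors$vectors[i, ]
      mentions <- lapply(seq_len(n_mentions), function(m)
        matrix(rep(v, each = n_layers), n_layers, length(v)) +
          matrix(stats::rnorm(n_layers * length(v), 0, noise_sd),
                 n_layers, length(v)))
      mention_vectors(vectors$names[i], mentions, cap = cap)
    })
    stats::setNames(out, vectors$names)
  })
}

#' Read / write mention vectors and benchmarks as TSV
#'
#' Long-format mention TSV columns: `entity_id, mention, layer,
#' d1 ... dk`. Benchmark TSV columns: `id1, id2, score`.
#'
#' @param mvs named list of `mention_vectors`; `path` a file path.
#' @name embedding_io
NULL

#' @rdname embedding_io
#' @export
write_mention_vectors_tsv <- function(mvs, path) {
  rows <- list()
  for (mv in mvs) {
    for (m in seq_along(mv$mentions)) {
      block <- mv$mentions[[m]]
      for (l in seq_len(nrow(block))) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_id = mv$entity_id, mention = m, layer = l,
          t(block[l, ]), stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  names(df) <- c("entity_id", "mention", "layer",
                 paste0("d", seq_len(ncol(df) - 3L)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname embedding_io
#' @export
read_mention_vectors_tsv <- function(path, cap = 32L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  dims <- grep("^d[0-9]+$", names(df), value = TRUE)
  out <- lapply(split(df, df$entity_id), function(sub) {
    mentions <- lapply(split(sub, sub$mention), function(mb) {
      mb <- mb[order(mb$layer), ]
      m <- as.matrix(mb[, dims, drop = FALSE])
      dimnames(m) <- NULL
      m
    })
    mention_vectors(sub$entity_id[1], unname(mentions), cap = cap)
  })
  out
}

#' @rdname embedding_io
#' @export
read_benchmark_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id1", "id2", "score") %in% names(df)))
  df
}
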