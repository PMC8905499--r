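#' TFCE parameters
#'
#' Threshold-free cluster enhancement over a one-dimensional (temporal)
#' statistic. `E` and `H` are the extent and height exponents (the
#' conventional defaults 0.5 and 2.0), `dh` the threshold step (when `NULL`,
#' 50 steps up to the observed maximum), `start` the first threshold, and
#' `adjacency_ms` the temporal adjacency radius: two samples belong to the
#' same cluster run only if their time difference is at most this many ms
#' (default 10 ms, the shortest duration of the post-synaptic potentials
#' EEG measures, so the signal can be assumed smooth within it).
#'
#' @param E extent exponent (>= 0, default 0.5).
#' @param H height exponent (>= 0, default 2).
#' @param dh threshold step; `NULL` means `max(stat) / 50`.
#' @param start first threshold offset (default 0).
#' @param adjacency_ms temporal adjacency radius in ms (default 10).
#' @return a `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, dh = NULL, start = 0,
                        adjacency_ms = 10) {
  if (E < 0 || H < 0) stop("E and H must be >= 0")
  if (!is.null(dh) && dh <= 0) stop("dh must be > 0")
  structure(list(E = E, H = H, dh = dh, start = start,
                 adjacency_ms = adjacency_ms), class = "tfce_params")
}

#' Threshold-free cluster enhancement of a 1-D statistic
#'
#' For each point p, sums over the threshold ladder
#' h = start + dh, start + 2 dh, ... <= stat(p) the quantity
#' e(h, p)^E * h^H * dh, where e(h, p) is the length of the maximal run of
#' temporally adjacent points containing p whose statistic is >= h. Runs
#' are broken wherever consecutive samples are further apart than
#' `adjacency_ms`. Tall, temporally extended effects are enhanced; isolated
#' spikes much less so.
#'
#' @param stat numeric vector of per-timepoint statistics (finite).
#' @param params a `tfce_params`.
#' @param times sample times in ms, strictly increasing, same length.
#' @return numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat, params = tfce_params(), times) {
  if (any(!is.finite(stat))) stop("stat must be finite")
  if (length(times) != length(stat)) stop("times and stat lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("time axis must be strictly increasing")
  n <- length(stat)
  enhanced <- numeric(n)
  top <- max(stat)
  if (top <= params$start) return(enhanced)
  dh <- if (is.null(params$dh)) (top - params$start) / 50 else params$dh
  # segment id: increments where the gap between samples exceeds adjacency
  seg <- c(0, cumsum(diff(times) > params$adjacency_ms + 1e-9))
  seg_brk <- c(TRUE, diff(seg) != 0)
  h <- params$start + dh
  while (h <= top + 1e-12) {
    above <- stat >= h
    if (!any(above)) break
    # run ids: break where the suprathreshold mask flips or segments change
    gid <- cumsum(c(TRUE, diff(above) != 0) | seg_brk)
    lens <- tabulate(gid)
    contrib <- lens[gid]^params$E * h^params$H * dh
    enhanced[above] <- enhanced[above] + contrib[above]
    h <- h + dh
  }
  enhanced
}

#' TFCE permutation significance for accuracy time courses
#'
#' Input is a subjects x timepoints matrix of accuracy-minus-chance. The
#' observed per-timepoint statistic (one-sample t across subjects by
#' default, or the plain mean) is TFCE-enhanced; the null distribution is
#' built by randomly sign-flipping whole subject rows (exchangeable under
#' the null of no effect), re-enhancing, and recording the maximum
#' enhanced value over timepoints. The max-statistic null provides
#' family-wise error control: p(t) is the fraction of permutations whose
#' maximum reaches the observed enhanced value at t. The identity
#' assignment is always included, so the smallest attainable p is
#' 1/n_perm.
#'
#' @param curves matrix (n_subjects x n_timepoints), accuracy minus chance.
#' @param times sample times in ms (default: sample index grid).
#' @param params a `tfce_params`.
#' @param n_perm number of sign-flip permutations (default 1024; fewer than
#'   100 triggers a warning).
#' @param alpha significance level (default 0.05).
#' @param statistic `"t"` (default) or `"mean"`.
#' @param seed integer seed for the sign flips.
#' @return a `significance_result`: list with `times`, `pvalues`, `alpha`,
#'   `significant_mask`, `observed` (enhanced statistic).
#' @export
permutation_significance <- function(curves, times = NULL,
                                     params = tfce_params(), n_perm = 1024L,
                                     alpha = 0.05, statistic = c("t", "mean"),
                                     seed = 1L) {
  statistic <- match.arg(statistic)
  curves <- as.matrix(curves)
  n_sub <- nrow(curves); n_tp <- ncol(curves)
  if (n_sub < 2L) stop("need at least 2 subjects")
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value grid")
  if (is.null(times)) times <- seq_len(n_tp)

  stat_fun <- function(m) {
    mu <- colMeans(m)
    if (statistic == "mean") return(mu)
    se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    se <- pmax(se, .Machine$double.eps)
    mu / se
  }

  obs_stat <- stat_fun(curves)
  top <- max(obs_stat)
  dh <- if (is.null(params$dh)) {
    if (top > params$start) (top - params$start) / 50 else 1
  } else params$dh
  p_fixed <- params; p_fixed$dh <- dh
  obs_enh <- tfce_enhance(obs_stat, p_fixed, times)

  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    signs <- if (b == 1L) rep(1, n_sub) else sample(c(-1, 1), n_sub, replace = TRUE)
    max(tfce_enhance(stat_fun(curves * signs), p_fixed, times))
  }, numeric(1)))

  pvalues <- vapply(obs_enh, function(v) mean(null_max >= v), numeric(1))
  pvalues <- pmin(pmax(pvalues, 1 / n_perm), 1)
  structure(list(times = times, pvalues = pvalues, alpha = alpha,
                 significant_mask = pvalues < alpha, observed = obs_enh),
            class = "significance_result")
}

#' Wilcoxon signed-rank test
#'
#' One-sample one-tailed ("greater") test of a location shift above `mu0`,
#' or a paired two-sided test against `y`. Zero differences are removed;
#' the p-value is exact for n <= 12 without ties and uses the normal
#' approximation with tie correction otherwise. If every difference is
#' zero the test carries no evidence and p = 1 is returned with a warning.
#'
#' @param x numeric sample.
#' @param mu0 null location for the one-sample mode (default 0).
#' @param mode `"one_sample_greater"` or `"paired_two_sided"`.
#' @param y paired sample (required for `paired_two_sided`).
#' @return the p-value.
#' @export
wilcoxon_test <- function(x, mu0 = 0,
                          mode = c("one_sample_greater", "paired_two_sided"),
                          y = NULL) {
  mode <- match.arg(mode)
  d <- if (mode == "paired_two_sided") {
    if (is.null(y)) stop("paired mode requires y")
    x - y
  } else x - mu0
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; returning p = 1")
    return(1)
  }
  if (length(d) < 3L) stop("need at least 3 nonzero differences")
  alternative <- if (mode == "one_sample_greater") "greater" else "two.sided"
  exact <- length(d) <= 12L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: sort p-values ascending, find the largest rank i with
#' p(i) <= i q / m, and reject hypotheses at all ranks up to i.
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return logical vector, `TRUE` where rejected, in input order.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Export a significance result as CSV
#' @param res a `significance_result`.
#' @param path output file.
#' @export
write_significance_csv <- function(res, path) {
  utils::write.csv(
    data.frame(time_ms = res$times, pvalue = res$pvalues,
               significant = res$significant_mask),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.significance_result <- function(x, ...) {
  cat("TFCE permutation test: ", sum(x$significant_mask), "/",
      length(x$pvalues), " timepoints significant at alpha = ", x$alpha,
      "\n", sep = "")
  invisible(x)
}
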