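#' Spearman rank correlation with a total ties rule
#'
#' Spearman's rho computed with average ranks for ties. If either input is
#' constant (so that ranks are degenerate and the usual estimator is
#' undefined), the correlation is defined as 0. This keeps split selection
#' and confound checks total over degenerate inputs.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a single number in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Time axis for an epoch window
#'
#' Samples are placed at t_k = start + k * 1000 / rate ms for
#' k = 0 ... floor((end - start) * rate / 1000), i.e. the grid starts exactly
#' at the window start and the last sample is the largest grid point not
#' exceeding the window end. For -100...1200 ms at 256 Hz this gives 333
#' samples.
#'
#' @param epoch_window length-2 numeric, window in ms (start, end).
#' @param rate sampling rate in Hz.
#' @return numeric vector of sample times in ms.
#' @export
epoch_times <- function(epoch_window = c(-100, 1200), rate = 256) {
  stopifnot(length(epoch_window) == 2, epoch_window[2] > epoch_window[1], rate > 0)
  n <- floor((epoch_window[2] - epoch_window[1]) * rate / 1000) + 1
  epoch_window[1] + (seq_len(n) - 1) * 1000 / rate
}

#' Sample indices covered by a time window
#'
#' Index-based window convention: with epoch start t0 and sampling rate r,
#' a window (a, b) in ms covers 1-based sample indices
#' floor((a - t0) * r / 1000) + 1 through floor((b - t0) * r / 1000) + 1,
#' endpoints inclusive. The floor at the start means a window edge falling
#' between two samples extends back to the previous sample, so the window is
#' never narrower than its nominal duration. For 100-1200 ms inside a
#' -100...1200 ms epoch at 256 Hz this covers 282 samples.
#'
#' @param times sample times in ms (as from [epoch_times()]).
#' @param window length-2 numeric window in ms.
#' @param rate sampling rate in Hz.
#' @return integer vector of 1-based indices into `times`.
#' @export
window_indices <- function(times, window, rate) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  t0 <- times[1]
  if (window[1] < t0 - 1e-9 || window[2] > times[length(times)] + 1000 / rate)
    stop("window (", window[1], ", ", window[2], ") outside epoch time axis")
  i0 <- floor((window[1] - t0) * rate / 1000) + 1
  i1 <- floor((window[2] - t0) * rate / 1000) + 1
  i1 <- min(i1, length(times))
  seq.int(i0, i1)
}

# Derive a child seed from a base seed and a small offset, staying within
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
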