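# Imbalance-aware training machinery: AUC binning, smoothed inverse-frequency
# bin weights, the multinomial weighted sampler, the double-weighted MSE loss
# and the focal loss used by the synergy classifier.

#' Assign dose-response AUC values to histogram bins
#'
#' Twelve equally spaced bins over `[0, 1.2]`: lower-closed, upper-open, with
#' the last bin closed at 1.2. Out-of-range values are clamped to the first or
#' last bin with a warning.
#'
#' @param auc Numeric vector of AUC values (finite).
#' @param n_bins Number of bins (default 12).
#' @param bin_range Range covered by the bins (default `c(0, 1.2)`).
#' @return Integer vector of 0-based bin indices (`0 .. n_bins - 1`).
#' @examples
#' assign_bin(c(0, 0.1, 0.95, 1.2))
#' @export
assign_bin <- function(auc, n_bins = 12L, bin_range = c(0, 1.2)) {
  if (any(is.na(auc)) || any(!is.finite(auc))) {
    stop("assign_bin: AUC values must be finite")
  }
  width <- diff(bin_range) / n_bins
  idx <- floor((auc - bin_range[1]) / width)
  oob <- auc < bin_range[1] | auc > bin_range[2]
  if (any(oob)) {
    warning("assign_bin: ", sum(oob), " AUC value(s) outside [",
            bin_range[1], ", ", bin_range[2], "] clamped to the edge bins")
  }
  as.integer(pmin(pmax(idx, 0), n_bins - 1L))
}

#' Smoothed inverse-frequency bin weights
#'
#' For bin counts `c_i`, relative frequencies `f_i = c_i / sum(c_j)`, the
#' smoothed inverses `v_i = 1 / (f_i + epsilon)` are normalized to weights
#' `w_i = v_i / sum(v_j)`. `epsilon = 0` yields pure inverse-frequency
#' (perfectly class-balancing) weights and requires every bin to be occupied;
#' as `epsilon` grows the weights flatten toward uniform.
#'
#' With `epsilon = 0` an empty bin's raw inverse is infinite; since such a
#' bin holds no records to sample or weight, it receives weight 0 and the
#' normalization runs over the occupied bins (with `epsilon > 0` empty bins
#' get the finite `1/epsilon` before normalization, as the formula states).
#'
#' @param aucs Numeric vector of AUC values (at least one).
#' @param epsilon Smoothing penalty, `>= 0`.
#' @inheritParams assign_bin
#' @return A `bin_weights`: list with `edges`, `counts`, `freq`, `inv`
#'   (smoothed inverses), `weights` (normalized, summing to 1) and `epsilon`.
#' @examples
#' bw <- compute_bin_weights(c(rep(0.05, 10), rep(0.95, 90)), epsilon = 0)
#' bw$weights[c(1, 10)] # rare bin 0.9, common bin 0.1
#' @export
compute_bin_weights <- function(aucs, epsilon, n_bins = 12L,
                                bin_range = c(0, 1.2)) {
  if (!length(aucs)) stop("compute_bin_weights: need at least one sample")
  if (epsilon < 0) stop("compute_bin_weights: epsilon must be >= 0")
  bins <- assign_bin(aucs, n_bins, bin_range)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  freq <- counts / sum(counts)
  inv <- 1 / (freq + epsilon)
  if (epsilon == 0) inv[counts == 0L] <- 0
  weights <- inv / sum(inv)
  structure(list(
    edges = seq(bin_range[1], bin_range[2], length.out = n_bins + 1L),
    counts = counts, freq = freq, inv = inv, weights = weights,
    epsilon = epsilon, n_bins = as.integer(n_bins), bin_range = bin_range
  ), class = "bin_weights")
}

#' Per-record sampling weights (the weight of each record's truth bin)
#' @param aucs Numeric vector of AUC values.
#' @param bw A `bin_weights`.
#' @return Numeric vector of per-record weights.
#' @export
record_weights <- function(aucs, bw) {
  bw$weights[assign_bin(aucs, bw$n_bins, bw$bin_range) + 1L]
}

#' Multinomial weighted resampling of record indices
#'
#' Draws `n_draws` indices with replacement, with per-record probabilities
#' proportional to `weights`; used to re-draw one epoch's worth of training
#' records.
#'
#' @param weights Nonnegative per-record weights, not all zero.
#' @param n_draws Number of draws (defaults to `length(weights)`).
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return Integer vector of 1-based indices of length `n_draws`.
#' @export
sample_indices <- function(weights, n_draws = length(weights), seed = 1L) {
  if (any(weights < 0)) stop("sample_indices: negative weights")
  if (all(weights == 0)) stop("sample_indices: all-zero weights")
  with_seed(seed, sample.int(length(weights), n_draws, replace = TRUE,
                             prob = weights))
}

#' Double-weighted mean squared error
#'
#' `L(p, t) = max(w_bin(p), w_bin(t)) * (p - t)^2`, averaged over records.
#' Errors are up-weighted whenever either the truth or the prediction falls in
#' a rare AUC bin.
#'
#' @param p,t Numeric vectors: predictions and ground truth.
#' @param bw A `bin_weights`.
#' @param reduce If `TRUE` (default) return the mean over records, else the
#'   per-record losses.
#' @return Nonnegative number (or vector when `reduce = FALSE`).
#' @export
double_weighted_mse <- function(p, t, bw, reduce = TRUE) {
  if (any(!is.finite(p)) || any(!is.finite(t))) {
    stop("double_weighted_mse: non-finite inputs")
  }
  wp <- record_weights(p, bw)
  wt <- record_weights(t, bw)
  per <- pmax(wp, wt) * (p - t)^2
  if (reduce) mean(per) else per
}

#' Binary focal loss
#'
#' `-alpha * (1 - prob)^gamma * log(prob)` for positives and
#' `-(1 - alpha) * prob^gamma * log(1 - prob)` for negatives; with
#' `gamma = 0`, `alpha = 0.5` this is half the binary cross-entropy.
#' Probabilities exactly 0 or 1 are clamped by a tiny eps.
#'
#' @param prob Predicted probabilities in `(0, 1)`.
#' @param y Binary labels (0/1).
#' @param alpha Class-balance weight (default 0.4).
#' @param gamma Focusing exponent (default 2).
#' @param reduce Mean over records when `TRUE` (default).
#' @return Nonnegative number (or vector when `reduce = FALSE`).
#' @export
focal_loss <- function(prob, y, alpha = 0.4, gamma = 2, reduce = TRUE) {
  eps <- 1e-12
  if (any(prob <= 0 | prob >= 1)) {
    message("focal_loss: probabilities at {0,1} clamped by ", eps)
    prob <- pmin(pmax(prob, eps), 1 - eps)
  }
  per <- ifelse(y == 1,
                -alpha * (1 - prob)^gamma * log(prob),
                -(1 - alpha) * prob^gamma * log(1 - prob))
  if (reduce) mean(per) else per
}

# Gradient of the (reduced) focal loss with respect to the pre-sigmoid logit.
focal_loss_grad_logit <- function(prob, y, alpha = 0.4, gamma = 2) {
  eps <- 1e-12
  prob <- pmin(pmax(prob, eps), 1 - eps)
  dLdp <- ifelse(
    y == 1,
    -alpha * (-gamma * (1 - prob)^(gamma - 1) * log(prob) + (1 - prob)^gamma / prob),
    -(1 - alpha) * (gamma * prob^(gamma - 1) * log(1 - prob) - prob^gamma / (1 - prob))
  )
  dLdp * prob * (1 - prob) / length(prob)
}

#' @export
print.bin_weights <- function(x, ...) {
  cat("bin_weights:", x$n_bins, "bins over [", x$bin_range[1], ",",
      x$bin_range[2], "], epsilon =", x$epsilon, "\n")
  print(data.frame(bin = seq_len(x$n_bins) - 1L, count = x$counts,
                   weight = round(x$weights, 5)))
  invisible(x)
}
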