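# Evaluation against ground truth: centre matching, precision/recall/
# success, spike-timing agreement, SNR conversions.

# Optimal one-to-one assignment allowing unmatched points: pairs farther
# apart than `max_dist` are forbidden, matching as many pairs as possible
# is preferred over any distance saving, and among maximal matchings the
# total distance is minimal. Solved as a linear sum assignment problem on
# an augmented square matrix (clue::solve_LSAP).
assign_within <- function(dist, max_dist) {
  n <- nrow(dist); m <- ncol(dist)
  if (n == 0L || m == 0L)
    return(cbind(est = integer(0), truth = integer(0)))
  big <- 1e9
  unmatch <- 10 * (max_dist + 1)
  cost <- matrix(big, n + m, n + m)
  allowed <- dist <= max_dist
  cost[seq_len(n), seq_len(m)] <- ifelse(allowed, dist, big)
  for (i in seq_len(n)) cost[i, m + i] <- unmatch
  for (j in seq_len(m)) cost[n + j, j] <- unmatch
  cost[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- clue::solve_LSAP(cost)
  est <- seq_len(n)
  truth <- as.integer(sol[seq_len(n)])
  keep <- truth <= m
  keep[keep] <- allowed[cbind(est[keep], truth[keep])]
  cbind(est = est[keep], truth = truth[keep])
}

#' Match estimated to ground-truth ROI centres
#'
#' One-to-one optimal assignment between two centroid sets: an estimate
#' can match a ground-truth cell only if their centres are within
#' `max_dist` pixels (default 5); among assignments with the maximal
#' number of matches, total centre distance is minimized.
#'
#' @param est,truth numeric matrices with one `(row, col)` centre per row
#'   (a list of masks is also accepted and reduced to centroids).
#' @param max_dist matching radius in pixels.
#' @return an object of class `roi_match`: list with `pairs` (data frame
#'   `est`, `truth`, `dist`), `unmatched_est`, `unmatched_truth`,
#'   `n_est`, `n_truth`.
#' @export
match_rois <- function(est, truth, max_dist = 5) {
  est <- as_centres(est)
  truth <- as_centres(truth)
  d <- outer(seq_len(nrow(est)), seq_len(nrow(truth)),
             function(i, j) sqrt((est[i, 1] - truth[j, 1])^2 +
                                 (est[i, 2] - truth[j, 2])^2))
  d <- matrix(d, nrow(est), nrow(truth))
  pr <- assign_within(d, max_dist)
  pairs <- data.frame(est = pr[, "est"], truth = pr[, "truth"],
                      dist = if (nrow(pr)) d[pr] else numeric(0))
  structure(list(pairs = pairs,
                 unmatched_est = setdiff(seq_len(nrow(est)), pairs$est),
                 unmatched_truth = setdiff(seq_len(nrow(truth)), pairs$truth),
                 n_est = nrow(est), n_truth = nrow(truth)),
            class = "roi_match")
}

as_centres <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- t(vapply(x, mask_centroid, numeric(2)))
  x <- as.matrix(x)
  if (length(x) && ncol(x) != 2L) stop_input("centres must be (row, col)")
  if (!length(x)) x <- matrix(numeric(0), 0, 2)
  x
}

#' @export
print.roi_match <- function(x, ...) {
  cat(sprintf("ROI matching: %d/%d estimates matched to %d truths\n",
              nrow(x$pairs), x$n_est, x$n_truth))
  invisible(x)
}

#' Precision, recall and fall-out of a matching
#'
#' Precision is the percentage of estimates found in the ground truth,
#' recall the percentage of ground-truth objects recovered, and fall-out
#' the complement of precision (estimates not in the ground truth). With
#' zero estimates precision is undefined and reported as 0 with
#' `undefined_precision = TRUE`.
#'
#' @param match a `roi_match` object.
#' @return list with `precision`, `recall`, `fallout` (percent) and
#'   `undefined_precision`.
#' @export
precision_recall_fallout <- function(match) {
  stopifnot(inherits(match, "roi_match"))
  k <- nrow(match$pairs)
  undef <- match$n_est == 0L
  precision <- if (undef) 0 else 100 * k / match$n_est
  recall <- if (match$n_truth == 0L) 0 else 100 * k / match$n_truth
  list(precision = precision, recall = recall,
       fallout = 100 - precision, undefined_precision = undef)
}

#' Segmentation success rate
#'
#' The harmonic mean `2 p r / (p + r)` of precision and recall (percent),
#' the headline score for comparing segmentations; 0 when both are 0.
#'
#' @param precision,recall percentages in `[0, 100]`.
#' @return the success rate in percent.
#' @examples
#' success_rate(56.5, 73.1)  # 63.7
#' @export
success_rate <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Match estimated to ground-truth spike trains
#'
#' One-dimensional analogue of [match_rois()]: spikes match when their
#' times differ by at most `window` seconds (default 0.22 s, three sample
#' widths at the reference frame rate), assigned one-to-one with minimal
#' total timing error. Reports precision/recall plus the RMSE and mean
#' absolute error of matched spike times.
#'
#' @param est,truth numeric vectors of spike times in seconds (sorted or
#'   not; they are sorted internally).
#' @param window matching window in seconds.
#' @return list with `match` (a `roi_match`), `precision`, `recall`,
#'   `success`, `rmse` and `mae` (seconds; `NA` with no matches).
#' @export
match_spikes <- function(est, truth, window = 0.22) {
  est <- sort(as.numeric(est))
  truth <- sort(as.numeric(truth))
  d <- abs(outer(est, truth, `-`))
  d <- matrix(d, length(est), length(truth))
  pr <- assign_within(d, window)
  pairs <- data.frame(est = pr[, "est"], truth = pr[, "truth"],
                      dist = if (nrow(pr)) d[pr] else numeric(0))
  match <- structure(list(pairs = pairs,
                          unmatched_est = setdiff(seq_along(est), pairs$est),
                          unmatched_truth = setdiff(seq_along(truth),
                                                    pairs$truth),
                          n_est = length(est), n_truth = length(truth)),
                     class = "roi_match")
  prf <- precision_recall_fallout(match)
  err <- pairs$dist
  list(match = match, precision = prf$precision, recall = prf$recall,
       success = success_rate(prf$precision, prf$recall),
       rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_,
       mae = if (length(err)) mean(err) else NA_real_)
}

#' Signal-to-noise ratio in decibels, and back
#'
#' `snr_db` converts a signal-power/noise-power ratio to decibels,
#' `10 log10(sp / np)`; `snr_ratio` inverts a dB value to the power ratio.
#'
#' @param signal_power,noise_power positive powers (variances).
#' @return decibels (`snr_db`) or the power ratio (`snr_ratio`).
#' @examples
#' snr_db(10, 1)    # 10 dB
#' snr_ratio(0)     # 1
#' @export
snr_db <- function(signal_power, noise_power) {
  if (any(signal_power <= 0) || any(noise_power <= 0))
    stop_input("powers must be positive")
  10 * log10(signal_power / noise_power)
}

#' @rdname snr_db
#' @param db SNR in decibels.
#' @export
snr_ratio <- function(db) 10^(db / 10)

#' Estimate the SNR of ROI-average traces in a video
#'
#' Estimates, in decibels, the signal-to-noise ratio of the average time
#' course of an `n_pixels`-pixel region of active tissue -- the quantity
#' the merge-threshold formula ([merge_threshold_from_snr()]) expects.
#' Per-pixel white-noise variance is estimated robustly from first
#' temporal differences (`var(diff(x))/2`, median over pixels; transients
#' and background vary slowly compared to frame noise, so differences are
#' noise-dominated). The per-pixel signal variance of active pixels is
#' the mean excess variance over the brightest-varying 15% of pixels.
#' Averaging over `n_pixels` divides the noise variance by `n_pixels`
#' while leaving the (spatially coherent) signal variance intact.
#'
#' @param video a [video_stack()].
#' @param n_pixels region size the trace is averaged over (e.g. the seed
#'   area used for initialization).
#' @return estimated SNR in dB.
#' @export
estimate_trace_snr <- function(video, n_pixels) {
  stopifnot(inherits(video, "video_stack"), n_pixels >= 1)
  M <- pixel_matrix(video)
  D <- M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE]
  noise_var <- stats::median(apply(D, 1, stats::var)) / 2
  tot <- apply(M, 1, stats::var)
  s2 <- pmax(tot - noise_var, 0)
  active <- s2 >= stats::quantile(s2, 0.85)
  signal_var <- mean(s2[active])
  snr_db(max(signal_var, .Machine$double.eps), noise_var / n_pixels)
}

#' Score a segmentation against ground-truth masks
#'
#' Convenience wrapper: reduces both sides to interior centroids, matches
#' them within `max_dist` pixels and reports precision, recall, fall-out
#' and success rate.
#'
#' @param seg a `segmentation` or `caimseg` fit, or a list of masks /
#'   centre matrix.
#' @param truth_masks list of ground-truth masks or a centre matrix.
#' @param max_dist matching radius in pixels.
#' @return list with the `roi_match` and the four percentages.
#' @export
evaluate_segmentation <- function(seg, truth_masks, max_dist = 5) {
  if (inherits(seg, "caimseg")) seg <- seg$segmentation
  est <- if (inherits(seg, "segmentation")) {
    lapply(seg_alive(seg), function(i) seg$states[[i]]$interior)
  } else seg
  m <- match_rois(est, truth_masks, max_dist)
  prf <- precision_recall_fallout(m)
  c(list(match = m), prf,
    list(success = success_rate(prf$precision, prf$recall)))
}
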