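#' Segmentation parameters
#'
#' Bundles the tunable parameters of the coupled level-set segmentation.
#' Only two must be chosen per dataset: the expected cell radius `radius`
#' (pixels) and the external-energy weight `lambda`, which balances the
#' data-driven velocity against the smoothing regularizer. The remaining
#' defaults follow the published values and rarely need changing.
#'
#' The discretized evolution is stable only when `mu * delta_tau < 0.25`
#' (Courant-Friedrichs-Lewy condition); this is asserted at construction
#' and never silently clamped. Defaults `delta_tau = 10`, `mu = 0.02`
#' give `mu * delta_tau = 0.2`.
#'
#' @param radius expected cell radius in pixels (required).
#' @param lambda weight of the external (data) energy (required).
#' @param metric dissimilarity metric: `"euclidean"` (default; compares
#'   pattern and magnitude) or `"correlation"` (pattern only, suited to
#'   donut cells and uneven brightness).
#' @param delta_tau evolution step size.
#' @param mu weight of the distance regularizer; default `0.2 / delta_tau`.
#' @param epsilon half-width (pixels) of the smoothed Dirac band in which
#'   the external velocity acts.
#' @param alpha seeding selectivity for automatic initialization, in SD
#'   units of the summary image (recommended range 0.2-0.8).
#' @param n_max maximum number of evolution sweeps.
#' @param n_con consecutive quiet sweeps required for convergence.
#' @param rho convergence tolerance: a sweep is quiet when fewer than
#'   `rho` pixels enter or leave the interior.
#' @param min_area,max_area pruning thresholds on interior area in pixels;
#'   defaults 3 and `3 * pi * radius^2`.
#' @param merge_threshold correlation above which two nearby ROIs are
#'   merged; default 0.8. Alternatively supply `snr_db` to derive it via
#'   [merge_threshold_from_snr()].
#' @param snr_db optional measured SNR (dB) of the data; when given,
#'   `merge_threshold` is set to `merge_threshold_from_snr(snr_db)`.
#' @param narrowband_width width of the exterior narrowband in pixels;
#'   default `2 * radius`.
#' @param prune_undifferentiated if `TRUE`, an ROI whose converged interior
#'   time course correlates with its narrowband time course at or above
#'   `undiff_threshold` is dropped: its interior is indistinguishable from
#'   local background. Off by default; useful with grid seeding where most
#'   seeds start on background.
#' @param undiff_threshold correlation gate for `prune_undifferentiated`;
#'   default 0.8. Kept separate from `merge_threshold` because it compares
#'   an ROI with its local background rather than two ROI interiors, so an
#'   SNR-derived merge threshold should not move it.
#' @param merge_start first sweep at which merging is considered (default
#'   1: every sweep). Freshly seeded contours still carry arbitrary mixed
#'   signal; with dense seeding it can help to let contours mature for a
#'   few sweeps (about one cell radius of travel) before interior
#'   correlations are trusted for merge decisions.
#' @return an object of class `seg_params`.
#' @examples
#' p <- seg_params(radius = 6, lambda = 1, metric = "correlation")
#' p$mu * p$delta_tau  # CFL number, < 0.25
#' @export
seg_params <- function(radius, lambda,
                       metric = c("euclidean", "correlation"),
                       delta_tau = 10,
                       mu = 0.2 / delta_tau,
                       epsilon = 2,
                       alpha = 0.5,
                       n_max = 100L,
                       n_con = 40L,
                       rho = 2,
                       min_area = 3,
                       max_area = 3 * pi * radius^2,
                       merge_threshold = 0.8,
                       snr_db = NULL,
                       narrowband_width = 2 * radius,
                       prune_undifferentiated = FALSE,
                       undiff_threshold = 0.8,
                       merge_start = 1L) {
  metric <- match.arg(metric)
  if (missing(radius) || !is.numeric(radius) || radius <= 0)
    stop_input("`radius` (expected cell radius, pixels) must be positive")
  if (missing(lambda) || !is.numeric(lambda))
    stop_input("`lambda` (external-energy weight) is required")
  if (mu * delta_tau >= 0.25)
    stop_input("CFL condition violated: mu * delta_tau = ",
               format(mu * delta_tau), " must be < 0.25")
  if (epsilon <= 0) stop_input("`epsilon` must be positive")
  if (min_area <= 0 || max_area <= min_area)
    stop_input("need 0 < min_area < max_area")
  if (narrowband_width <= 0) stop_input("`narrowband_width` must be positive")
  if (!is.null(snr_db)) merge_threshold <- merge_threshold_from_snr(snr_db)
  if (merge_threshold <= 0 || merge_threshold > 1)
    stop_input("`merge_threshold` must be in (0, 1]")
  if (undiff_threshold <= 0 || undiff_threshold > 1)
    stop_input("`undiff_threshold` must be in (0, 1]")
  structure(list(radius = radius, lambda = lambda, metric = metric,
                 delta_tau = delta_tau, mu = mu, epsilon = epsilon,
                 alpha = alpha, n_max = as.integer(n_max),
                 n_con = as.integer(n_con), rho = rho,
                 min_area = min_area, max_area = max_area,
                 merge_threshold = merge_threshold,
                 narrowband_width = narrowband_width,
                 prune_undifferentiated = prune_undifferentiated,
                 undiff_threshold = undiff_threshold,
                 merge_start = as.integer(merge_start)),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat("Coupled level-set segmentation parameters\n")
  cat(sprintf("  radius %g px, lambda %g, metric %s\n",
              x$radius, x$lambda, x$metric))
  cat(sprintf("  delta_tau %g, mu %g (CFL %g), epsilon %g px\n",
              x$delta_tau, x$mu, x$mu * x$delta_tau, x$epsilon))
  cat(sprintf("  sweeps: max %d, converged after %d quiet (< %g px change)\n",
              x$n_max, x$n_con, x$rho))
  cat(sprintf("  area bounds [%g, %g] px, merge threshold %.3f, narrowband %g px\n",
              x$min_area, x$max_area, x$merge_threshold, x$narrowband_width))
  invisible(x)
}

#' Merge-correlation threshold implied by a measured SNR
#'
#' Two disjoint pixel sets from the same cell share an underlying signal
#' but carry independent additive noise, so the correlation between their
#' average time courses is attenuated to
#' `1 / (1 + 10^(-snr_db / 10))`. ROIs whose interior time courses
#' correlate above this value are therefore indistinguishable from two
#' fragments of one cell and are merged. The function is strictly
#' increasing in `snr_db` and tends to 1 as SNR grows.
#'
#' @param snr_db signal-to-noise ratio of the time courses in decibels.
#' @return a threshold in `(0, 1)`.
#' @examples
#' merge_threshold_from_snr(0)   # 0.5
#' merge_threshold_from_snr(5)   # ~0.76
#' @export
merge_threshold_from_snr <- function(snr_db) {
  if (!is.numeric(snr_db) || !all(is.finite(snr_db)))
    stop_input("`snr_db` must be finite")
  1 / (1 + 10^(-snr_db / 10))
}
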