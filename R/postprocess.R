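#' Extract raw and neuropil time courses
#'
#' For each surviving ROI, the raw trace is the mean time course over its
#' interior and the neuropil trace the mean over its narrowband pixels
#' outside all interiors -- the same local background feature that guided
#' the contour, so neuropil correction comes as a by-product of the
#' segmentation.
#'
#' @param video a [video_stack()].
#' @param seg a `segmentation` object with at least one surviving ROI.
#' @return list with two `M x T` matrices, `raw` and `neuropil`, row names
#'   the ROI indices.
#' @export
extract_timecourses <- function(video, seg) {
  stopifnot(inherits(video, "video_stack"), inherits(seg, "segmentation"))
  alive <- seg_alive(seg)
  if (!length(alive)) stop_input("segmentation has no surviving ROIs")
  M <- pixel_matrix(video)
  raw <- t(vapply(alive, function(i)
    colMeans(M[which(seg$states[[i]]$interior), , drop = FALSE]),
    numeric(ncol(M))))
  np <- t(vapply(alive, function(i) {
    px <- seg$states[[i]]$narrowband & seg$n_in == 0L
    if (!any(px)) px <- seg$states[[i]]$narrowband
    colMeans(M[which(px), , drop = FALSE])
  }, numeric(ncol(M))))
  rownames(raw) <- rownames(np) <- alive
  list(raw = raw, neuropil = np)
}

#' Neuropil correction of a fluorescence trace
#'
#' Subtracts the weighted local neuropil trace from the raw cellular
#' trace: `corrected = raw - weight * neuropil`. The weight depends on the
#' imaging set-up and is deliberately user-supplied, never estimated; 0.7
#' is a common convention.
#'
#' @param raw numeric vector or `M x T` matrix of raw traces.
#' @param neuropil neuropil trace(s), same shape as `raw`.
#' @param weight scalar in `[0, 1]`.
#' @return corrected trace(s), same shape as `raw`.
#' @export
neuropil_correct <- function(raw, neuropil, weight = 0.7) {
  if (!identical(dim(raw), dim(neuropil)) ||
      length(raw) != length(neuropil))
    stop_input("`raw` and `neuropil` must have the same shape")
  if (!is.numeric(weight) || weight < 0 || weight > 1)
    stop_input("`weight` must be in [0, 1]")
  raw - weight * neuropil
}
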