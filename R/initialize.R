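# ROI seeding: automatic (extended maxima of summary images) or fixed grid,
# and construction of the initial signed-distance level set for each seed.

# Grayscale morphological reconstruction of `marker` under `mask` by
# iterated geodesic dilation (8-connected), run to stability.
grey_reconstruct <- function(marker, mask) {
  stopifnot(all(marker <= mask + 1e-12))
  cur <- pmin(marker, mask)
  repeat {
    dil <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      dil <- pmax(dil, shift_replicate(cur, dr, dc))
    }
    nxt <- pmin(dil, mask)
    if (identical(nxt, cur) || max(abs(nxt - cur)) == 0) return(nxt)
    cur <- nxt
  }
}

# Extended-maxima transform: regional maxima of the h-maxima of `img`.
# h is in absolute intensity units of img.
extended_maxima <- function(img, h) {
  stopifnot(h > 0)
  hmax <- grey_reconstruct(img - h, img)
  delta <- max(h * 1e-3, 1e-9)
  rec <- grey_reconstruct(hmax - delta, hmax)
  (hmax - rec) > delta / 2
}

#' Candidate ROIs from summary images
#'
#' Seeds initial ROI estimates automatically from the correlation image and
#' the mean-intensity image. Each image is thresholded by the
#' extended-maxima transform (h-maxima by morphological reconstruction with
#' `h = alpha * SD(image)`, followed by regional maxima), and every
#' surviving 8-connected component becomes a candidate. Seeding bright but
#' inactive structures from the mean image is deliberate: if left unseeded
#' they would contaminate the narrowband signal of genuine ROIs.
#'
#' Low `alpha` (0.2-0.8) over-seeds on purpose; redundant estimates are
#' merged or pruned automatically during contour evolution, and smaller
#' `alpha` also yields smaller seeds, reducing the risk of a single seed
#' spanning several cells. Mean-image candidates whose centroid lies within
#' `radius` of a correlation-image candidate are considered duplicates and
#' collapsed onto the latter. Candidates larger than `max_area` are
#' replaced by a disc of radius `radius` at their centroid so that a merged
#' blob of seeds is not instantly pruned.
#'
#' @param summaries a [summary_images()] object.
#' @param radius expected cell radius in pixels.
#' @param alpha peak selectivity in SD units of each summary image
#'   (`> 0`); higher is more conservative.
#' @param exclusion optional `H x W` logical mask; candidates touching it
#'   are discarded (e.g. electrodes or other artefacts).
#' @param max_area area above which a candidate is shrunk to a disc;
#'   defaults to the pruning bound `3 * pi * radius^2`.
#' @return a list of candidate masks (`H x W` logical, single 8-connected
#'   component each) with a `source` attribute, `"correlation_peak"` or
#'   `"mean_peak"`. Empty list (with a warning) if nothing is found.
#' @export
candidate_rois <- function(summaries, radius, alpha = 0.5, exclusion = NULL,
                           max_area = 3 * pi * radius^2) {
  stopifnot(inherits(summaries, "summary_images"))
  if (!is.numeric(alpha) || alpha <= 0) stop_input("`alpha` must be > 0")
  harvest <- function(img, source) {
    s <- stats::sd(img)
    if (s == 0) return(list())
    lab <- label8(extended_maxima(img, alpha * s))
    n <- max(lab)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      m <- lab == i
      attr(m, "source") <- source
      out[[i]] <- m
    }
    out
  }
  cand <- c(harvest(summaries$correlation_image, "correlation_peak"),
            harvest(summaries$mean_image, "mean_peak"))
  if (!is.null(exclusion)) {
    keep <- vapply(cand, function(m) !any(m & exclusion), logical(1))
    cand <- cand[keep]
  }
  if (length(cand)) {
    cents <- t(vapply(cand, mask_centroid, numeric(2)))
    src <- vapply(cand, function(m) attr(m, "source"), character(1))
    # collapse mean-image duplicates onto the correlation-image candidate
    drop <- rep(FALSE, length(cand))
    ci <- which(src == "correlation_peak")
    for (j in which(src == "mean_peak")) {
      if (length(ci) &&
          min(sqrt((cents[ci, 1] - cents[j, 1])^2 +
                   (cents[ci, 2] - cents[j, 2])^2)) < radius)
        drop[j] <- TRUE
    }
    cand <- cand[!drop]
    # oversized seeds become a disc of the expected radius at the centroid
    cand <- lapply(cand, function(m) {
      if (sum(m) > max_area) {
        d <- disc_mask(nrow(m), ncol(m), mask_centroid(m), radius)
        attr(d, "source") <- attr(m, "source")
        d
      } else m
    })
  }
  if (!length(cand)) warning("no candidate ROIs found")
  cand
}

#' Candidate ROIs on a fixed grid
#'
#' Seeds discs of radius `disc_radius` on a regular lattice. A grid covers
#' the whole field so no cell is missed for want of a seed; seeds landing
#' on background shrink or merge away during evolution.
#'
#' @param shape integer vector `(H, W)`.
#' @param spacing lattice spacing in pixels; must exceed `2 * disc_radius`
#'   so seeds start disjoint.
#' @param disc_radius radius of each seed disc in pixels.
#' @return list of candidate masks with `source = "grid"`.
#' @export
grid_init <- function(shape, spacing, disc_radius) {
  stopifnot(length(shape) == 2L)
  if (spacing <= 2 * disc_radius)
    stop_input("`spacing` must exceed 2 * disc_radius")
  h <- shape[1]; w <- shape[2]
  lattice <- function(n) {
    start <- ceiling(spacing / 2)
    if (start > n) round(n / 2) else seq(start, n, by = spacing)
  }
  rows <- lattice(h)
  cols <- lattice(w)
  out <- list()
  for (r in rows) for (cc in cols) {
    m <- disc_mask(h, w, c(r, cc), disc_radius)
    if (!any(m)) next
    attr(m, "source") <- "grid"
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Initial level set for a candidate ROI
#'
#' Builds the signed Euclidean distance field `phi` of a candidate mask:
#' positive inside the interior, negative outside, with `|grad phi| = 1` --
#' the canonical well-conditioned shape that the distance regularizer
#' preserves during evolution. The narrowband, the annular exterior within
#' `narrowband_width` (default twice the expected cell radius) of the
#' interior, supplies the local background feature.
#'
#' @param mask `H x W` logical candidate interior (non-empty).
#' @param radius expected cell radius in pixels.
#' @param narrowband_width narrowband width in pixels (default `2*radius`).
#' @return an object of class `level_set_state`: list with `phi`,
#'   `interior`, `narrowband`, convergence bookkeeping and `status`
#'   (`"active"`).
#' @export
init_level_set <- function(mask, radius, narrowband_width = 2 * radius) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop_input("candidate mask is empty")
  phi <- signed_distance(mask)
  state <- list(phi = phi,
                interior = mask & TRUE,  # strip attributes
                narrowband = narrowband_of(mask, narrowband_width),
                stable_iters = 0L,
                sweeps = 0L,
                converged_sweep = NA_integer_,
                status = "active",
                f_in = NULL)
  class(state) <- "level_set_state"
  state
}

# Signed Euclidean distance: + distance-to-exterior inside, - distance-to-
# interior outside (discrete pixel-centre convention).
signed_distance <- function(mask) {
  storage.mode(mask) <- "integer"
  din <- unclass(EBImage::distmap(mask))
  din - dist_to_mask(mask)
}

# Distance of every pixel to the nearest mask pixel (0 on the mask itself);
# a mask-less field is "infinitely" far everywhere.
dist_to_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L))
    return(matrix(sqrt(sum(dim(mask)^2)) + 1, nrow(mask), ncol(mask)))
  unclass(EBImage::distmap(1L - mask))
}

# Exterior pixels within `width` of the interior.
narrowband_of <- function(interior, width) {
  if (!any(interior)) return(interior & FALSE)
  !interior & dist_to_mask(interior) <= width
}

#' @export
print.level_set_state <- function(x, ...) {
  cat(sprintf("Level set state [%s]: interior %d px, narrowband %d px\n",
              x$status, sum(x$interior), sum(x$narrowband)))
  invisible(x)
}
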