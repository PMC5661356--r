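#' Segment a calcium imaging video
#'
#' The main fitting function: detects ROIs (somata, neurites) in a
#' fluorescence video by evolving one active contour per seed under the
#' activity-based external energy, with overlap-aware coupling, merging
#' and pruning, then extracts per-ROI raw and neuropil time courses.
#'
#' Only two parameters need tuning per dataset: the expected cell
#' `radius` (pixels) and the external-energy weight `lambda`; `lambda`
#' must be large enough to beat the regularizer's bias toward smooth
#' contours but not so large that the evolution overshoots. Use the
#' `"correlation"` metric for indicators with uneven brightness (donut
#' cells); the default `"euclidean"` metric also uses magnitude.
#'
#' @param video a [video_stack()], a `T x H x W` array, or a file path
#'   accepted by [read_video()].
#' @param radius expected cell radius in pixels.
#' @param lambda external-energy weight.
#' @param metric dissimilarity metric, `"euclidean"` or `"correlation"`.
#' @param init seeding: `"auto"` (extended maxima of the correlation and
#'   mean images), `"grid"` (fixed lattice of discs), or a list of
#'   `H x W` logical seed masks.
#' @param alpha seeding selectivity for `init = "auto"` (SD units).
#' @param grid_spacing,grid_disc_radius lattice geometry for
#'   `init = "grid"`; defaults `2 * radius` and `radius / 2`.
#' @param exclusion optional `H x W` logical mask of forbidden areas
#'   (artefacts, electrodes); seeds touching it are discarded.
#' @param downsample temporal downsampling factor applied before
#'   segmentation (see [downsample_time()]).
#' @param params a full [seg_params()] object; when supplied it overrides
#'   `radius`, `lambda`, `metric` and `...`.
#' @param ... further arguments to [seg_params()] (e.g. `snr_db`,
#'   `merge_threshold`, `prune_undifferentiated`, `n_max`). Passing
#'   `snr_db = "auto"` measures the trace SNR of the working video with
#'   [estimate_trace_snr()] and derives the merge threshold from it via
#'   [merge_threshold_from_snr()].
#' @param verbose print per-sweep progress.
#' @return an object of class `caimseg`: list with `segmentation`,
#'   `traces` (`raw` and `neuropil` matrices), `summaries`, `params`,
#'   `n_candidates`, `downsample` and `call`. Methods: [print.caimseg()],
#'   [summary.caimseg()], [coef.caimseg()], [plot.caimseg()],
#'   [fitted.caimseg()].
#' @examples
#' \donttest{
#' sim <- simulate_video(synth_spec(H = 40, W = 40, T = 120, n_cells = 1,
#'                                  overlap_fraction = 0, noise_sd = 20,
#'                                  seed = 7))
#' fit <- caimseg(sim$video, radius = 6, lambda = 2, metric = "correlation")
#' coef(fit)
#' }
#' @export
caimseg <- function(video, radius, lambda,
                    metric = c("euclidean", "correlation"),
                    init = "auto", alpha = 0.5,
                    grid_spacing = 2 * radius,
                    grid_disc_radius = radius / 2,
                    exclusion = NULL, downsample = 1L,
                    params = NULL, ..., verbose = FALSE) {
  cl <- match.call()
  if (is.character(video)) video <- read_video(video)
  if (is.array(video) && !inherits(video, "video_stack"))
    video <- video_stack(video)
  stopifnot(inherits(video, "video_stack"))
  if (downsample > 1L) video <- downsample_time(video, downsample)
  if (is.null(params)) {
    metric <- match.arg(metric)
    extra <- list(...)
    if (identical(extra$snr_db, "auto")) {
      # measure the trace SNR on the working (downsampled) video at the
      # seeding scale, and let it set the merge threshold
      extra$snr_db <- estimate_trace_snr(video,
                                         n_pixels = pi * (radius / 2)^2)
    }
    params <- do.call(seg_params,
                      c(list(radius = radius, lambda = lambda,
                             metric = metric, alpha = alpha), extra))
  }
  stopifnot(inherits(params, "seg_params"))

  summaries <- summary_images(video)
  candidates <- if (is.list(init)) {
    lapply(init, function(m) {
      m <- m > 0
      attr(m, "source") <- "user"
      m
    })
  } else if (identical(init, "auto")) {
    candidate_rois(summaries, radius = params$radius, alpha = params$alpha,
                   exclusion = exclusion, max_area = params$max_area)
  } else if (identical(init, "grid")) {
    g <- grid_init(field_dim(video), grid_spacing, grid_disc_radius)
    if (!is.null(exclusion))
      g <- Filter(function(m) !any(m & exclusion), g)
    g
  } else stop_input("`init` must be \"auto\", \"grid\" or a list of masks")
  if (!length(candidates)) stop_input("initialization produced no seeds")

  seg <- segment_video(video, candidates, params, verbose = verbose)
  traces <- if (length(seg_alive(seg))) extract_timecourses(video, seg)
            else list(raw = NULL, neuropil = NULL)
  structure(list(segmentation = seg, traces = traces, summaries = summaries,
                 params = params, n_candidates = length(candidates),
                 downsample = downsample, frame_rate = video$frame_rate,
                 call = cl),
            class = "caimseg")
}

#' @export
print.caimseg <- function(x, ...) {
  st <- vapply(x$segmentation$states, `[[`, character(1), "status")
  cat("Activity-based level-set segmentation\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d ROI(s) from %d seed(s) after %d sweep(s)",
              sum(st %in% c("active", "converged")), x$n_candidates,
              x$segmentation$sweeps_run))
  extra <- table(st[st %in% c("pruned", "merged")])
  if (length(extra))
    cat(" (", paste(sprintf("%d %s", extra, names(extra)), collapse = ", "),
        ")", sep = "")
  cat("\n")
  invisible(x)
}

#' ROI table of a segmentation fit
#'
#' One row per seed with its final status, interior centroid, area and
#' the sweep at which it converged (`NA` if it never did).
#'
#' @param object a `caimseg` fit.
#' @param ... unused.
#' @return a data frame with columns `roi`, `status`, `row`, `col`,
#'   `area`, `converged_sweep`.
#' @export
coef.caimseg <- function(object, ...) {
  seg <- object$segmentation
  rows <- lapply(seq_along(seg$states), function(i) {
    st <- seg$states[[i]]
    alive <- st$status %in% c("active", "converged")
    ctr <- if (alive && any(st$interior)) mask_centroid(st$interior)
           else c(NA_real_, NA_real_)
    data.frame(roi = i, status = st$status, row = ctr[1], col = ctr[2],
               area = if (alive) sum(st$interior) else NA_integer_,
               converged_sweep = st$converged_sweep)
  })
  do.call(rbind, rows)
}

#' @export
summary.caimseg <- function(object, ...) {
  tab <- coef(object)
  alive <- tab[tab$status %in% c("active", "converged"), , drop = FALSE]
  out <- list(rois = alive, all = tab,
              sweeps = object$segmentation$sweeps_run,
              params = object$params,
              n_candidates = object$n_candidates)
  class(out) <- "summary.caimseg"
  out
}

#' @export
print.summary.caimseg <- function(x, ...) {
  cat(sprintf("Segmentation of %d seed(s): %d surviving ROI(s), %d sweep(s)\n",
              x$n_candidates, nrow(x$rois), x$sweeps))
  print(x$params)
  if (nrow(x$rois)) {
    cat("Surviving ROIs:\n")
    print(x$rois, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extracted raw traces of a fit
#'
#' @param object a `caimseg` fit.
#' @param ... unused.
#' @return the `M x T` matrix of raw interior time courses.
#' @export
fitted.caimseg <- function(object, ...) object$traces$raw

#' Plot detected contours over a summary image
#'
#' @param x a `caimseg` fit.
#' @param image which summary image to use as backdrop.
#' @param col contour colour.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.caimseg <- function(x, image = c("correlation", "mean", "max"),
                         col = "red", ...) {
  image <- match.arg(image)
  img <- switch(image,
                correlation = x$summaries$correlation_image,
                mean = x$summaries$mean_image,
                max = x$summaries$max_image)
  h <- nrow(img); w <- ncol(img)
  graphics::image(x = seq_len(w), y = seq_len(h), z = t(img)[, h:1],
                  col = grDevices::gray.colors(256), xlab = "col",
                  ylab = "row", useRaster = TRUE, ...)
  seg <- x$segmentation
  for (i in seg_alive(seg)) {
    m <- seg$states[[i]]$interior
    graphics::contour(x = seq_len(w), y = seq_len(h),
                      z = t(m * 1)[, h:1], levels = 0.5,
                      drawlabels = FALSE, add = TRUE, col = col)
  }
  invisible(x)
}

#' Surviving ROI masks of a fit
#'
#' @param fit a `caimseg` fit or `segmentation`.
#' @return named list of `H x W` logical interiors (names = seed index).
#' @export
roi_masks <- function(fit) {
  seg <- if (inherits(fit, "caimseg")) fit$segmentation else fit
  stopifnot(inherits(seg, "segmentation"))
  alive <- seg_alive(seg)
  stats::setNames(lapply(alive, function(i) seg$states[[i]]$interior),
                  alive)
}

#' Write segmentation outputs to a directory
#'
#' Writes the surviving ROI masks as a multi-page TIFF (one page per ROI,
#' page order = ROI id order), a JSON index with id, centroid, area and
#' status, the raw and neuropil traces as CSV (one row per ROI, one
#' column per frame), and the parameters as YAML.
#'
#' @param fit a `caimseg` fit.
#' @param dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_segmentation <- function(fit, dir) {
  stopifnot(inherits(fit, "caimseg"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  masks <- roi_masks(fit)
  paths <- character(0)
  if (length(masks)) {
    p <- file.path(dir, "roi_masks.tif")
    write_float_tiff(lapply(masks, function(m) m * 1), p)
    paths <- c(paths, p)
  }
  tab <- coef(fit)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "rois.json")
    jsonlite::write_json(tab, p, dataframe = "rows", na = "null",
                         digits = NA)
    paths <- c(paths, p)
  }
  for (kind in c("raw", "neuropil")) {
    tr <- fit$traces[[kind]]
    if (is.null(tr)) next
    p <- file.path(dir, paste0("traces_", kind, ".csv"))
    utils::write.csv(as.data.frame(tr), p, row.names = TRUE)
    paths <- c(paths, p)
  }
  if (requireNamespace("yaml", quietly = TRUE)) {
    p <- file.path(dir, "config.yaml")
    writeLines(yaml::as.yaml(unclass(fit$params)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
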