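#' Construct a video stack
#'
#' A `video_stack` holds a fluorescence video as a `T x H x W` array of
#' non-negative intensities (frame, row, column), optionally with the
#' acquisition frame rate. Every pixel `x` carries a length-`T` time course
#' `I(x)`, the basic object the segmentation model operates on.
#'
#' @param data numeric array of dimension `T x H x W`; all values finite.
#' @param frame_rate optional acquisition rate in Hz. Only required when
#'   spike-time metrics or the transient kernel need a time axis.
#' @return an object of class `video_stack` with elements `data` and
#'   `frame_rate`.
#' @examples
#' v <- video_stack(array(1, dim = c(4, 8, 8)))
#' dim(v$data)
#' @export
video_stack <- function(data, frame_rate = NULL) {
  if (length(dim(data)) != 3L)
    stop_input("`data` must be a 3-D array (frame, row, col)")
  if (!all(is.finite(data)))
    stop_input("video intensities must all be finite")
  d <- dim(data)
  if (d[2] < 3L || d[3] < 3L)
    stop_input("video frames must be at least 3 x 3 pixels")
  if (!is.null(frame_rate) && (!is.numeric(frame_rate) || frame_rate <= 0))
    stop_input("`frame_rate` must be a positive number (Hz)")
  structure(list(data = data, frame_rate = frame_rate),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Calcium imaging video: %d frames of %d x %d pixels\n",
              d[1], d[2], d[3]))
  if (!is.null(x$frame_rate))
    cat(sprintf("  frame rate: %g Hz (%.1f s)\n", x$frame_rate,
                d[1] / x$frame_rate))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$data)

n_frames <- function(video) dim(video$data)[1]

field_dim <- function(video) dim(video$data)[2:3]

# Video as an (H*W) x T pixel-by-time matrix; pixel p = (col-1)*H + row,
# matching R's column-major linearisation of an H x W mask.
pixel_matrix <- function(video) {
  d <- dim(video$data)
  matrix(aperm(video$data, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
}

#' Read a fluorescence video
#'
#' Reads a multi-page grayscale TIFF or an HDF5 dataset into a
#' [video_stack()]. Intensities are passed through unchanged (no
#' normalisation); frames are ordered (frame, row, col).
#'
#' @param path path to a `.tif`/`.tiff` or `.h5`/`.hdf5` file.
#' @param dataset name of the 3-D dataset for HDF5 input; ignored for TIFF.
#' @param frame_rate optional frame rate in Hz attached to the result.
#' @return a [video_stack()].
#' @seealso [write_video()]
#' @export
read_video <- function(path, dataset = NULL, frame_rate = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # as.is = TRUE returns integer samples unscaled; it is rejected for
    # float images, which readTIFF already returns as stored
    pages <- tryCatch(
      tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
               error = function(e) tiff::readTIFF(path, all = TRUE)),
      error = function(e)
        stop_input("unreadable TIFF file: ", conditionMessage(e)))
    if (is.matrix(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1] else p  # collapse spurious channels
    })
    d <- dim(pages[[1]])
    arr <- array(NA_real_, dim = c(length(pages), d[1], d[2]))
    for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  } else if (ext %in% c("h5", "hdf5")) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop_input("reading HDF5 requires the rhdf5 package")
    if (is.null(dataset)) {
      ls <- rhdf5::h5ls(path)
      cand <- ls$name[ls$otype == "H5I_DATASET"]
      if (length(cand) != 1L)
        stop_input("HDF5 file has ", length(cand),
                   " datasets; name one via `dataset`")
      dataset <- cand
    }
    arr <- rhdf5::h5read(path, dataset)
    if (length(dim(arr)) != 3L)
      stop_input("HDF5 dataset must be 3-D (frame, row, col)")
    arr <- aperm(arr, 3:1)  # h5 stores column-major (col, row, frame)
  } else {
    stop_input("unsupported video format: .", ext)
  }
  video_stack(arr, frame_rate = frame_rate)
}

#' Write a fluorescence video
#'
#' Writes a [video_stack()] as a multi-page 32-bit float TIFF, or to an HDF5
#' dataset when the path ends in `.h5`/`.hdf5`. Round trips are lossless at
#' the stored (single) precision for TIFF and exact for HDF5.
#'
#' @param video a [video_stack()].
#' @param path output file path.
#' @param dataset HDF5 dataset name (default `"video"`).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, dataset = "video") {
  stopifnot(inherits(video, "video_stack"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop_input("writing HDF5 requires the rhdf5 package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    # store (col, row, frame) so h5read + aperm round-trips
    rhdf5::h5write(aperm(video$data, 3:1), path, dataset)
    rhdf5::H5close()
  } else {
    pages <- lapply(seq_len(n_frames(video)),
                    function(t) video$data[t, , ])
    write_float_tiff(pages, path)
  }
  invisible(path)
}

#' Average consecutive frames of a video
#'
#' Temporal downsampling by a factor `k`: output frame `j` is the mean of
#' input frames `(j-1)k + 1, ..., jk`; a trailing remainder shorter than `k`
#' is dropped so every output sample is an equal-weight mean. Averaging
#' raises the per-pixel SNR by about `sqrt(k)` and shortens long recordings
#' before segmentation, which the contour evolution is insensitive to
#' because it assumes no stereotyped temporal waveform.
#'
#' @param video a [video_stack()].
#' @param k positive integer downsampling factor; `k = 1` is the identity.
#' @return a [video_stack()] with `floor(T/k)` frames; the frame rate, when
#'   present, is divided by `k`.
#' @export
downsample_time <- function(video, k) {
  stopifnot(inherits(video, "video_stack"))
  k <- as.integer(k)
  if (k < 1L) stop_input("`k` must be a positive integer")
  T0 <- n_frames(video)
  if (k > T0) stop_input("`k` exceeds the number of frames (", T0, ")")
  if (k == 1L) return(video)
  Tn <- T0 %/% k
  d <- dim(video$data)
  kept <- video$data[seq_len(Tn * k), , , drop = FALSE]
  dim(kept) <- c(k, Tn, d[2], d[3])
  out <- colMeans(kept)  # averages over the first extent (the k block)
  video_stack(out, frame_rate = if (is.null(video$frame_rate)) NULL
              else video$frame_rate / k)
}

#' Summary images of a video
#'
#' Computes the three 2-D summaries used for seeding and reporting: the
#' temporal mean image, the temporal maximum image, and the correlation
#' image. The correlation image at a pixel is the average Pearson
#' correlation between that pixel's time course and the time courses of its
#' 8-connected neighbours; border pixels average over their existing
#' neighbours, and a pixel with a constant (zero-variance) time course
#' contributes correlation 0, a neutral value that stops dead pixels from
#' seeding ROIs. Coherent cellular activity shows up as local peaks in the
#' correlation image regardless of brightness.
#'
#' @param video a [video_stack()] with at least 2 frames.
#' @return an object of class `summary_images`: list with `mean_image`,
#'   `max_image` and `correlation_image`, each `H x W`.
#' @export
summary_images <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  if (n_frames(video) < 2L)
    stop_input("the correlation image needs at least 2 frames")
  d <- dim(video$data)
  hw <- field_dim(video)
  M <- pixel_matrix(video)
  mean_img <- matrix(rowMeans(M), hw[1], hw[2])
  max_img <- matrix(do.call(pmax, lapply(seq_len(d[1]), function(t) M[, t])),
                    hw[1], hw[2])

  # standardise each pixel's time course; zero-variance rows become all-zero
  # so their correlation with anything is the fallback value 0
  ctr <- M - rowMeans(M)
  nrm <- sqrt(rowSums(ctr^2))
  Z <- ctr / ifelse(nrm > 0, nrm, 1)
  Zarr <- array(Z, dim = c(hw[1], hw[2], d[1]))

  acc <- matrix(0, hw[1], hw[2])
  cnt <- matrix(0, hw[1], hw[2])
  ones <- matrix(1, hw[1], hw[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    dot <- matrix(0, hw[1], hw[2])
    for (t in seq_len(d[1]))
      dot <- dot + Zarr[, , t] * shift_pad(Zarr[, , t], dr, dc, fill = 0)
    acc <- acc + dot
    cnt <- cnt + shift_pad(ones, dr, dc, fill = 0)
  }
  corr_img <- acc / cnt

  structure(list(mean_image = mean_img, max_image = max_img,
                 correlation_image = corr_img),
            class = "summary_images")
}

#' @export
print.summary_images <- function(x, ...) {
  cat(sprintf("Summary images (%d x %d): mean, max, correlation\n",
              nrow(x$mean_image), ncol(x$mean_image)))
  cat(sprintf("  correlation image range: [%.3f, %.3f]\n",
              min(x$correlation_image), max(x$correlation_image)))
  invisible(x)
}

#' Write summary images to single-page float TIFFs
#'
#' @param summaries a [summary_images()] object.
#' @param dir output directory (created if missing).
#' @return character vector of the three file paths, invisibly.
#' @export
write_summary_images <- function(summaries, dir) {
  stopifnot(inherits(summaries, "summary_images"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("mean.tif", "max.tif", "correlation.tif"))
  imgs <- list(summaries$mean_image, summaries$max_image,
               summaries$correlation_image)
  for (i in 1:3) write_float_tiff(imgs[[i]], paths[i])
  invisible(paths)
}
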