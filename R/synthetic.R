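# Seeded generator of ground-truthed calcium imaging videos.
#
# Cells are donut-shaped discs whose temporal activity is a stationary
# uniform baseline plus a Poisson spike train convolved with a stereotyped
# calcium transient; pixels in two cells sum both contributions. Non-cell
# pixels carry spatiotemporally varying background independent of the
# cells, and white Gaussian noise is added everywhere.

#' Specification of a synthetic calcium imaging video
#'
#' Collects every generative parameter; [simulate_video()] turns a spec
#' into a video plus ground truth. Defaults describe a 128 x 128, 30 s,
#' 10 Hz recording of 25 cells of radius 6 px, 17 of which overlap a
#' neighbour, with transient amplitude 100 a.u. and noise SD 60 -- a
#' moderate-noise overlapping-cell benchmark.
#'
#' @param H,W field size in pixels.
#' @param T number of frames.
#' @param frame_rate acquisition rate, Hz.
#' @param n_cells number of cells.
#' @param cell_radius expected cell radius, pixels; each cell's actual
#'   radius is jittered by up to `radius_jitter` relative.
#' @param overlap_fraction fraction of cells that overlap some neighbour;
#'   overlapping cells are laid out in pairs (plus one triple when the
#'   count is odd) with centre distance 1.5 radii.
#' @param spike_rate Poisson firing rate per cell, Hz.
#' @param amplitude calcium transient peak amplitude, a.u.
#' @param decay transient exponential decay constant, seconds.
#' @param baseline range (low, high) of the uniform stationary baseline.
#' @param donut_attenuation intensity factor at the cell centre relative
#'   to its boundary, in `[0, 1]`; 1 gives a uniform (non-donut) disc.
#' @param background_scale spatial correlation scale of the background
#'   fields, pixels.
#' @param background_amplitude amplitude of the background's temporal
#'   modulation, a.u.
#' @param noise_sd SD of the additive white Gaussian noise, a.u.
#' @param radius_jitter relative cell-radius jitter.
#' @param centers optional `n_cells x 2` matrix of (row, col) centres
#'   overriding the automatic layout.
#' @param seed RNG seed; identical spec and seed give a bit-identical
#'   video.
#' @return an object of class `synth_spec`.
#' @seealso [demix25_spec()] for the 25-cell benchmark preset.
#' @export
synth_spec <- function(H = 128, W = 128, T = 300, frame_rate = 10,
                       n_cells = 25, cell_radius = 6,
                       overlap_fraction = 17 / 25,
                       spike_rate = 0.5, amplitude = 100, decay = 1,
                       baseline = c(20, 50), donut_attenuation = 0.3,
                       background_scale = 4 * cell_radius,
                       background_amplitude = 40, noise_sd = 60,
                       radius_jitter = 0.15, centers = NULL, seed = 1) {
  stopifnot(H >= 3, W >= 3, T >= 2, frame_rate > 0, n_cells >= 1,
            cell_radius > 0, overlap_fraction >= 0, overlap_fraction <= 1,
            spike_rate >= 0, amplitude > 0, decay > 0,
            length(baseline) == 2, baseline[1] <= baseline[2],
            donut_attenuation >= 0, donut_attenuation <= 1,
            background_scale > 0, background_amplitude >= 0, noise_sd >= 0,
            radius_jitter >= 0, radius_jitter < 1)
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n_cells, ncol(centers) == 2)
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' The 25-cell overlapping benchmark preset
#'
#' 25 donut cells, 17 with some overlap, transient amplitude 100 a.u.,
#' on a 128 x 128 field -- the configuration used to measure demixing
#' performance across noise levels.
#'
#' @param noise_sd noise SD in a.u. (60 is the moderate-noise regime).
#' @param seed RNG seed.
#' @param ... further arguments passed to [synth_spec()].
#' @return a `synth_spec`.
#' @export
demix25_spec <- function(noise_sd = 60, seed = 1, ...) {
  synth_spec(noise_sd = noise_sd, seed = seed, ...)
}

#' Homogeneous Poisson spike train
#'
#' @param rate firing rate in Hz (`>= 0`).
#' @param duration recording length in seconds.
#' @param seed optional seed; with `NULL` the current RNG stream is used.
#' @return sorted numeric vector of spike times in seconds.
#' @export
poisson_spike_train <- function(rate, duration, seed = NULL) {
  stopifnot(rate >= 0, duration >= 0)
  with_seed(seed, {
    n <- stats::rpois(1L, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
}

#' Stereotyped calcium transient kernel
#'
#' Causal single-exponential pulse `A exp(-t / decay)` sampled at the
#' frame rate and truncated at five decay constants. The segmentation
#' itself is shape-agnostic; the kernel only defines the simulated
#' indicator response.
#'
#' @param amplitude peak amplitude A, a.u.
#' @param decay decay constant, seconds.
#' @param frame_rate sampling rate, Hz.
#' @return numeric vector of kernel samples with attribute `times`.
#' @export
calcium_transient_kernel <- function(amplitude, decay, frame_rate) {
  stopifnot(amplitude > 0, decay > 0, frame_rate > 0)
  t <- seq(0, 5 * decay, by = 1 / frame_rate)
  k <- amplitude * exp(-t / decay)
  attr(k, "times") <- t
  k
}

#' Donut intensity profile of a cell mask
#'
#' Weight 1 on the boundary pixels of the mask, decreasing linearly with
#' distance from the boundary to `attenuation` at the innermost pixel --
#' mimicking indicators excluded from the nucleus. `attenuation = 1`
#' degenerates to a uniform disc.
#'
#' @param mask `H x W` logical cell mask (non-empty).
#' @param attenuation centre-to-boundary intensity ratio in `[0, 1]`.
#' @return `H x W` numeric weights in `[0, 1]`, zero outside the mask.
#' @export
donut_profile <- function(mask, attenuation) {
  if (!any(mask)) stop_input("cell mask is empty")
  stopifnot(attenuation >= 0, attenuation <= 1)
  storage.mode(mask) <- "integer"
  depth <- unclass(EBImage::distmap(mask))   # distance to exterior
  w <- matrix(0, nrow(mask), ncol(mask))
  inside <- mask == 1L
  dmin <- min(depth[inside]); dmax <- max(depth[inside])
  w[inside] <- if (dmax > dmin)
    1 - (1 - attenuation) * (depth[inside] - dmin) / (dmax - dmin)
  else 1
  w
}

# Deterministic seeded layout: overlapping cells as pairs (one triple when
# the overlap count is odd) and singles, on a jittered anchor lattice.
place_cells <- function(spec) {
  n <- spec$n_cells
  r <- spec$cell_radius
  k <- round(n * spec$overlap_fraction)
  if (k == 1) k <- 2
  n_triple <- k %% 2
  n_pair <- (k - 3 * n_triple) / 2
  n_single <- n - k
  groups <- c(rep(3, n_triple), rep(2, n_pair), rep(1, n_single))
  g <- ceiling(sqrt(length(groups)))
  d <- 1.5 * r                               # overlapping centre distance
  # a 3-cluster is an open chain (120 degrees at the middle cell): each
  # neighbour pair overlaps but the two ends stay clear, so no pixel ever
  # lies in more than two cells -- overlap contributions are pairwise sums
  # per-cluster half-extent (centres measured from the cluster centroid)
  # incl. radius jitter and 2 px of anchor jitter; anchors sit at least
  # the widest extent from the border, and any two adjacent clusters need
  # the sum of the two largest extents that can meet between them
  exts <- ifelse(groups >= 3, 0.882 * d, ifelse(groups == 2, d / 2, 0)) +
    r * (1 + spec$radius_jitter) + 2
  margin <- max(exts)
  srt <- sort(exts, decreasing = TRUE)
  need <- if (length(srt) > 1) srt[1] + srt[2] else 0
  if (g > 1) {
    sp <- (min(spec$H, spec$W) - 2 * margin) / (g - 1)
    if (sp < need)
      stop_input("impossible placement: ", n, " cells of radius ", r,
                 " do not fit a ", spec$H, " x ", spec$W, " field")
  } else if (2 * margin > min(spec$H, spec$W)) {
    stop_input("impossible placement: cell radius ", r,
               " too large for a ", spec$H, " x ", spec$W, " field")
  }
  anchors_r <- if (g > 1) seq(margin, spec$H - margin, length.out = g)
               else spec$H / 2
  anchors_c <- if (g > 1) seq(margin, spec$W - margin, length.out = g)
               else spec$W / 2
  anchors <- as.matrix(expand.grid(anchors_r, anchors_c))
  slots <- sample(nrow(anchors), length(groups))
  centres <- NULL
  for (gi in seq_along(groups)) {
    a <- anchors[slots[gi], ] + stats::runif(2, -2, 2)
    th <- stats::runif(1, 0, 2 * pi)
    pts <- switch(groups[gi],
      `1` = rbind(a),
      `2` = rbind(a + d / 2 * c(cos(th), sin(th)),
                  a - d / 2 * c(cos(th), sin(th))),
      `3` = {
        # open chain centred on its centroid: middle cell plus two arms
        # at 120 degrees; consecutive centres d apart, ends > 2r apart
        mid <- a - d / 3 * c(cos(th + pi / 3), sin(th + pi / 3))
        rbind(mid,
              mid + d * c(cos(th), sin(th)),
              mid + d * c(cos(th + 2 * pi / 3), sin(th + 2 * pi / 3)))
      })
    centres <- rbind(centres, pts)
  }
  list(centres = centres,
       radii = r * (1 + stats::runif(n, -spec$radius_jitter,
                                     spec$radius_jitter)),
       overlapping = rep(groups >= 2, groups))
}

# Separable Gaussian smoothing with edge renormalisation.
gaussian_smooth <- function(m, sigma) {
  smooth_1d <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K / rowSums(K)
  }
  smooth_1d(nrow(m)) %*% m %*% t(smooth_1d(ncol(m)))
}

#' Simulate a calcium imaging video with ground truth
#'
#' Generates cells, activity, background and noise from a [synth_spec()]:
#' each cell's temporal activity is `baseline + spikes (*) transient`,
#' scaled per pixel by its donut weight; overlap pixels receive the sum of
#' both cells' contributions; non-cell pixels carry a background
#' `static field + amplitude * gain(x) * modulation(t)` generated
#' independently of the cells (smooth spatial fields at the spec's
#' background scale, slow temporal modulation of unit SD); white Gaussian
#' noise of SD `noise_sd` is added everywhere.
#'
#' @param spec a [synth_spec()].
#' @return an object of class `synthetic_video`: list with `video` (a
#'   [video_stack()]) and `truth`, a `ground_truth` list carrying per-cell
#'   masks, centres, spike trains, pixel weight maps, activity traces, the
#'   background components, and the exact noiseless video
#'   (`noiseless = sum of cells + background`).
#' @export
simulate_video <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    if (is.null(spec$centers)) {
      pl <- place_cells(spec)
    } else {
      pl <- list(centres = spec$centers,
                 radii = spec$cell_radius *
                   (1 + stats::runif(n, -spec$radius_jitter,
                                     spec$radius_jitter)),
                 overlapping = rep(NA, n))
    }
    masks <- lapply(seq_len(n), function(i)
      disc_mask(spec$H, spec$W, pl$centres[i, ], pl$radii[i]))
    if (any(!vapply(masks, any, logical(1))))
      stop_input("impossible placement: a cell fell outside the field")
    weights <- lapply(masks, donut_profile,
                      attenuation = spec$donut_attenuation)

    duration <- spec$T / spec$frame_rate
    kern <- calcium_transient_kernel(spec$amplitude, spec$decay,
                                     spec$frame_rate)
    baselines <- stats::runif(n, spec$baseline[1], spec$baseline[2])
    spikes <- lapply(seq_len(n), function(i)
      poisson_spike_train(spec$spike_rate, duration))
    activity <- matrix(0, n, spec$T)   # cellular temporal activity
    for (i in seq_len(n)) {
      counts <- tabulate(pmin(floor(spikes[[i]] * spec$frame_rate) + 1L,
                              spec$T), nbins = spec$T)
      padded <- c(rep(0, length(kern) - 1L), counts)
      conv <- stats::filter(padded, kern, method = "convolution", sides = 1)
      activity[i, ] <- baselines[i] +
        as.numeric(conv[length(kern):(length(kern) + spec$T - 1L)])
    }

    # background: static inhomogeneous offset + smooth gain x slow modulation
    base_field <- gaussian_smooth(matrix(stats::rnorm(spec$H * spec$W),
                                         spec$H, spec$W),
                                  spec$background_scale)
    base_field <- spec$baseline[1] +
      (spec$baseline[2] - spec$baseline[1]) * unit_range(base_field)
    gain_field <- 0.5 + 0.5 * unit_range(
      gaussian_smooth(matrix(stats::rnorm(spec$H * spec$W), spec$H, spec$W),
                      spec$background_scale))
    modulation <- gaussian_smooth(matrix(stats::rnorm(spec$T), ncol = 1),
                                  2 * spec$frame_rate)
    modulation <- as.numeric(scale(modulation))

    # assemble noiseless video as pixel x time, then add noise
    hw <- spec$H * spec$W
    cellpix <- Reduce(`|`, masks)
    noiseless <- matrix(0, hw, spec$T)
    bg_idx <- which(!cellpix)
    noiseless[bg_idx, ] <- base_field[bg_idx] +
      spec$background_amplitude * outer(gain_field[bg_idx], modulation)
    for (i in seq_len(n)) {
      idx <- which(masks[[i]])
      noiseless[idx, ] <- noiseless[idx, ] +
        outer(weights[[i]][idx], activity[i, ])
    }
    noisy <- noiseless + stats::rnorm(length(noiseless), sd = spec$noise_sd)

    to_stack <- function(m) aperm(array(m, dim = c(spec$H, spec$W, spec$T)),
                                  c(3, 1, 2))
    truth <- structure(
      list(masks = masks, centres = pl$centres, radii = pl$radii,
           overlapping = pl$overlapping, spikes = spikes,
           weights = weights, baselines = baselines, activity = activity,
           background = list(base_field = base_field,
                             gain_field = gain_field,
                             modulation = modulation,
                             amplitude = spec$background_amplitude),
           noiseless = to_stack(noiseless),
           noise_sd = spec$noise_sd, seed = spec$seed),
      class = "ground_truth")
    structure(list(video = video_stack(to_stack(noisy),
                                       frame_rate = spec$frame_rate),
                   truth = truth, spec = spec),
              class = "synthetic_video")
  })
}

unit_range <- function(m) (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)

#' @export
print.synthetic_video <- function(x, ...) {
  cat(sprintf("Synthetic calcium video: %d cells, noise SD %g, seed %s\n",
              x$spec$n_cells, x$spec$noise_sd, format(x$spec$seed)))
  print(x$video)
  invisible(x)
}

#' Noise SD achieving a target per-pixel SNR
#'
#' Measures the temporal signal power of the noiseless cellular
#' contribution, averaged over all cell-interior pixels of a simulated
#' spec, and returns the white-noise SD at which the mean per-pixel SNR
#' equals `target_db` decibels.
#'
#' @param spec a [synth_spec()].
#' @param target_db target mean pixel SNR in dB.
#' @return noise SD in a.u.
#' @export
calibrate_noise_sd <- function(spec, target_db) {
  spec$noise_sd <- 0
  sim <- simulate_video(spec)
  M <- pixel_matrix(sim$video)
  idx <- which(Reduce(`|`, sim$truth$masks))
  pw <- mean(apply(M[idx, , drop = FALSE], 1, stats::var))
  sqrt(pw / snr_ratio(target_db))
}
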