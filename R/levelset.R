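# Coupled level-set evolution engine.
#
# Each ROI carries a level set field phi (positive inside, negative in the
# exterior narrowband). Per sweep, every active contour is updated in turn
# by the discretized gradient flow
#     phi <- phi - delta_tau * (lambda * dirac(phi) * V + mu * dR/dphi)
# where V is the data-driven external velocity and R the double-well
# distance regularizer. Contours are coupled only through the overlap map
# (which interiors contain a pixel), so evolution stays local.

#' Smoothed Dirac delta of a level set field
#'
#' Cosine approximation `(1/(2 eps)) (1 + cos(pi phi / eps))` for
#' `|phi| <= eps`, zero elsewhere. It localizes the external velocity to a
#' band of half-width `epsilon` pixels around the contour, so the data term
#' only ever needs evaluating near the boundary.
#'
#' @param phi numeric matrix (level set field).
#' @param epsilon band half-width in pixels.
#' @return matrix of the same shape, non-negative, integrating to ~1 across
#'   the contour.
#' @export
dirac_delta <- function(phi, epsilon) {
  stopifnot(epsilon > 0)
  out <- (1 + cos(pi * phi / epsilon)) / (2 * epsilon)
  out[abs(phi) > epsilon] <- 0
  out
}

#' Gradient of the distance regularizer
#'
#' Variational derivative `dR/dphi = -div(d_p(|grad phi|) grad phi)` of the
#' double-well distance-regularization energy, whose wells at gradient
#' magnitudes 0 and 1 keep `phi` flat far from the contour and
#' signed-distance-like near it, so no periodic re-initialization is
#' needed. Spatial derivatives are central differences with replicate
#' (Neumann) boundaries.
#'
#' @param phi numeric matrix.
#' @return matrix of the same shape; (approximately) zero wherever
#'   `|grad phi|` is 0 or 1.
#' @export
distreg_gradient <- function(phi) {
  gr <- (shift_replicate(phi, -1, 0) - shift_replicate(phi, 1, 0)) / 2
  gc <- (shift_replicate(phi, 0, -1) - shift_replicate(phi, 0, 1)) / 2
  s <- sqrt(gr^2 + gc^2)
  dp <- double_well_dp(s)
  fr <- dp * gr
  fc <- dp * gc
  div <- (shift_replicate(fr, -1, 0) - shift_replicate(fr, 1, 0)) / 2 +
         (shift_replicate(fc, 0, -1) - shift_replicate(fc, 0, 1)) / 2
  -div
}

# d_p(s) = p'(s)/s for the standard double-well potential with minima at
# s = 0 and s = 1; continuous limit d_p(0) = 1.
double_well_dp <- function(s) {
  out <- (s - 1) / ifelse(s > 0, s, 1)
  low <- s <= 1
  sl <- s[low]
  out[low] <- ifelse(sl > 1e-10, sin(2 * pi * sl) / (2 * pi * sl), 1)
  out
}

# potential itself, used only by descent tests
double_well_p <- function(s) {
  ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, (s - 1)^2 / 2)
}

# ---------------------------------------------------------------------------
# Segmentation container

new_segmentation <- function(states, shape, params) {
  n_in <- matrix(0L, shape[1], shape[2])
  for (st in states)
    if (st$status %in% c("active", "converged")) n_in <- n_in + st$interior
  structure(list(states = states, n_in = n_in, shape = shape,
                 params = params, sweeps_run = 0L,
                 events = list()),
            class = "segmentation")
}

seg_alive <- function(seg)
  which(vapply(seg$states, function(s) s$status %in% c("active", "converged"),
               logical(1)))

#' @export
print.segmentation <- function(x, ...) {
  st <- vapply(x$states, `[[`, character(1), "status")
  cat(sprintf("Segmentation: %d ROI(s) [%s] after %d sweep(s)\n",
              sum(st %in% c("active", "converged")),
              paste(sprintf("%s: %d", names(table(st)), table(st)),
                    collapse = ", "),
              x$sweeps_run))
  invisible(x)
}

# Engine-private precomputation bundle for a video.
make_engine <- function(video, params) {
  M <- pixel_matrix(video)
  prep <- NULL
  if (params$metric == "correlation") {
    ctr <- M - rowMeans(M)
    nrm <- sqrt(rowSums(ctr^2))
    prep <- list(ctr = ctr, nrm = nrm)
  }
  list(M = M, prep = prep, T = ncol(M), shape = field_dim(video))
}

# D(I(x), f) for a set of pixel indices against one feature vector.
eng_dissimilarity <- function(eng, idx, f, metric) {
  prep <- if (is.null(eng$prep)) NULL
          else list(ctr = eng$prep$ctr[idx, , drop = FALSE],
                    nrm = eng$prep$nrm[idx])
  row_dissimilarity(eng$M[idx, , drop = FALSE], f, metric, prep)
}

# D(I(x), F[x,]) with a per-pixel feature matrix.
eng_dissimilarity_rowwise <- function(eng, idx, F, metric) {
  prep <- if (is.null(eng$prep)) NULL
          else list(ctr = eng$prep$ctr[idx, , drop = FALSE],
                    nrm = eng$prep$nrm[idx])
  rowwise_dissimilarity(eng$M[idx, , drop = FALSE], F, metric, prep)
}

# ---------------------------------------------------------------------------
# Region features

# f_in: mean time course of pixels exclusively in interior i (all interior
# pixels if none are exclusive); f_out: mean over narrowband pixels outside
# every interior (all narrowband pixels if none qualify).
compute_features <- function(eng, seg, i) {
  st <- seg$states[[i]]
  excl <- st$interior & (seg$n_in - st$interior) == 0L
  if (!any(excl)) excl <- st$interior
  idx_in <- which(excl)
  out_px <- st$narrowband & seg$n_in == 0L
  if (!any(out_px)) out_px <- st$narrowband
  idx_out <- which(out_px)
  if (!length(idx_out)) stop("narrowband of ROI ", i, " is empty")
  list(f_in = colMeans(eng$M[idx_in, , drop = FALSE]),
       f_out = colMeans(eng$M[idx_out, , drop = FALSE]))
}

#' Region feature time courses of one ROI
#'
#' The interior feature `f_in` is the average time course of pixels
#' belonging exclusively to this ROI's interior (pixels shared with
#' overlapping neighbours are left out so each cell's feature stays
#' demixed); if every interior pixel is shared, all interior pixels are
#' used. The background feature `f_out` is the average over the ROI's
#' narrowband pixels that lie in no cell's interior -- a local estimate of
#' the global exterior that absorbs neuropil and slow intensity
#' inhomogeneity.
#'
#' @param video a [video_stack()].
#' @param seg a `segmentation` object.
#' @param i ROI index.
#' @return list with numeric vectors `f_in` and `f_out` of length `T`.
#' @export
region_timecourses <- function(video, seg, i) {
  stopifnot(inherits(seg, "segmentation"))
  eng <- make_engine(video, seg$params)
  compute_features(eng, seg, i)
}

# Cached f_in for state j, computing (and storing) it if stale.
cached_f_in <- function(eng, seg, j) {
  f <- seg$states[[j]]$f_in
  if (is.null(f)) compute_features(eng, seg, j)$f_in else f
}

# ---------------------------------------------------------------------------
# External velocity

# Velocity values over the band pixels `band_idx` for ROI i; features of
# neighbouring ROIs are their latest cached f_in.
velocity_values <- function(eng, seg, i, band_idx, feats, params) {
  st <- seg$states[[i]]
  metric <- params$metric
  V <- numeric(length(band_idx))
  n_other <- seg$n_in[band_idx] - st$interior[band_idx]
  plain <- n_other == 0L
  if (any(plain)) {
    idx <- band_idx[plain]
    V[plain] <- eng_dissimilarity(eng, idx, feats$f_in, metric) -
                eng_dissimilarity(eng, idx, feats$f_out, metric)
  }
  if (any(!plain)) {
    idx <- band_idx[!plain]
    others <- setdiff(seg_alive(seg), i)
    memb <- vapply(others,
                   function(j) as.numeric(seg$states[[j]]$interior[idx]),
                   numeric(length(idx)))
    if (length(idx) == 1L) memb <- matrix(memb, nrow = 1L)
    Fin <- t(vapply(others, function(j) cached_f_in(eng, seg, j),
                    numeric(eng$T)))
    S <- memb %*% Fin                      # per-pixel sum of neighbour f_in
    Fi <- matrix(feats$f_in, nrow = length(idx), ncol = eng$T, byrow = TRUE)
    V[!plain] <- eng_dissimilarity_rowwise(eng, idx, S + Fi, metric) -
                 eng_dissimilarity_rowwise(eng, idx, S, metric)
  }
  V
}

#' External velocity field of one ROI
#'
#' The data-driven velocity evaluated on the Dirac band
#' `|phi_i| <= epsilon`. At a band pixel in no other cell's interior it is
#' `D(I(x), f_in) - D(I(x), f_out)`: negative (inclusion) when the pixel's
#' time course resembles the interior, positive (repulsion) when it
#' resembles the local background. At a pixel inside neighbouring cells it
#' is `D(I(x), f_in_i + sum_j f_in_j) - D(I(x), sum_j f_in_j)` over the
#' neighbours `j` containing the pixel: the contour expands into the
#' overlap exactly when adding this cell's time course improves the fit --
#' the demixing mechanism.
#'
#' @param video a [video_stack()].
#' @param seg a `segmentation` object.
#' @param i ROI index.
#' @param params a [seg_params()] object (defaults to `seg$params`).
#' @return an `H x W` matrix, zero outside the band, with attribute `band`
#'   holding the band's pixel indices.
#' @export
external_velocity <- function(video, seg, i, params = seg$params) {
  eng <- make_engine(video, params)
  st <- seg$states[[i]]
  band_idx <- which(abs(st$phi) <= params$epsilon)
  feats <- compute_features(eng, seg, i)
  V <- velocity_values(eng, seg, i, band_idx, feats, params)
  out <- matrix(0, seg$shape[1], seg$shape[2])
  out[band_idx] <- V
  attr(out, "band") <- band_idx
  out
}

# ---------------------------------------------------------------------------
# Energy (diagnostics and tests; the evolution never evaluates it)

#' External energy of a segmentation
#'
#' The data term of the cost: summed dissimilarity between each pixel in
#' the union of interiors and the summed interior features of the cells
#' containing it, plus the dissimilarity of every narrowband (global
#' exterior) pixel to its local background feature. A pixel covered by
#' several narrowbands uses the average of their `f_out`. With a single
#' ROI this reduces exactly to the two-region interior/exterior energy.
#'
#' @param video a [video_stack()].
#' @param seg a `segmentation` object.
#' @param metric `"euclidean"` or `"correlation"` (defaults to the
#'   segmentation's metric).
#' @return a non-negative scalar.
#' @export
external_energy <- function(video, seg, metric = seg$params$metric) {
  eng <- make_engine(video, seg$params)
  alive <- seg_alive(seg)
  if (!length(alive)) return(0)
  feats <- lapply(alive, function(j) compute_features(eng, seg, j))
  Fin <- t(vapply(feats, `[[`, numeric(eng$T), "f_in"))
  Fout <- t(vapply(feats, `[[`, numeric(eng$T), "f_out"))

  inside_idx <- which(seg$n_in > 0L)
  e_in <- 0
  if (length(inside_idx)) {
    memb <- vapply(seq_along(alive),
                   function(k) as.numeric(seg$states[[alive[k]]]$interior[inside_idx]),
                   numeric(length(inside_idx)))
    if (length(inside_idx) == 1L) memb <- matrix(memb, nrow = 1L)
    S <- memb %*% Fin
    e_in <- sum(eng_dissimilarity_rowwise(eng, inside_idx, S, metric))
  }

  nb_cov <- matrix(0L, seg$shape[1], seg$shape[2])
  for (j in alive) nb_cov <- nb_cov + (seg$states[[j]]$narrowband & seg$n_in == 0L)
  out_idx <- which(nb_cov > 0L)
  e_out <- 0
  if (length(out_idx)) {
    membo <- vapply(seq_along(alive),
                    function(k) as.numeric(seg$states[[alive[k]]]$narrowband[out_idx]),
                    numeric(length(out_idx)))
    if (length(out_idx) == 1L) membo <- matrix(membo, nrow = 1L)
    Fo <- (membo / rowSums(membo)) %*% Fout   # local (averaged) f_out
    e_out <- sum(eng_dissimilarity_rowwise(eng, out_idx, Fo, metric))
  }
  e_in + e_out
}

# ---------------------------------------------------------------------------
# Evolution

#' One evolution step of a level set state
#'
#' Applies `phi <- phi - delta_tau (lambda dirac(phi) V + mu dR/dphi)`,
#' recomputes the interior (`phi > 0`) and narrowband, and records the
#' number of pixels that entered or left the interior (attribute
#' `pixels_changed`) together with the convergence counter: the counter
#' advances when fewer than `rho` pixels changed and resets otherwise.
#'
#' @param state a `level_set_state`.
#' @param V external velocity field (`H x W`, zero off the band).
#' @param params a [seg_params()] object.
#' @return the updated `level_set_state`.
#' @export
evolve_step <- function(state, V, params) {
  stopifnot(state$status == "active")
  phi <- state$phi -
    params$delta_tau * (params$lambda * dirac_delta(state$phi, params$epsilon) * V +
                        params$mu * distreg_gradient(state$phi))
  if (!all(is.finite(phi)))
    stop("level set field became non-finite (lambda too large?)")
  interior <- phi > 0
  changed <- sum(interior != state$interior)
  state$phi <- phi
  state$interior <- interior
  state$narrowband <- narrowband_of(interior, params$narrowband_width)
  state$sweeps <- state$sweeps + 1L
  state$stable_iters <- if (changed < params$rho) state$stable_iters + 1L
                        else 0L
  attr(state, "pixels_changed") <- changed
  state
}

#' Has a contour converged?
#'
#' TRUE once the interior has changed by fewer than `rho` pixels for
#' `n_con` consecutive sweeps.
#'
#' @param state a `level_set_state`.
#' @param params a [seg_params()] object.
#' @return logical.
#' @export
has_converged <- function(state, params) {
  state$stable_iters >= params$n_con
}

# ---------------------------------------------------------------------------
# Pruning and merging

#' Prune out-of-bounds ROIs
#'
#' Marks as pruned any active ROI whose interior area lies outside
#' `[min_area, max_area]` (defaults 3 and `3 pi r^2` pixels) and removes it
#' from the overlap map. Shrinking background seeds and runaway merged
#' blobs are eliminated this way.
#'
#' @param seg a `segmentation` object.
#' @param params a [seg_params()] object (defaults to `seg$params`).
#' @return the updated `segmentation`.
#' @export
prune_rois <- function(seg, params = seg$params) {
  for (i in seq_along(seg$states)) {
    st <- seg$states[[i]]
    if (st$status != "active") next
    a <- sum(st$interior)
    if (a < params$min_area || a > params$max_area) {
      seg$states[[i]]$status <- "pruned"
      seg$n_in <- seg$n_in - st$interior
      seg$events[[length(seg$events) + 1L]] <-
        list(sweep = seg$sweeps_run, event = "prune", roi = i, area = a)
    }
  }
  seg
}

#' Merge redundant ROIs
#'
#' Two surviving ROIs are two views of one cell when they are close
#' (minimum boundary-to-boundary distance at most one cell radius) and
#' their interior time courses correlate at or above the merge threshold.
#' Qualifying pairs are merged greedily in descending correlation order,
#' once per sweep: both states are retired and replaced by a single active
#' level set initialized as the signed distance of the union of the two
#' interiors, with convergence counters reset.
#'
#' @param seg a `segmentation` object.
#' @param video a [video_stack()].
#' @param params a [seg_params()] object (defaults to `seg$params`).
#' @return the updated `segmentation`.
#' @export
try_merge <- function(seg, video, params = seg$params) {
  if (seg$sweeps_run > 0 && seg$sweeps_run < params$merge_start)
    return(seg)
  alive <- seg_alive(seg)
  if (length(alive) < 2L) return(seg)
  eng <- make_engine(video, params)
  # bounding boxes give a cheap lower bound on pair distance; the exact
  # boundary distance uses one distance field per ROI, computed lazily
  bbox <- lapply(alive, function(i) {
    xy <- mask_coords(seg$states[[i]]$interior)
    c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  })
  dfield <- vector("list", length(alive))
  pairs <- NULL
  for (a in seq_along(alive)) for (b in seq_len(a - 1L)) {
    i <- alive[b]; j <- alive[a]
    gap_r <- max(0, bbox[[a]][1] - bbox[[b]][2], bbox[[b]][1] - bbox[[a]][2])
    gap_c <- max(0, bbox[[a]][3] - bbox[[b]][4], bbox[[b]][3] - bbox[[a]][4])
    if (sqrt(gap_r^2 + gap_c^2) > params$radius) next
    if (is.null(dfield[[b]]))
      dfield[[b]] <- dist_to_mask(seg$states[[i]]$interior)
    if (min(dfield[[b]][seg$states[[j]]$interior]) > params$radius) next
    ci <- cached_f_in(eng, seg, i)
    cj <- cached_f_in(eng, seg, j)
    r <- suppressWarnings(stats::cor(ci, cj))
    if (!is.finite(r) || r < params$merge_threshold) next
    pairs <- rbind(pairs, c(i, j, r))
  }
  if (is.null(pairs)) return(seg)
  pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
  done <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (i %in% done || j %in% done) next
    union_mask <- seg$states[[i]]$interior | seg$states[[j]]$interior
    seg$n_in <- seg$n_in - seg$states[[i]]$interior - seg$states[[j]]$interior
    new_st <- init_level_set(union_mask, params$radius,
                             params$narrowband_width)
    seg$states[[j]]$status <- "merged"
    seg$states[[i]] <- new_st           # replaces the lower index in place
    seg$n_in <- seg$n_in + new_st$interior
    seg$events[[length(seg$events) + 1L]] <-
      list(sweep = seg$sweeps_run, event = "merge", roi = i, absorbed = j,
           corr = pairs[k, 3])
    done <- c(done, i, j)
  }
  seg
}

# ---------------------------------------------------------------------------
# Main loop

#' Segment a video with coupled active contours
#'
#' Runs the full evolution: initializes one level set per candidate,
#' sweeps over all active contours (ascending index, each update seeing
#' the latest neighbour states), then prunes and merges, until every
#' surviving contour has converged or `n_max` sweeps have run. Converged
#' contours are frozen but keep contributing to their neighbours' overlap
#' map, feature sums and merge tests. With `prune_undifferentiated`, an
#' ROI whose converged interior time course correlates with its narrowband
#' at or above the merge threshold is dropped as background.
#'
#' @param video a [video_stack()].
#' @param candidates list of candidate masks (from [candidate_rois()],
#'   [grid_init()], or user-supplied `H x W` logicals).
#' @param params a [seg_params()] object.
#' @param verbose print per-sweep progress.
#' @return a `segmentation` object; surviving states have status
#'   `"active"` (stopped at `n_max`) or `"converged"`.
#' @export
segment_video <- function(video, candidates, params, verbose = FALSE) {
  stopifnot(inherits(video, "video_stack"), inherits(params, "seg_params"))
  if (!length(candidates)) stop_input("no candidate ROIs supplied")
  states <- lapply(candidates, init_level_set, radius = params$radius,
                   narrowband_width = params$narrowband_width)
  seg <- new_segmentation(states, field_dim(video), params)
  eng <- make_engine(video, params)

  for (sweep in seq_len(params$n_max)) {
    seg$sweeps_run <- sweep
    for (i in seq_along(seg$states)) {
      st <- seg$states[[i]]
      if (st$status != "active") next
      feats <- compute_features(eng, seg, i)
      seg$states[[i]]$f_in <- feats$f_in   # latest feature for neighbours
      band_idx <- which(abs(st$phi) <= params$epsilon)
      V <- matrix(0, seg$shape[1], seg$shape[2])
      V[band_idx] <- velocity_values(eng, seg, i, band_idx, feats, params)
      old_interior <- st$interior
      st <- evolve_step(seg$states[[i]], V, params)
      seg$n_in <- seg$n_in + st$interior - old_interior
      if (has_converged(st, params)) {
        st$status <- "converged"
        st$converged_sweep <- sweep
        if (params$prune_undifferentiated &&
            undifferentiated(eng, seg, i, st, params)) {
          st$status <- "pruned"
          seg$n_in <- seg$n_in - st$interior
          seg$events[[length(seg$events) + 1L]] <-
            list(sweep = sweep, event = "prune_undifferentiated", roi = i)
        }
      }
      seg$states[[i]] <- st
    }
    seg <- prune_rois(seg, params)
    seg <- try_merge(seg, video, params)
    alive <- seg_alive(seg)
    n_active <- sum(vapply(seg$states[alive], function(s)
      s$status == "active", logical(1)))
    if (verbose)
      message(sprintf("sweep %3d: %d alive (%d still active)",
                      sweep, length(alive), n_active))
    if (n_active == 0L) break
  }

  if (params$prune_undifferentiated) {
    # contours still active at n_max get the same background test
    for (i in seg_alive(seg)) {
      st <- seg$states[[i]]
      if (st$status != "active") next
      if (undifferentiated(eng, seg, i, st, params)) {
        seg$states[[i]]$status <- "pruned"
        seg$n_in <- seg$n_in - st$interior
        seg$events[[length(seg$events) + 1L]] <-
          list(sweep = seg$sweeps_run, event = "prune_undifferentiated",
               roi = i)
      }
    }
  }

  seg <- prune_redundant(seg, eng, params)
  if (!length(seg_alive(seg)))
    warning("all candidate ROIs were pruned; empty segmentation")
  seg
}

# End-of-run redundancy resolution. Two degenerate survivors can outlast
# the evolution because, under the correlation metric, their velocity is
# neutral: (i) a contour wholly contained in other interiors (fewer than
# min_area exclusive pixels) duplicates its hosts; (ii) a contour sitting
# exactly on the overlap zone of two or more neighbours has an interior
# time course equal to the *sum* of those neighbours' features -- the
# partition {A-O, B-O, O} fits the data exactly as well as the
# overlapping {A, B}, so the spurious middle piece must be removed by an
# explicit test. Both are pruned smallest-first, re-examining after each
# removal.
prune_redundant <- function(seg, eng, params) {
  repeat {
    alive <- seg_alive(seg)
    if (length(alive) < 2L) break
    redundant <- logical(length(alive))
    for (k in seq_along(alive)) {
      i <- alive[k]
      st <- seg$states[[i]]
      excl <- sum(st$interior & (seg$n_in - st$interior) == 0L)
      if (excl < params$min_area) {
        redundant[k] <- TRUE
        next
      }
      # neighbours within one radius (boundary-to-boundary)
      d <- dist_to_mask(st$interior)
      nb <- Filter(function(j)
        min(d[seg$states[[j]]$interior]) <= params$radius,
        setdiff(alive, i))
      if (length(nb) < 2L) next
      f_i <- compute_features(eng, seg, i)$f_in
      f_sum <- Reduce(`+`, lapply(nb, function(j)
        compute_features(eng, seg, j)$f_in))
      r <- suppressWarnings(stats::cor(f_i, f_sum))
      if (is.finite(r) && r >= params$merge_threshold) redundant[k] <- TRUE
    }
    if (!any(redundant)) break
    areas <- vapply(alive[redundant], function(i)
      sum(seg$states[[i]]$interior), numeric(1))
    i <- alive[redundant][which.min(areas)]
    seg$states[[i]]$status <- "pruned"
    seg$n_in <- seg$n_in - seg$states[[i]]$interior
    seg$events[[length(seg$events) + 1L]] <-
      list(sweep = seg$sweeps_run, event = "prune_redundant", roi = i)
  }
  seg
}

# Interior time course indistinguishable from the narrowband's?
undifferentiated <- function(eng, seg, i, st, params) {
  seg$states[[i]] <- st
  f <- compute_features(eng, seg, i)
  r <- suppressWarnings(stats::cor(f$f_in, f$f_out))
  is.finite(r) && r >= params$undiff_threshold
}
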