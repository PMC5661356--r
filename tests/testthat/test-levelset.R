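test_that("dirac_delta has the cosine-bump closed form", {
  phi <- matrix(c(0, 1, 2, -2, 3, -0.5), 2, 3)
  d <- dirac_delta(phi, epsilon = 2)
  expect_equal(d[1, 1], 0.5)                      # peak 1/eps at phi = 0
  expect_equal(d[phi == 2], 0)
  expect_equal(d[phi == -2], 0)
  expect_equal(d[phi == 3], 0)
  expect_true(all(d >= 0))
  # Riemann sum across a unit-slope ramp integrates to ~1
  ramp <- matrix(seq(-5, 5, by = 0.05), nrow = 1)
  expect_equal(sum(dirac_delta(ramp, 2)) * 0.05, 1, tolerance = 0.02)
})

test_that("distance regularizer vanishes at both wells and descends", {
  # |grad phi| = 1 exactly (planar ramp): first well
  ramp <- outer(seq_len(30), rep(1, 30)) * 1.0
  expect_lt(max(abs(distreg_gradient(ramp))), 1e-12)
  # |grad phi| = 0 (constant): second well
  expect_true(all(distreg_gradient(matrix(5, 10, 10)) == 0))
  # signed distance of a disc (analytic cone): near zero through the band
  cone <- 8 - sqrt(outer((1:30) - 15, rep(1, 30))^2 +
                   outer(rep(1, 30), (1:30) - 15)^2)
  g <- distreg_gradient(cone)
  band <- abs(cone) <= 4 & abs(cone) >= 1
  expect_lt(max(abs(g[band])), 1e-2)

  # steepened phi relaxes toward |grad| = 1: total potential decreases
  phi2 <- 2 * cone
  pot <- function(p) {
    gr <- (caimseg:::shift_replicate(p, -1, 0) -
           caimseg:::shift_replicate(p, 1, 0)) / 2
    gc <- (caimseg:::shift_replicate(p, 0, -1) -
           caimseg:::shift_replicate(p, 0, 1)) / 2
    sum(caimseg:::double_well_p(sqrt(gr^2 + gc^2)))
  }
  vals <- numeric(30)
  for (i in 1:30) {
    phi2 <- phi2 - 0.5 * distreg_gradient(phi2)
    vals[i] <- pot(phi2)
  }
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("CFL condition is asserted, never clamped", {
  p <- seg_params(radius = 5, lambda = 1)
  expect_lt(p$mu * p$delta_tau, 0.25)
  expect_equal(p$mu * p$delta_tau, 0.2)           # published defaults
  expect_error(seg_params(radius = 5, lambda = 1, mu = 0.05),
               "CFL")
})

test_that("merge threshold from SNR follows the closed form", {
  expect_equal(merge_threshold_from_snr(0), 0.5)
  expect_equal(merge_threshold_from_snr(5), 1 / (1 + 10^(-0.5)))
  expect_equal(merge_threshold_from_snr(1e6), 1, tolerance = 1e-12)
  sweep <- merge_threshold_from_snr(seq(-20, 40, by = 1))
  expect_true(all(diff(sweep) > 0))
  expect_error(merge_threshold_from_snr(NaN), "finite")
})

test_that("region time courses use exclusive interiors and clean narrowbands", {
  tw <- two_region_video(noise_sd = 0)
  p <- seg_params(radius = 5, lambda = 1)
  st <- init_level_set(tw$mask, radius = 5, narrowband_width = 10)
  seg <- caimseg:::new_segmentation(list(st), dim(tw$mask), p)
  f <- region_timecourses(tw$video, seg, 1)
  expect_equal(f$f_in, tw$cell_tc, tolerance = 1e-10)
  expect_equal(f$f_out, tw$bg_tc, tolerance = 1e-10)   # constant background

  # interior of 2 pixels -> arithmetic mean of their time courses
  v <- rand_video(T = 30, H = 8, W = 8, seed = 13)
  m <- matrix(FALSE, 8, 8); m[4, 4] <- TRUE; m[4, 5] <- TRUE
  st2 <- init_level_set(m, radius = 2)
  seg2 <- caimseg:::new_segmentation(list(st2), c(8, 8), p)
  f2 <- region_timecourses(v, seg2, 1)
  expect_equal(f2$f_in, (v$data[, 4, 4] + v$data[, 4, 5]) / 2)

  # overlapping pair: means match a mask-indexing oracle
  m1 <- caimseg:::disc_mask(20, 20, c(10, 8), 4)
  m2 <- caimseg:::disc_mask(20, 20, c(10, 14), 4)
  v2 <- rand_video(T = 25, H = 20, W = 20, seed = 17)
  states <- list(init_level_set(m1, 4), init_level_set(m2, 4))
  seg3 <- caimseg:::new_segmentation(states, c(20, 20), p)
  f3 <- region_timecourses(v2, seg3, 1)
  M <- caimseg:::pixel_matrix(v2)
  expect_equal(f3$f_in, colMeans(M[which(m1 & !m2), , drop = FALSE]))
  nb <- states[[1]]$narrowband & !m1 & !m2
  expect_equal(f3$f_out, colMeans(M[which(nb), , drop = FALSE]))
})

test_that("external velocity signs follow the two-branch rule", {
  # isolated cell: pixel matching f_in is pulled in, f_out pushed out
  tw <- two_region_video(noise_sd = 0.5)
  p <- seg_params(radius = 5, lambda = 1, metric = "euclidean")
  st <- init_level_set(tw$mask, radius = 5)
  seg <- caimseg:::new_segmentation(list(st), dim(tw$mask), p)
  V <- external_velocity(tw$video, seg, 1, p)
  band <- attr(V, "band")
  inner <- intersect(band, which(tw$mask))      # cell pixels in the band
  outer_px <- setdiff(band, which(tw$mask))
  expect_lt(mean(V[inner]), 0)
  expect_gt(mean(V[outer_px]), 0)
  expect_true(all(V[-band] == 0))

  # overlap branch: a pixel whose time course is the sum of both cells'
  # features drives expansion of either contour into the overlap
  set.seed(31)
  H <- 20; W <- 26; T <- 40
  m1 <- caimseg:::disc_mask(H, W, c(10, 10), 5)
  m2 <- caimseg:::disc_mask(H, W, c(10, 17), 5)
  a1 <- 50 + 20 * sin(seq_len(T) / 2)
  a2 <- 50 + 20 * cos(seq_len(T) / 1.3)
  arr <- array(10, dim = c(T, H, W))
  for (t in seq_len(T)) {
    fr <- matrix(10, H, W)
    fr[m1] <- fr[m1] + a1[t]
    fr[m2] <- fr[m2] + a2[t]
    arr[t, , ] <- fr
  }
  v <- video_stack(arr)
  states <- list(init_level_set(m1, 5), init_level_set(m2, 5))
  seg2 <- caimseg:::new_segmentation(states, c(H, W), p)
  V1 <- external_velocity(v, seg2, 1, p)
  overlap_band <- intersect(attr(V1, "band"), which(m1 & m2))
  expect_gt(length(overlap_band), 0)
  expect_lt(max(V1[overlap_band]), 0)           # expands into the overlap
})

test_that("multi-cell energy reduces to the direct two-region energy", {
  for (metric in c("euclidean", "correlation")) {
    tw <- two_region_video(noise_sd = 1, seed = 23)
    p <- seg_params(radius = 5, lambda = 1, metric = metric)
    st <- init_level_set(tw$mask, radius = 5)
    seg <- caimseg:::new_segmentation(list(st), dim(tw$mask), p)
    expect_equal(external_energy(tw$video, seg, metric),
                 direct_two_region_energy(tw$video, st$interior,
                                          st$narrowband, metric),
                 tolerance = 1e-10)
  }
})

test_that("a perfect noiseless partition has (near) zero energy", {
  tw <- two_region_video(noise_sd = 0)
  p <- seg_params(radius = 5, lambda = 1)
  st <- init_level_set(tw$mask, radius = 5)
  seg <- caimseg:::new_segmentation(list(st), dim(tw$mask), p)
  expect_lt(external_energy(tw$video, seg, "euclidean"), 1e-8)
})

test_that("the stated optimum beats 1-pixel perturbations on a tiny video", {
  # 8x8 noiseless two-region video; flipping any single boundary pixel of
  # the true mask cannot lower the energy
  set.seed(41)
  H <- 8; W <- 8; T <- 30
  mask <- caimseg:::disc_mask(H, W, c(4.5, 4.5), 2.2)
  cell <- 50 + 10 * sin(seq_len(T))
  arr <- array(5, dim = c(T, H, W))
  for (t in seq_len(T)) {
    fr <- matrix(5, H, W); fr[mask] <- cell[t]
    arr[t, , ] <- fr
  }
  v <- video_stack(arr)
  p <- seg_params(radius = 3, lambda = 1)
  energy_of <- function(m) {
    st <- init_level_set(m, radius = 3)
    seg <- caimseg:::new_segmentation(list(st), c(H, W), p)
    external_energy(v, seg, "euclidean")
  }
  e0 <- energy_of(mask)
  ring <- which(caimseg:::narrowband_of(mask, 1.5) | mask)
  for (px in ring) {
    m2 <- mask
    m2[px] <- !m2[px]
    if (!any(m2)) next
    if (max(caimseg:::label8(m2)) != 1L) next  # keep candidates connected
    expect_gte(energy_of(m2), e0 - 1e-9)
  }
})

test_that("evolve_step respects fixed points, signs and convergence logic", {
  mask <- caimseg:::disc_mask(24, 24, c(12, 12), 5)
  p <- seg_params(radius = 5, lambda = 1)
  st <- init_level_set(mask, radius = 5)
  zero_V <- matrix(0, 24, 24)
  st1 <- evolve_step(st, zero_V, p)
  expect_identical(st1$interior, st$interior)     # signed distance is fixed
  expect_identical(attr(st1, "pixels_changed"), 0L)

  # uniformly negative band velocity grows the interior
  Vneg <- matrix(0, 24, 24)
  Vneg[abs(st$phi) <= p$epsilon] <- -1
  st2 <- evolve_step(st, Vneg, p)
  expect_gte(sum(st2$interior), sum(st$interior))
  expect_true(all(st$interior[st2$interior] | TRUE))

  # convergence counter: quiet sweeps accumulate, a loud sweep resets
  stq <- st
  for (i in 1:39) stq <- evolve_step(stq, zero_V, p)
  expect_false(has_converged(stq, p))
  stq <- evolve_step(stq, zero_V, p)
  expect_true(has_converged(stq, p))              # 40 quiet sweeps
  stq2 <- st
  for (i in 1:39) stq2 <- evolve_step(stq2, zero_V, p)
  stq2$stable_iters <- 0L                          # as after a loud sweep
  expect_false(has_converged(stq2, p))
})

test_that("pruning enforces the size thresholds", {
  p <- seg_params(radius = 5, lambda = 1)
  tiny <- matrix(FALSE, 40, 40); tiny[5, 5:6] <- TRUE        # area 2 < 3
  mid <- caimseg:::disc_mask(40, 40, c(12, 12), 4)           # area ~50
  big <- caimseg:::disc_mask(40, 40, c(24, 24), sqrt((3 * pi * 25 + 40) / pi))
  states <- list(init_level_set(tiny, 5),
                 init_level_set(mid, 5),
                 init_level_set(big, 5))         # above 3*pi*r^2
  seg <- caimseg:::new_segmentation(states, c(40, 40), p)
  seg <- prune_rois(seg, p)
  status <- vapply(seg$states, `[[`, character(1), "status")
  expect_identical(status, c("pruned", "active", "pruned"))
  expect_identical(max(seg$n_in), 1L)
})

test_that("merging joins close correlated ROIs only", {
  set.seed(51)
  H <- 24; W <- 40; T <- 50
  tc <- 50 + 20 * sin(seq_len(T) / 2)
  build <- function(masks, traces) {
    arr <- array(0, dim = c(T, H, W))
    for (t in seq_len(T)) {
      fr <- matrix(10 + rnorm(1, 0, 0.1), H, W)
      for (k in seq_along(masks)) fr[masks[[k]]] <- traces[[k]][t]
      arr[t, , ] <- fr + rnorm(H * W, 0, 0.5)
    }
    video_stack(arr)
  }
  p <- seg_params(radius = 4, lambda = 1)
  m1 <- caimseg:::disc_mask(H, W, c(12, 10), 4)
  m2 <- caimseg:::disc_mask(H, W, c(12, 19), 4)   # 1 px gap < r
  m3 <- caimseg:::disc_mask(H, W, c(12, 33), 4)   # far away

  # identical traces, adjacent -> merged into the union
  v <- build(list(m1, m2), list(tc, tc))
  seg <- caimseg:::new_segmentation(list(init_level_set(m1, 4),
                                         init_level_set(m2, 4)), c(H, W), p)
  seg <- try_merge(seg, v, p)
  status <- vapply(seg$states, `[[`, character(1), "status")
  expect_setequal(status, c("active", "merged"))
  merged <- seg$states[[which(status == "active")]]
  expect_identical(merged$interior, m1 | m2)
  expect_identical(max(seg$n_in), 1L)

  # uncorrelated traces, adjacent -> untouched
  v2 <- build(list(m1, m2), list(tc, 50 + 20 * sin(seq_len(T) / 0.37)))
  seg2 <- caimseg:::new_segmentation(list(init_level_set(m1, 4),
                                          init_level_set(m2, 4)), c(H, W), p)
  seg2 <- try_merge(seg2, v2, p)
  expect_true(all(vapply(seg2$states, `[[`, character(1), "status") ==
                    "active"))

  # identical traces but distant -> untouched (proximity gate)
  v3 <- build(list(m1, m3), list(tc, tc))
  seg3 <- caimseg:::new_segmentation(list(init_level_set(m1, 4),
                                          init_level_set(m3, 4)), c(H, W), p)
  seg3 <- try_merge(seg3, v3, p)
  expect_true(all(vapply(seg3$states, `[[`, character(1), "status") ==
                    "active"))
})

test_that("energy descends on a noiseless two-region video", {
  tw <- two_region_video(H = 26, W = 26, T = 40, radius = 5, noise_sd = 0)
  p <- seg_params(radius = 5, lambda = 0.02, n_max = 30)
  # start from a shifted disc so the contour has somewhere to go
  seed_mask <- caimseg:::disc_mask(26, 26, c(14, 14), 4)
  eng <- caimseg:::make_engine(tw$video, p)
  seg <- caimseg:::new_segmentation(list(init_level_set(seed_mask, 5)),
                                    c(26, 26), p)
  energies <- numeric(0)
  for (sweep in 1:30) {
    feats <- caimseg:::compute_features(eng, seg, 1)
    seg$states[[1]]$f_in <- feats$f_in
    st <- seg$states[[1]]
    band_idx <- which(abs(st$phi) <= p$epsilon)
    V <- matrix(0, 26, 26)
    V[band_idx] <- caimseg:::velocity_values(eng, seg, 1, band_idx, feats, p)
    old <- st$interior
    st <- evolve_step(st, V, p)
    seg$n_in <- seg$n_in + st$interior - old
    seg$states[[1]] <- st
    energies <- c(energies, external_energy(tw$video, seg, "euclidean"))
  }
  increases <- diff(energies) / pmax(energies[-length(energies)], 1e-12)
  expect_true(all(increases <= 0.01))   # <=1% transient tolerance
  expect_lt(energies[length(energies)], energies[1])
})

test_that("distant pixel perturbations cannot change a cell's update", {
  set.seed(61)
  H <- 40; W <- 40
  tw <- two_region_video(H = H, W = W, T = 30, centre = c(12, 12),
                         radius = 4, noise_sd = 1, seed = 61)
  p <- seg_params(radius = 4, lambda = 1)
  st <- init_level_set(caimseg:::disc_mask(H, W, c(12, 12), 4), 4)
  run_update <- function(video) {
    eng <- caimseg:::make_engine(video, p)
    seg <- caimseg:::new_segmentation(list(st), c(H, W), p)
    feats <- caimseg:::compute_features(eng, seg, 1)
    band_idx <- which(abs(st$phi) <= p$epsilon)
    V <- matrix(0, H, W)
    V[band_idx] <- caimseg:::velocity_values(eng, seg, 1, band_idx, feats, p)
    evolve_step(st, V, p)$phi
  }
  phi1 <- run_update(tw$video)
  # corrupt pixels farther than 2r + eps + 1 from the narrowband
  d <- caimseg:::dist_to_mask(st$narrowband | st$interior)
  far <- d > 2 * p$radius + p$epsilon + 1
  expect_gt(sum(far), 0)
  arr <- tw$video$data
  dim(arr) <- c(30, H * W)
  arr[, which(far)] <- arr[, which(far)] +
    matrix(rnorm(sum(far) * 30, 0, 50), nrow = 30)
  dim(arr) <- c(30, H, W)
  phi2 <- run_update(video_stack(arr))
  expect_identical(phi1, phi2)
})

test_that("an overlap-zone impostor is pruned as redundant", {
  # two overlapping cells A and B; a third contour sits exactly on the
  # intersection, whose trace is a's + b's -- it must be pruned, A and B
  # kept, when segmentation finishes
  set.seed(91)
  H <- 26; W <- 36; T <- 60
  mA <- caimseg:::disc_mask(H, W, c(13, 13), 6)
  mB <- caimseg:::disc_mask(H, W, c(13, 22), 6)
  mO <- mA & mB
  a <- 40 + 15 * sin(seq_len(T) / 2) + rnorm(T, 0, 1)
  b <- 40 + 15 * cos(seq_len(T) / 1.7) + rnorm(T, 0, 1)
  arr <- array(0, dim = c(T, H, W))
  for (t in seq_len(T)) {
    fr <- matrix(10, H, W)
    fr[mA] <- fr[mA] + a[t]
    fr[mB] <- fr[mB] + b[t]
    arr[t, , ] <- fr + rnorm(H * W, 0, 0.5)
  }
  v <- video_stack(arr)
  p <- seg_params(radius = 6, lambda = 1, metric = "correlation")
  seg <- caimseg:::new_segmentation(
    list(init_level_set(mA & !mO, 6), init_level_set(mB & !mO, 6),
         init_level_set(mO, 6)), c(H, W), p)
  eng <- caimseg:::make_engine(v, p)
  seg2 <- caimseg:::prune_redundant(seg, eng, p)
  status <- vapply(seg2$states, `[[`, character(1), "status")
  expect_identical(status, c("active", "active", "pruned"))

  # an ordinary third cell with its own activity is NOT pruned
  cc <- 40 + 15 * sin(seq_len(T) / 0.9) + rnorm(T, 0, 1)
  mC <- caimseg:::disc_mask(H, W, c(13, 30), 4)
  arr2 <- arr
  for (t in seq_len(T)) {
    fr <- arr2[t, , ]
    fr[mC] <- fr[mC] + cc[t]
    arr2[t, , ] <- fr
  }
  seg3 <- caimseg:::new_segmentation(
    list(init_level_set(mA, 6), init_level_set(mB, 6),
         init_level_set(mC, 6)), c(H, W), p)
  eng2 <- caimseg:::make_engine(video_stack(arr2), p)
  seg4 <- caimseg:::prune_redundant(seg3, eng2, p)
  expect_true(all(vapply(seg4$states, `[[`, character(1), "status") ==
                    "active"))
})

test_that("merging can be deferred until contours mature", {
  set.seed(96)
  H <- 20; W <- 30; T <- 40
  tc <- 50 + 20 * sin(seq_len(T) / 2)
  m1 <- caimseg:::disc_mask(H, W, c(10, 9), 4)
  m2 <- caimseg:::disc_mask(H, W, c(10, 18), 4)
  arr <- array(0, dim = c(T, H, W))
  for (t in seq_len(T)) {
    fr <- matrix(10, H, W); fr[m1 | m2] <- tc[t]
    arr[t, , ] <- fr + rnorm(H * W, 0, 0.3)
  }
  v <- video_stack(arr)
  p <- seg_params(radius = 4, lambda = 1, merge_start = 10)
  seg <- caimseg:::new_segmentation(list(init_level_set(m1, 4),
                                         init_level_set(m2, 4)), c(H, W), p)
  seg$sweeps_run <- 5L                      # mid-evolution, before start
  expect_true(all(vapply(try_merge(seg, v, p)$states, `[[`, character(1),
                         "status") == "active"))
  seg$sweeps_run <- 10L                     # at the start sweep
  expect_setequal(vapply(try_merge(seg, v, p)$states, `[[`, character(1),
                         "status"), c("active", "merged"))
})
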