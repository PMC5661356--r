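# Shared fixture builders: small, fully in-code videos and masks.

# Deterministic random video stack.
rand_video <- function(T = 50, H = 6, W = 6, seed = 42, mean = 0, sd = 1,
                       frame_rate = NULL) {
  set.seed(seed)
  video_stack(array(rnorm(T * H * W, mean, sd), dim = c(T, H, W)),
              frame_rate = frame_rate)
}

# Two-region video: a disc with a common activity trace on a constant
# background, plus optional noise. Returns video + mask + traces.
two_region_video <- function(H = 24, W = 24, T = 60, centre = c(12, 12),
                             radius = 5, cell_level = 60, bg_level = 20,
                             noise_sd = 0, seed = 9, frame_rate = 10) {
  set.seed(seed)
  mask <- caimseg:::disc_mask(H, W, centre, radius)
  cell_tc <- cell_level + 30 * sin(seq_len(T) / 3) + rnorm(T, 0, 4)
  bg_tc <- rep(bg_level, T)
  arr <- array(rep(bg_tc, each = 1), dim = c(T, H, W))
  for (t in seq_len(T)) {
    fr <- matrix(bg_tc[t], H, W)
    fr[mask] <- cell_tc[t]
    arr[t, , ] <- fr
  }
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
  list(video = video_stack(arr, frame_rate = frame_rate), mask = mask,
       cell_tc = cell_tc, bg_tc = bg_tc)
}

# Jaccard index of two masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Direct two-region external energy (independent implementation of the
# single-cell cost: interior vs narrowband against their mean features).
direct_two_region_energy <- function(video, interior, narrowband, metric) {
  M <- caimseg:::pixel_matrix(video)
  f_in <- colMeans(M[which(interior), , drop = FALSE])
  f_out <- colMeans(M[which(narrowband), , drop = FALSE])
  D <- if (metric == "euclidean") euclidean_dissimilarity
       else correlation_dissimilarity
  e <- 0
  for (p in which(interior)) e <- e + D(M[p, ], f_in)
  for (p in which(narrowband)) e <- e + D(M[p, ], f_out)
  e
}
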