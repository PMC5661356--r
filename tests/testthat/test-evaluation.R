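test_that("success rate reproduces its closed forms", {
  expect_equal(round(success_rate(56.5, 73.1), 1), 63.7)
  # the published table prints 63.4 for this row (its success column was
  # evidently computed from unrounded precision/recall); the harmonic mean
  # of the printed one-decimal values agrees within one printed ulp
  expect_equal(success_rate(60.7, 66.5), 63.4, tolerance = 0.1 / 63.4)
  expect_equal(success_rate(80, 80), 80)            # fixed point
  expect_equal(success_rate(0, 0), 0)
  expect_equal(success_rate(30, 70), success_rate(70, 30))
  # bounded by its arguments
  set.seed(2)
  for (i in 1:25) {
    p <- runif(1, 0, 100); r <- runif(1, 0, 100)
    s <- success_rate(p, r)
    expect_gte(s, min(p, r) - 1e-9)
    expect_lte(s, max(p, r) + 1e-9)
  }
})

test_that("roi matching obeys the distance gate and is optimal", {
  truth <- rbind(c(10, 10), c(30, 30))
  expect_equal(nrow(match_rois(truth, truth)$pairs), 2L)
  expect_equal(match_rois(truth, truth)$pairs$dist, c(0, 0))

  # 6 px apart -> both unmatched under the 5 px rule
  m <- match_rois(rbind(c(10, 16)), rbind(c(10, 10)))
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$unmatched_est, 1L)
  expect_equal(m$unmatched_truth, 1L)

  # brute-force assignment oracle on random small instances
  set.seed(14)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  for (rep in 1:10) {
    ne <- sample(1:5, 1); nt <- sample(1:5, 1)
    est <- matrix(runif(ne * 2, 0, 25), ne, 2)
    tru <- matrix(runif(nt * 2, 0, 25), nt, 2)
    got <- match_rois(est, tru, max_dist = 6)
    d <- as.matrix(stats::dist(rbind(est, tru)))[seq_len(ne),
                                                 ne + seq_len(nt),
                                                 drop = FALSE]
    # exhaustive search over injections est -> truth (padded)
    best <- c(-1, Inf)
    k <- min(ne, nt)
    for (pm in perms(seq_len(max(ne, nt)))) {
      sel <- pm[seq_len(ne)]
      ok <- sel <= nt
      dd <- d[cbind(which(ok), sel[ok])]
      use <- dd <= 6
      score <- c(sum(use), sum(dd[use]))
      if (score[1] > best[1] ||
          (score[1] == best[1] && score[2] < best[2] - 1e-12))
        best <- score
    }
    expect_equal(nrow(got$pairs), best[1])
    if (nrow(got$pairs))
      expect_equal(sum(got$pairs$dist), best[2], tolerance = 1e-9)
    expect_true(all(got$pairs$dist <= 6))
    expect_equal(anyDuplicated(got$pairs$est), 0L)
    expect_equal(anyDuplicated(got$pairs$truth), 0L)
  }
})

test_that("precision/recall/fallout follow the set arithmetic", {
  set.seed(8)
  for (rep in 1:10) {
    nt <- sample(3:12, 1)
    tru <- cbind(runif(nt, 10, 90), runif(nt, 10, 90))
    keep <- runif(nt) < 0.7
    est <- tru[keep, , drop = FALSE] +
      matrix(runif(2 * sum(keep), -2, 2), ncol = 2)
    nfp <- sample(0:3, 1)
    if (nfp) est <- rbind(est, cbind(runif(nfp, 150, 200),
                                     runif(nfp, 150, 200)))
    m <- match_rois(est, tru)
    prf <- precision_recall_fallout(m)
    expect_equal(prf$precision, 100 * nrow(m$pairs) / nrow(est))
    expect_equal(prf$recall, 100 * nrow(m$pairs) / nt)
    expect_equal(prf$fallout, 100 - prf$precision)
  }
  # 9 of 10 matched
  tru <- cbind(seq(10, 100, by = 10), 50)
  est <- tru; est[10, ] <- c(500, 500)
  prf <- precision_recall_fallout(match_rois(est, tru))
  expect_equal(prf$precision, 90)
  expect_equal(prf$recall, 90)
  expect_equal(prf$fallout, 10)
  # zero estimates: undefined precision flagged
  prf0 <- precision_recall_fallout(match_rois(matrix(numeric(0), 0, 2), tru))
  expect_true(prf0$undefined_precision)
  expect_equal(prf0$precision, 0)
})

test_that("swapping estimate and truth roles swaps precision and recall", {
  set.seed(19)
  a <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  b <- cbind(runif(9, 0, 50), runif(9, 0, 50))
  f <- precision_recall_fallout(match_rois(a, b))
  g <- precision_recall_fallout(match_rois(b, a))
  expect_equal(f$precision, g$recall)
  expect_equal(f$recall, g$precision)
})

test_that("spike matching applies the 0.22 s window and timing errors", {
  t0 <- c(1, 2, 3.5, 7)
  r <- match_spikes(t0, t0)
  expect_equal(r$recall, 100)
  expect_equal(r$rmse, 0)

  # single spike offset by 0.3 s is unmatched
  r2 <- match_spikes(5.3, 5.0)
  expect_equal(nrow(r2$match$pairs), 0L)
  # 0.2 s offset is matched
  r3 <- match_spikes(5.2, 5.0)
  expect_equal(nrow(r3$match$pairs), 1L)
  expect_equal(r3$mae, 0.2)

  # jittered train: RMSE recovers the jitter SD
  set.seed(33)
  truth <- sort(runif(400, 0, 4000))
  jit <- rnorm(length(truth), 0, 0.05)
  r4 <- match_spikes(truth + jit, truth)
  expect_equal(r4$rmse, 0.05, tolerance = 0.2)
})

test_that("snr conversions are exact and invertible", {
  expect_equal(snr_db(4, 4), 0)
  expect_equal(snr_db(40, 4), 10)
  expect_error(snr_db(-1, 2), "positive")
  set.seed(4)
  x <- runif(20, 0.1, 100)
  expect_equal(snr_ratio(snr_db(x, 1)), x, tolerance = 1e-12)
  expect_equal(snr_db(snr_ratio(x), 1), x, tolerance = 1e-12)
})

test_that("trace SNR estimation recovers a constructed SNR", {
  # 30% of pixels carry a shared smooth signal of known variance over
  # white noise of known variance
  set.seed(44)
  H <- 30; W <- 30; T <- 400
  sig <- 4 * sin(seq_len(T) / 5)            # var = 8
  noise_sd <- 2
  carrier <- matrix(runif(H * W) < 0.3, H, W)
  arr <- array(rnorm(T * H * W, 0, noise_sd), dim = c(T, H, W))
  for (t in seq_len(T)) arr[t, , ][carrier] <- arr[t, , ][carrier] + sig[t]
  v <- video_stack(arr)
  n <- 25
  est <- estimate_trace_snr(v, n_pixels = n)
  expected <- snr_db(var(sig), noise_sd^2 / n)
  expect_equal(est, expected, tolerance = 0.15)
})
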