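#' Euclidean dissimilarity between time courses
#'
#' `||x - f||_2`, the default metric for data in which both the pattern and
#' the magnitude of a pixel's temporal activity are informative (typical
#' for synthetic dyes). Zero if and only if the two time courses are
#' identical.
#'
#' @param x,f numeric vectors of equal length (fluorescence time courses).
#' @return a non-negative scalar.
#' @seealso [correlation_dissimilarity()]
#' @examples
#' euclidean_dissimilarity(c(1, 0, 0), c(0, 0, 0))
#' @export
euclidean_dissimilarity <- function(x, f) {
  if (length(x) != length(f))
    stop_input("time courses must have equal length")
  sqrt(sum((x - f)^2))
}

#' Correlation dissimilarity between time courses
#'
#' `1 - cor(x, f)` with the Pearson correlation coefficient, in `[0, 2]`.
#' Invariant to positive affine rescaling of either argument, so pixels
#' that follow the same activity pattern at different brightness (donut
#' cells, uneven indicator expression) score as similar. If either input
#' has zero variance the correlation is undefined; a flat trace is treated
#' as maximally uninformative (correlation 0), giving dissimilarity 1.
#'
#' @param x,f numeric vectors of equal length, at least 2 samples.
#' @return a scalar in `[0, 2]`.
#' @export
correlation_dissimilarity <- function(x, f) {
  if (length(x) != length(f))
    stop_input("time courses must have equal length")
  if (length(x) < 2L)
    stop_input("correlation dissimilarity needs at least 2 samples")
  sx <- sum((x - mean(x))^2)
  sf <- sum((f - mean(f))^2)
  if (sx == 0 || sf == 0) return(1)
  1 - sum((x - mean(x)) * (f - mean(f))) / sqrt(sx * sf)
}

# Dissimilarities between each row of a pixel-by-time matrix and a single
# feature time course. `prep` carries per-row centred values and norms for
# the correlation metric so they are computed once per video.
row_dissimilarity <- function(M, f, metric, prep = NULL) {
  if (metric == "euclidean") {
    sqrt(rowSums((M - rep(f, each = nrow(M)))^2))
  } else {
    f0 <- f - mean(f)
    nf <- sqrt(sum(f0^2))
    if (nf == 0) return(rep(1, nrow(M)))
    if (is.null(prep)) {
      ctr <- M - rowMeans(M)
      nrm <- sqrt(rowSums(ctr^2))
    } else {
      ctr <- prep$ctr
      nrm <- prep$nrm
    }
    r <- as.vector(ctr %*% f0) / (ifelse(nrm > 0, nrm, 1) * nf)
    1 - ifelse(nrm > 0, r, 0)
  }
}

# As row_dissimilarity but with a different feature per row (rows of F).
rowwise_dissimilarity <- function(M, F, metric, prep = NULL) {
  if (metric == "euclidean") {
    sqrt(rowSums((M - F)^2))
  } else {
    F0 <- F - rowMeans(F)
    nF <- sqrt(rowSums(F0^2))
    if (is.null(prep)) {
      ctr <- M - rowMeans(M)
      nrm <- sqrt(rowSums(ctr^2))
    } else {
      ctr <- prep$ctr
      nrm <- prep$nrm
    }
    r <- rowSums(ctr * F0) / (ifelse(nrm > 0, nrm, 1) * ifelse(nF > 0, nF, 1))
    1 - ifelse(nrm > 0 & nF > 0, r, 0)
  }
}
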