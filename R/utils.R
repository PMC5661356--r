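# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shift a matrix by (dr, dc) replicating border values (Neumann boundary).
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_pad <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Row/col indices of TRUE pixels of a mask as a 2-column matrix.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# Centroid (row, col) of a boolean mask.
mask_centroid <- function(mask) {
  xy <- mask_coords(mask)
  c(mean(xy[, 1]), mean(xy[, 2]))
}

# 8-connected labelling of a boolean mask (EBImage::bwlabel is 4-connected).
label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  idx <- which(mask)
  if (!length(idx)) return(lab)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack[1L] <- start
    top <- 1L
    lab[start] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- (p - 1L) %% h + 1L
      cc <- (p - 1L) %/% h + 1L
      for (k in 1:8) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 < 1L || r2 > h || c2 < 1L || c2 > w) next
        q <- (c2 - 1L) * h + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- q
        }
      }
    }
  }
  lab
}

# Disc mask of given radius centred at (row, col) in an h x w field.
disc_mask <- function(h, w, centre, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

stop_input <- function(...) stop(..., call. = FALSE)
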