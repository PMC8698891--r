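# Independent oracles and small scene builders shared across tests.

# brute-force Otsu: exhaustively minimize within-class variance over the
# same histogram bins the implementation uses
otsu_bruteforce <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  levels <- 256L
  integral <- all(v == round(v)) && (hi - lo + 1) <= levels
  if (integral) {
    vals <- lo:hi
    bins <- v - lo + 1L
  } else {
    width <- (hi - lo) / levels
    bins <- pmin(levels, floor((v - lo) / width) + 1L)
    vals <- lo + seq_len(levels) * width
  }
  counts <- tabulate(bins, nbins = length(vals))
  wvar <- function(x, wt) {
    if (sum(wt) == 0) return(0)
    m <- sum(x * wt) / sum(wt)
    sum(wt * (x - m)^2) / sum(wt)
  }
  within <- vapply(seq_len(length(vals) - 1L), function(t) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) return(Inf)
    (w0 * wvar(vals[1:t], counts[1:t]) +
       w1 * wvar(vals[-(1:t)], counts[-(1:t)])) / sum(counts)
  }, numeric(1))
  best <- min(within)
  ties <- which(within <= best + 1e-10 * max(best, 1))
  mean(vals[ties])
}

# recursive flood-fill labeling oracle (queue-based)
floodfill_labels <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  k <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (j in seq_along(dr)) {
        r <- p[1] + dr[j]; c <- p[2] + dc[j]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# two labelings agree up to renumbering iff the label pairing is bijective
labels_equivalent <- function(a, b) {
  if (any((a > 0) != (b > 0))) return(FALSE)
  on <- a > 0
  if (!any(on)) return(TRUE)
  pairs <- unique(cbind(a[on], b[on]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# direct covariance-based moment oracle for a pixel set (rows, cols)
moments_oracle <- function(px) {
  x <- px[, 2]; y <- -px[, 1]  # y-up
  n <- nrow(px)
  vxx <- mean(x^2) - mean(x)^2 + 1 / 12
  vyy <- mean(y^2) - mean(y)^2 + 1 / 12
  vxy <- mean(x * y) - mean(x) * mean(y)
  tr2 <- (vxx + vyy) / 2
  disc <- sqrt(((vxx - vyy) / 2)^2 + vxy^2)
  l1 <- tr2 + disc; l2 <- tr2 - disc
  th <- 0.5 * atan2(2 * vxy, vxx - vyy) * 180 / pi
  if (th <= -90) th <- th + 180
  list(ecc = sqrt(max(0, 1 - l2 / l1)), orientation = th,
       l1 = l1, l2 = l2)
}

# small noiseless scene with a handful of well-separated opacities
tiny_scene <- function(opacities = list(), speckle = Inf, width = 220,
                       height = 120) {
  scene_spec(width = width, height = height, speckle_shape = speckle,
             opacities = opacities)
}

tiny_calibration <- function(width = 220, height = 120) {
  default_calibration(width_px = width, height_px = height,
                      width_mm = 3 * width / 1536,
                      height_mm = 0.969 * height / 496)
}
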