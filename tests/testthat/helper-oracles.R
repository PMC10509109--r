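# Independent reference implementations used as oracles in tests.
# These deliberately take the naive route (flood fill, pair counting,
# explicit ANOVA) so they share no code with the package internals.

# exhaustive 8-connected flood fill over a logical matrix; returns an
# integer label matrix (0 = background)
flood_fill_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# tau-b by brute-force pair counting over the expanded subject list
tau_b_pairs <- function(x, y) {
  n <- length(x)
  P <- 0; Q <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) P <- P + 1
    else Q <- Q + 1
  }
  n0 <- n * (n - 1) / 2
  (P - Q) / sqrt((P + Q + tx) * (P + Q + ty))
}

# ICC(A,1) via an explicit two-way ANOVA fit (long format, aov)
icc_a1_aov <- function(ref, cmp) {
  n <- length(ref)
  d <- data.frame(y = c(ref, cmp),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# pixel count of a rasterized disc by direct enumeration over the full grid
disc_pixel_count <- function(center, radius_px, nr = 512, nc = 512) {
  ctr_r <- center[1]; ctr_c <- center[2]
  count <- 0L
  for (j in seq_len(nc)) {
    dc2 <- (j - ctr_c)^2
    if (dc2 > radius_px^2) next
    count <- count + sum((seq_len(nr) - ctr_r)^2 + dc2 <= radius_px^2)
  }
  count
}

# small volume builder for scoring tests (default spacing = 250/512 mm)
tiny_volume <- function(nr = 32, nc = 32, ns = 1, background = 40,
                        spacing = 250 / 512) {
  image_volume(array(as.integer(background), dim = c(nr, nc, ns)),
               pixel_spacing = spacing)
}
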