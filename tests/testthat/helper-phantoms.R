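# Geometric phantoms and small fixture images used across the suite.

# Logical disk mask.
disk_mask <- function(h, w, cr, cc, r) {
  dy <- outer(seq_len(h) - cr, rep(1, w))
  dx <- outer(rep(1, h), seq_len(w) - cc)
  dy^2 + dx^2 <= r^2
}

# Minimal calibrated test image: bluish noisy background with dark disks.
# `disks` is a data frame with columns cr, cc, r (px) and optionally
# core_r (px). Background red ~150, pellet red ~60, core luma dark.
phantom_image <- function(h = 200, w = 200, disks = NULL, pixel_size = 10,
                          bg_red = 150, noise = 2, seed = 42) {
  set.seed(seed)
  R <- matrix(bg_red, h, w) + matrix(rnorm(h * w, 0, noise), h, w)
  G <- matrix(155, h, w) + matrix(rnorm(h * w, 0, noise), h, w)
  B <- matrix(210, h, w) + matrix(rnorm(h * w, 0, noise), h, w)
  if (!is.null(disks)) for (i in seq_len(nrow(disks))) {
    m <- disk_mask(h, w, disks$cr[i], disks$cc[i], disks$r[i])
    R[m] <- 60; G[m] <- 110; B[m] <- 140
    if (!is.null(disks$core_r) && !is.na(disks$core_r[i]) &&
        disks$core_r[i] > 0) {
      cm <- disk_mask(h, w, disks$cr[i], disks$cc[i], disks$core_r[i])
      R[cm] <- 55; G[cm] <- 45; B[cm] <- 55
    }
  }
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- round(pmin(255, pmax(0, R)))
  px[, , 2] <- round(pmin(255, pmax(0, G)))
  px[, , 3] <- round(pmin(255, pmax(0, B)))
  calibrated_image(px, pixel_size, source_id = "phantom")
}

# Brute-force oracle for the 3-class between-class-variance criterion:
# naive scan over all boundary pairs of observed values, recomputing class
# weights and means directly at every pair. Independent of the package's
# prefix-sum implementation.
brute_force_three_level <- function(x) {
  v <- sort(unique(as.numeric(x)))
  vals <- as.numeric(x)
  best_crit <- -Inf
  best <- c(NA, NA)
  for (i in 1:(length(v) - 2)) {
    for (j in (i + 1):(length(v) - 1)) {
      c1 <- vals[vals <= v[i]]
      c2 <- vals[vals > v[i] & vals <= v[j]]
      c3 <- vals[vals > v[j]]
      mu <- mean(vals)
      crit <- length(c1) / length(vals) * (mean(c1) - mu)^2 +
        length(c2) / length(vals) * (mean(c2) - mu)^2 +
        length(c3) / length(vals) * (mean(c3) - mu)^2
      if (crit > best_crit + 1e-12) {
        best_crit <- crit
        best <- c((v[i] + v[i + 1]) / 2, (v[j] + v[j + 1]) / 2)
      }
    }
  }
  best
}

# IoU between two logical masks.
mask_iou <- function(a, b) sum(a & b) / sum(a | b)
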