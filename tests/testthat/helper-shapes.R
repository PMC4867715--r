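# Shared fixtures and independent oracles, built in code at test time.

# A reproducible non-degenerate random shape.
rand_shape <- function(k = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(2 * k, -1, 1), ncol = 2)
}

# Apply a similarity transform (rotation theta, scaling s, translation t).
sim_transform <- function(x, theta = 0, s = 1, t = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(x %*% R * s, 2, t, `+`)
}

# Independent closed-form oracle for the partial Procrustes distance of 2D
# shapes, via complex arithmetic on Kendall preshapes: with unit-norm
# centered complex vectors z and w, the rotation-minimized squared
# distance is 2 - 2 * |<z, w>|.
complex_procrustes_oracle <- function(a, b) {
  z <- complex(real = a[, 1], imaginary = a[, 2])
  w <- complex(real = b[, 1], imaginary = b[, 2])
  z <- z - mean(z); z <- z / sqrt(sum(Mod(z)^2))
  w <- w - mean(w); w <- w / sqrt(sum(Mod(w)^2))
  sqrt(max(0, 2 - 2 * Mod(sum(Conj(z) * w))))
}

# Brute-force rotation-grid oracle for the superimposition residual.
grid_search_residual <- function(a, b, step_deg = 0.1) {
  ac <- scale(a, scale = FALSE); ac <- ac / sqrt(sum(ac^2))
  bc <- scale(b, scale = FALSE); bc <- bc / sqrt(sum(bc^2))
  thetas <- seq(0, 2 * pi, by = step_deg * pi / 180)
  min(vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((ac %*% R - bc)^2)
  }, numeric(1)))
}

# Assert two configurations share a shape: superimpose and compare
# coordinates (avoids the sqrt-precision floor of near-zero Procrustes
# distances).
expect_same_shape <- function(a, b, tol = 1e-9) {
  fit <- superimpose(a, b)
  bb <- scale(b, scale = FALSE)
  bb <- bb / sqrt(sum(bb^2))
  expect_lt(max(abs(fit$aligned - bb)), tol)
}

# Point-in-polygon (ray casting) and segment-intersection helpers for the
# template topology checks.
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  idx <- rbind(cbind(seq_len(n), c(2:n, 1)))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (segments_cross(poly[idx[i, 1], ], poly[idx[i, 2], ],
                         poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(FALSE)
    }
  TRUE
}

# A small three-group score dataset with known separation, for LDA tests.
make_group_scores <- function(n_per = 15, p = 6, sep = 5, seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("A", "B", "C"), each = n_per))
  centers <- rbind(c(rep(0, p)),
                   c(sep, rep(0, p - 1)),
                   c(0, sep, rep(0, p - 2)))
  x <- centers[as.integer(g), ] + matrix(rnorm(3 * n_per * p), ncol = p)
  colnames(x) <- paste0("PC", seq_len(p))
  list(x = x, g = g)
}

# A small taxonomy for io tests (labels drawn from the valid schemes).
toy_taxonomy <- function(ids) {
  data.frame(specimen_id = ids,
             species = "Cebus_albifrons", genus = "Cebus",
             subfamily_G = "Cebinae", subfamily_R = "Cebinae",
             family = "Cebidae", fossil_flag = FALSE,
             fossil_code = NA_character_, stringsAsFactors = FALSE)
}
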