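make_study <- function(n_spec = 3, n_rep = 3, sigma = 0.01, seed = 1) {
  set.seed(seed)
  bases <- lapply(seq_len(n_spec), function(i)
    molar_template() + matrix(rnorm(30, sd = 0.05), ncol = 2))
  names(bases) <- sprintf("sp%d", seq_len(n_spec))
  generate_repetition_study(bases, n_rep = n_rep, digit_sigma = sigma,
                            seed = seed + 100)
}

test_that("identical repetitions give zero paired distances, with the right pair count", {
  study <- make_study(n_spec = 3, n_rep = 3, sigma = 0)
  res <- repetition_distances(study)
  expect_equal(res$mean, 0, tolerance = 1e-12)
  expect_equal(res$sd, 0, tolerance = 1e-12)
  expect_equal(nrow(res$distances), 3 * choose(3, 2))
  expect_equal(as.vector(table(res$distances$specimen)), rep(3L, 3))
})

test_that("paired distances grow monotonically with digitizing noise", {
  sigmas <- c(0.001, 0.005, 0.01)
  means <- vapply(seq_along(sigmas), function(i) {
    m <- vapply(1:50, function(b) {
      st <- generate_repetition_study(molar_template(), n_rep = 3,
                                      digit_sigma = sigmas[i],
                                      seed = 1000 * i + b)
      repetition_distances(st)$mean
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the Mantel statistic behaves as a matrix correlation", {
  set.seed(2)
  x <- matrix(rnorm(20 * 3), ncol = 3)
  D <- as.matrix(dist(x))
  expect_equal(mantel_test(D, D, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  # invariance to positive affine rescaling of the off-diagonal entries
  D2 <- 3.2 * D + 0.7
  diag(D2) <- 0
  expect_equal(mantel_test(D, D2, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  dimnames(D2) <- list(letters[1:20], letters[1:20])
  dimnames(D) <- list(LETTERS[1:20], LETTERS[1:20])
  expect_error(mantel_test(D, D2), "mismatched ids")
})

test_that("the Mantel statistic matches the reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  d1 <- as.matrix(dist(matrix(rnorm(15 * 4), ncol = 4)))
  d2 <- as.matrix(dist(matrix(rnorm(15 * 4), ncol = 4)))
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  # p-values from independent permutation streams agree loosely
  expect_lt(abs(ours$p - ref$signif), 0.25)
})

test_that("Mantel r is invariant to joint row/column permutation", {
  set.seed(4)
  d1 <- as.matrix(dist(matrix(rnorm(12 * 3), ncol = 3)))
  d2 <- as.matrix(dist(matrix(rnorm(12 * 3), ncol = 3)))
  r0 <- mantel_test(d1, d2, n_perm = 9, seed = 1)$r
  pp <- sample(12)
  r1 <- mantel_test(d1[pp, pp], d2[pp, pp], n_perm = 9, seed = 1)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("repetition-wise Mantel correlations are near one for small noise", {
  study <- make_study(n_spec = 5, n_rep = 4, sigma = 0.002, seed = 5)
  rep_r <- repeatability_mantel(study)
  expect_length(rep_r$r, choose(4, 2))
  expect_gt(rep_r$mean_r, 0.95)
  expect_lte(rep_r$mean_r, 1)
})

test_that("the pseudo-F equals per-coordinate classical sums of squares", {
  set.seed(6)
  x <- matrix(rnorm(24 * 5), ncol = 5)
  g <- factor(rep(c("a", "b", "c"), each = 8))
  res <- perm_manova(x, g, n_perm = 9, seed = 1)
  # closed-form oracle: classical one-way SS summed over coordinates
  a <- nlevels(g); n <- nrow(x)
  ssb <- sum(vapply(seq_len(ncol(x)), function(j) {
    m <- tapply(x[, j], g, mean)
    sum(table(g) * (m - mean(x[, j]))^2)
  }, numeric(1)))
  ssw <- sum(vapply(seq_len(ncol(x)), function(j)
    sum(tapply(x[, j], g, function(v) sum((v - mean(v))^2))), numeric(1)))
  f_oracle <- (ssb / (a - 1)) / (ssw / (n - a))
  expect_equal(res$F, f_oracle, tolerance = 1e-9)
  expect_equal(res$ss_between, ssb, tolerance = 1e-9)
  expect_equal(res$ss_within, ssw, tolerance = 1e-9)
})

test_that("the pseudo-F matches the reference permutational MANOVA", {
  skip_if_not_installed("vegan")
  set.seed(7)
  x <- matrix(rnorm(30 * 4), ncol = 4)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  res <- perm_manova(x, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 99)
  expect_equal(res$F, ref$F[1], tolerance = 1e-9)
})

test_that("duplicated groups give a near-zero pseudo-F and p near one", {
  set.seed(8)
  block <- matrix(rnorm(10 * 4), ncol = 4)
  x <- rbind(block, block)
  g <- factor(rep(c("a", "b"), each = 10))
  res <- perm_manova(x, g, n_perm = 199, seed = 2)
  expect_lt(res$F, 1e-9)
  expect_gt(res$p, 0.95)
})

test_that("a strong group offset is detected at the permutation floor", {
  set.seed(9)
  sigma <- 1
  x <- rbind(matrix(rnorm(15 * 4, sd = sigma), ncol = 4),
             matrix(rnorm(15 * 4, mean = 10 * sigma, sd = sigma), ncol = 4))
  g <- factor(rep(c("a", "b"), each = 15))
  res <- perm_manova(x, g, n_perm = 999, seed = 3)
  expect_lte(res$p, 0.001)
})

test_that("permutation routines are reproducible and leave the RNG alone", {
  set.seed(10)
  d1 <- as.matrix(dist(matrix(rnorm(10 * 3), ncol = 3)))
  d2 <- as.matrix(dist(matrix(rnorm(10 * 3), ncol = 3)))
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  p1 <- mantel_test(d1, d2, n_perm = 99, seed = 42)$p
  after <- rnorm(1)
  expect_equal(before, after)
  p2 <- mantel_test(d1, d2, n_perm = 99, seed = 42)$p
  expect_identical(p1, p2)
})

test_that("the full error study summarizes all three components", {
  study <- make_study(n_spec = 5, n_rep = 9, sigma = 0.01, seed = 11)
  res <- error_study(study, n_perm = 199, seed = 4)
  expect_gt(res$mean_pairwise, 0)
  expect_gte(res$sd_pairwise, 0)
  expect_true(res$mantel_r_mean >= -1 && res$mantel_r_mean <= 1)
  expect_gte(res$manova_F, 0)
  expect_true(res$manova_p > 0 && res$manova_p <= 1)
  # repetitions carry no group signal, so the repetition factor is null
  expect_gt(res$manova_p, 0.2)
  # grouping by digitization day works too
  res_day <- error_study(study, group_by = "day", n_perm = 99, seed = 5)
  expect_true(res_day$manova_p > 0 && res_day$manova_p <= 1)
})
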