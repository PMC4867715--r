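test_that("two groups give one discriminant function carrying all variance", {
  d <- make_group_scores(n_per = 12, sep = 3, seed = 1)
  two <- d$g != "C"
  fit <- shape_lda(d$x[two, ], droplevels(d$g[two]))
  expect_length(fit$df_percent, 1)
  expect_equal(fit$df_percent, 100, ignore_attr = TRUE)
})

test_that("well-separated synthetic groups classify perfectly", {
  d <- make_group_scores(n_per = 15, sep = 12, seed = 2)
  fit <- shape_lda(d$x, d$g)
  expect_equal(fit$pcc_original, 100)
  cv <- loocv_pcc(fit)
  expect_equal(cv$pcc, 100)
})

test_that("posteriors are normalized and centroid placement wins the arg-max", {
  d <- make_group_scores(n_per = 15, sep = 4, seed = 3)
  fit <- shape_lda(d$x, d$g)
  at_centroid <- predict(fit, fit$means["B", ])
  expect_identical(as.character(at_centroid$class), "B")
  expect_equal(rowSums(at_centroid$posterior), 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(4)
  unknowns <- matrix(rnorm(5 * ncol(d$x), sd = 3), nrow = 5)
  pr <- predict(fit, unknowns)
  expect_equal(rowSums(pr$posterior), rep(1, 5), tolerance = 1e-9)
})

test_that("the fit agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  d <- make_group_scores(n_per = 20, sep = 2.5, seed = 5)
  fit <- shape_lda(d$x, d$g)
  ref <- MASS::lda(d$x, grouping = d$g,
                   prior = rep(1 / 3, 3))
  # discriminant-function variance shares
  expect_equal(fit$df_percent, 100 * ref$svd^2 / sum(ref$svd^2),
               tolerance = 1e-6, ignore_attr = TRUE)
  # posterior probabilities and class assignments on the training data
  pr_ref <- predict(ref, d$x)
  pr_fit <- predict(fit, d$x)
  expect_equal(unclass(pr_fit$posterior), unclass(pr_ref$posterior),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.character(pr_fit$class), as.character(pr_ref$class))
})

test_that("leave-one-out equals a from-scratch brute-force refit oracle", {
  d <- make_group_scores(n_per = 30, p = 8, sep = 1.5, seed = 6)  # n = 90
  fit <- shape_lda(d$x, d$g)
  cv <- loocv_pcc(fit)
  # independent oracle: naive per-fold statistics and Mahalanobis rule
  oracle <- vapply(seq_len(nrow(d$x)), function(i) {
    xt <- d$x[-i, , drop = FALSE]
    gt <- d$g[-i]
    mns <- do.call(rbind, lapply(levels(gt), function(l)
      colMeans(xt[gt == l, , drop = FALSE])))
    sw <- Reduce(`+`, lapply(levels(gt), function(l) {
      xg <- xt[gt == l, , drop = FALSE]
      crossprod(sweep(xg, 2, colMeans(xg)))
    })) / (nrow(xt) - nlevels(gt))
    d2 <- apply(mns, 1, function(m)
      drop(t(d$x[i, ] - m) %*% solve(sw, d$x[i, ] - m)))
    levels(gt)[which.min(d2)]
  }, character(1))
  expect_identical(as.character(cv$predicted), oracle)
})

test_that("permuted labels classify at chance level", {
  set.seed(7)
  x <- matrix(rnorm(400 * 6), ncol = 6)
  g <- factor(sample(rep(c("A", "B", "C"), length.out = 400)))
  cv <- loocv_pcc(x, g)
  expect_gt(cv$pcc, 100 / 3 - 5)
  expect_lt(cv$pcc, 100 / 3 + 5)
})

test_that("discriminant variance shares are invariant to invertible score maps", {
  d <- make_group_scores(n_per = 15, sep = 3, seed = 8)
  fit <- shape_lda(d$x, d$g)
  set.seed(9)
  repeat {   # a well-conditioned random invertible map
    A <- matrix(rnorm(ncol(d$x)^2), ncol(d$x))
    if (kappa(A) < 50) break
  }
  fit2 <- shape_lda(d$x %*% A, d$g)
  expect_equal(fit$df_percent, fit2$df_percent, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with actionable errors", {
  d <- make_group_scores(n_per = 10, sep = 3, seed = 10)
  g1 <- as.character(d$g)
  g1[g1 == "C"] <- "B"
  g1[30] <- "C"   # group with a single member
  expect_error(shape_lda(d$x, factor(g1)), "at least 2 specimens")
  # a constant score column is singular however few PCs are kept
  expect_error(shape_lda(matrix(1, nrow(d$x), 1), d$g), "singular")
  # a duplicated leading column is dropped by the automatic retention rule
  xx <- cbind(d$x[, 1], d$x[, 1])
  expect_equal(shape_lda(xx, d$g)$n_pcs, 1L)
  expect_error(shape_lda(d$x, d$g[1:10]), "one label per row")
})

test_that("automatic PC retention keeps the pooled covariance well-conditioned", {
  d <- make_group_scores(n_per = 15, p = 8, sep = 3, seed = 11)
  # append a near-constant column: variance 1e-20 versus O(1)
  x <- cbind(d$x, tiny = rnorm(nrow(d$x), sd = 1e-10))
  fit <- shape_lda(x, d$g)
  expect_lte(fit$n_pcs, 8)
  ev <- eigen(fit$pooled, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev) / min(ev), 1e8)
})

test_that("the four-factor run produces a complete classification table", {
  gen <- generate_dataset(synth_spec(taxonomy = platyrrhine_taxonomy(),
                                     n_fossils = 3), seed = 2)
  # thin the sample for speed: keep 4 specimens per species
  ds <- gen$dataset
  keep <- unlist(lapply(split(ds$info$specimen_id, ds$info$species),
                        utils::head, 4))
  keep <- c(keep, ds$info$specimen_id[ds$info$fossil])
  ds$configs <- ds$configs[keep]
  ds$info <- ds$info[match(keep, ds$info$specimen_id), ]
  ds$taxonomy <- ds$taxonomy[ds$taxonomy$specimen_id %in% keep, ]
  ds <- standardize_dataset(ds)
  res <- run_all_ldas(list(M1 = ds))
  expect_equal(nrow(res$table), 4)
  expect_true(all(res$table$pcc_original >= 0 &
                    res$table$pcc_original <= 100))
  expect_true(all(res$table$pcc_crossval >= 0 &
                    res$table$pcc_crossval <= 100))
  # family level: 3 groups, so DF1 + DF2 carry all discriminant variance
  fam <- res$table[res$table$factor == "family", ]
  expect_equal(fam$df1_percent + fam$df2_percent, 100, tolerance = 1e-9)
  # fossil posteriors present for every factor, rows normalized
  expect_length(res$posteriors, 4)
  for (post in res$posteriors) {
    expect_equal(nrow(post), 3)
    expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
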