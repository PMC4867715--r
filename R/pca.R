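#' Principal component analysis of tangent shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the tangent-space
#' coordinates of the superimposed specimens (no column scaling: shape
#' coordinates share units). For k 2D landmarks after Procrustes
#' superimposition at most `2k - 4` components are non-null (translation,
#' scale and rotation are removed); `percent_variance` is reported over the
#' non-null components and sums to 100. Eigenvector signs follow a
#' deterministic rule: the loading coordinate of largest magnitude is made
#' positive.
#'
#' @param object a fitted [gpa()] object.
#' @param scope `"all"` fits the axes on every superimposed specimen
#'   (fossils included, as in a joint morphospace plot);
#'   `"extant"` fits on extant specimens only, with fossils to be projected
#'   afterwards via [predict.shape_pca()]. When the GPA carries no
#'   specimen metadata, `"all"` is used.
#' @return An object of class `"shape_pca"`: list with `eigenvalues`,
#'   `percent_variance`, `scores` (fitted specimens x components),
#'   `loadings` (2k x components, orthonormal columns), `center`,
#'   `consensus`, `n_nonnull`, `scope`, `info`.
#' @export
shape_pca <- function(object, scope = c("all", "extant")) {
  stopifnot(inherits(object, "gpa"))
  scope <- match.arg(scope)
  tang <- object$tangent
  keep <- rep(TRUE, nrow(tang))
  if (scope == "extant") {
    if (is.null(object$info)) scope <- "all"
    else keep <- !object$info$fossil
  }
  x <- tang[keep, , drop = FALSE]
  if (nrow(x) < 3L) stop("PCA needs at least 3 specimens after filtering")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  k <- object$k
  max_rank <- 2L * k - 4L
  n_nonnull <- min(max_rank, sum(eig > max(eig) * 1e-10))
  eig <- eig[seq_len(n_nonnull)]
  load <- pc$rotation[, seq_len(n_nonnull), drop = FALSE]
  scores <- pc$x[, seq_len(n_nonnull), drop = FALSE]
  # deterministic sign: largest-magnitude loading coordinate positive
  for (j in seq_len(n_nonnull)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(eigenvalues = eig,
         percent_variance = 100 * eig / sum(eig),
         scores = scores, loadings = load,
         center = pc$center,
         consensus = object$consensus,
         n_nonnull = n_nonnull,
         total_variance = sum(pc$sdev^2),
         scope = scope,
         fitted_ids = rownames(x),
         info = if (!is.null(object$info)) object$info[keep, , drop = FALSE]),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA (%s specimens): %d non-null components\n",
              x$scope, x$n_nonnull))
  pv <- x$percent_variance
  shown <- utils::head(pv, 5L)
  cat(sprintf("  PC%d: %5.2f%%\n", seq_along(shown), shown), sep = "")
  if (length(pv) > 5L)
    cat(sprintf("  ... (%d more components)\n", length(pv) - 5L))
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  tab <- data.frame(
    component = seq_len(object$n_nonnull),
    eigenvalue = object$eigenvalues,
    percent = object$percent_variance,
    cumulative = cumsum(object$percent_variance)
  )
  class(tab) <- c("summary.shape_pca", "data.frame")
  tab
}

#' Project new specimens onto fitted shape PCA axes
#'
#' Projects tangent-space coordinates (aligned to the same consensus as the
#' fit, e.g. fossil specimens from the joint superimposition) onto the
#' principal axes. The consensus itself (a zero tangent vector) projects to
#' the zero score vector up to the centering of the fitted sample.
#'
#' @param object a [shape_pca()] fit.
#' @param newdata a numeric vector of length 2k, an n x 2k matrix of
#'   tangent coordinates, or a [gpa()] object (all its specimens are
#'   projected).
#' @param ... unused.
#' @return A score matrix (rows = specimens, columns = components).
#' @export
predict.shape_pca <- function(object, newdata, ...) {
  if (inherits(newdata, "gpa")) newdata <- newdata$tangent
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$center))
    stop(sprintf("tangent dimension mismatch: %d vs %d", ncol(newdata),
                 length(object$center)))
  scores <- sweep(newdata, 2L, object$center) %*% object$loadings
  colnames(scores) <- colnames(object$loadings)
  scores
}

#' Scatterplot of the first two shape principal components
#'
#' PC1 x PC2 scatter with per-group 95% data ellipses and fossil overlays,
#' the usual morphospace display. The ellipses are data (dispersion)
#' ellipses of each group's scores, not confidence ellipses of the group
#' mean.
#'
#' @param x a [shape_pca()] fit.
#' @param groups factor of group labels for the fitted specimens; defaults
#'   to the `subfamily_G` column of the attached metadata.
#' @param fossil_scores optional matrix of projected fossil scores (from
#'   [predict.shape_pca()]) drawn as labelled points.
#' @param ellipse_level coverage of the data ellipses.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.shape_pca <- function(x, groups = NULL, fossil_scores = NULL,
                           ellipse_level = 0.95, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  if (is.null(groups) && !is.null(x$info)) groups <- x$info$subfamily_G
  xlab <- sprintf("PC1 (%.2f%%)", x$percent_variance[1])
  ylab <- sprintf("PC2 (%.2f%%)", x$percent_variance[2])
  graphics::plot(s, xlab = xlab, ylab = ylab, pch = 16, cex = 0.6,
                 col = if (is.null(groups)) "grey40"
                       else as.integer(factor(groups)) + 1L, ...)
  if (!is.null(groups)) {
    groups <- factor(groups)
    for (g in levels(groups)) {
      gs <- s[groups == g, , drop = FALSE]
      if (nrow(gs) < 3L) next
      e <- data_ellipse(gs, level = ellipse_level)
      graphics::lines(e, col = which(levels(groups) == g) + 1L)
    }
    graphics::legend("topright", legend = levels(groups), cex = 0.7,
                     col = seq_along(levels(groups)) + 1L, pch = 16,
                     bty = "n")
  }
  if (!is.null(fossil_scores)) {
    graphics::points(fossil_scores[, 1:2, drop = FALSE], pch = 23,
                     bg = "gold", cex = 1.1)
    graphics::text(fossil_scores[, 1:2, drop = FALSE],
                   labels = rownames(fossil_scores), pos = 3, cex = 0.7)
  }
  invisible(x)
}

# Points of a 95% (by default) data ellipse for a 2-column score matrix.
data_ellipse <- function(s, level = 0.95, n = 120L) {
  mu <- colMeans(s)
  sig <- stats::cov(s)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(theta), sin(theta))
  ch <- chol(sig)
  sweep(r * circ %*% ch, 2L, mu, `+`)
}

## ---- thin-plate splines ----------------------------------------------

tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

# Solve the 2D thin-plate-spline interpolation source -> target.
# Returns coefficient matrices and the bending energy (sum over the two
# coordinates of w' K w, zero iff the map is affine).
tps_solve <- function(source, target) {
  source <- as_shape_matrix(source)
  target <- as_shape_matrix(target)
  k <- nrow(source)
  if (nrow(target) != k) stop("source/target landmark count mismatch")
  d2 <- as.matrix(stats::dist(source))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, source)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  rhs <- rbind(target, matrix(0, 3L, 2L))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate-spline system (coincident landmarks?)",
         call. = FALSE))
  w <- coef[seq_len(k), , drop = FALSE]
  a <- coef[k + 1:3, , drop = FALSE]
  energy <- sum(diag(t(w) %*% K %*% w))
  list(w = w, a = a, source = source, energy = energy)
}

# Apply a solved TPS map to arbitrary points (m x 2).
tps_apply <- function(fit, pts) {
  pts <- as_shape_matrix(pts)
  d2 <- outer(rowSums(pts^2), rowSums(fit$source^2), `+`) -
    2 * pts %*% t(fit$source)
  d2[d2 < 0] <- 0
  U <- tps_kernel(d2)
  cbind(1, pts) %*% fit$a + U %*% fit$w
}

#' Thin-plate-spline warp of arbitrary points
#'
#' Interpolates the smooth (minimum bending energy) 2D deformation that
#' maps `source` landmarks exactly onto `target` landmarks, and applies it
#' to `points`.
#'
#' @param source,target k x 2 landmark matrices.
#' @param points m x 2 matrix of points to warp.
#' @return The warped m x 2 matrix.
#' @export
tps_warp <- function(source, target, points) {
  tps_apply(tps_solve(source, target), points)
}

#' Bending energy of a thin-plate-spline deformation
#'
#' Zero (to numerical precision) if and only if the source-to-target map is
#' affine; grows with the localized, non-uniform part of the deformation.
#'
#' @param source,target k x 2 landmark matrices.
#' @return A non-negative number.
#' @export
tps_bending_energy <- function(source, target) {
  max(0, tps_solve(source, target)$energy)
}

#' Deformation grid for a principal component extreme
#'
#' Thin-plate-spline interpolation of the shape change along one principal
#' component: the consensus is deformed to
#' `consensus + score * loading(component)` and the deformation is applied
#' to a rectangular lattice covering the consensus bounding box with a 10%
#' margin, the classic deformation-grid display of PC extremes.
#'
#' @param pca a [shape_pca()] fit.
#' @param component which component to display.
#' @param score the score at which to evaluate the deformation (e.g. an
#'   observed extreme); must lie within 1.5 x the observed score range.
#' @param lattice integer vector `c(nx, ny)` of grid lines.
#' @param margin fractional margin around the consensus bounding box.
#' @return An object of class `"deformation_grid"`: list with `component`,
#'   `score`, `grid` (undeformed lattice points), `warped` (deformed
#'   lattice), `nx`, `ny`, `consensus`, `warped_consensus`.
#' @export
warp_grid <- function(pca, component = 1L, score, lattice = c(24L, 24L),
                      margin = 0.1) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component > pca$n_nonnull) stop("component out of range")
  obs <- range(pca$scores[, component])
  lim <- 1.5 * max(abs(obs))
  if (abs(score) > lim)
    stop(sprintf("score %.4g outside 1.5 x observed range [%.4g, %.4g]",
                 score, obs[1], obs[2]))
  consensus <- pca$consensus
  target <- consensus + unflatten_shape(score * pca$loadings[, component])
  rx <- range(consensus[, 1]); ry <- range(consensus[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = lattice[1])
  gy <- seq(ry[1] - my, ry[2] + my, length.out = lattice[2])
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  fit <- tps_solve(consensus, target)
  structure(
    list(component = component, score = score, grid = grid,
         warped = tps_apply(fit, grid), nx = lattice[1], ny = lattice[2],
         consensus = consensus, warped_consensus = target,
         bending_energy = fit$energy),
    class = "deformation_grid"
  )
}

#' @export
print.deformation_grid <- function(x, ...) {
  cat(sprintf("Deformation grid: PC%d at score %.4g (%dx%d lattice)\n",
              x$component, x$score, x$nx, x$ny))
  cat(sprintf("  bending energy %.6g\n", x$bending_energy))
  invisible(x)
}

#' @export
plot.deformation_grid <- function(x, ...) {
  graphics::plot(x$warped, type = "n", asp = 1, xlab = "", ylab = "",
                 axes = FALSE,
                 main = sprintf("PC%d, score %.3g", x$component, x$score),
                 ...)
  w <- x$warped
  for (i in seq_len(x$ny))
    graphics::lines(w[((i - 1) * x$nx + 1):(i * x$nx), ], col = "grey55")
  for (j in seq_len(x$nx))
    graphics::lines(w[seq(j, x$nx * x$ny, by = x$nx), ], col = "grey55")
  graphics::points(x$warped_consensus, pch = 16, col = "firebrick")
  invisible(x)
}
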