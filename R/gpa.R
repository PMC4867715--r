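#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid: the size measure removed by Procrustes scaling. Invariant to
#' translation and rotation, and homogeneous of degree one in scale.
#'
#' @param x a k x 2 coordinate matrix or a [landmark_config()].
#' @return A positive number.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
centroid_size <- function(x) {
  if (inherits(x, "landmark_config")) x <- x$landmarks
  x <- as_shape_matrix(x)
  cs <- sqrt(sum(center_shape(x)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks identical")
  cs
}

# Center x and scale to unit centroid size.
preshape <- function(x) {
  x <- center_shape(as_shape_matrix(x))
  x / sqrt(sum(x^2))
}

# Optimal rotation carrying (centered) a onto (centered) b:
# maximizes tr(R' a' b). Returns list(rotation, s = corrected singular
# value sum, reflected = logical).
optimal_rotation <- function(a, b, allow_reflection = FALSE) {
  m <- crossprod(a, b)
  sv <- svd(m)
  d <- diag(2L)
  reflected <- FALSE
  if (det(sv$u %*% t(sv$v)) < 0) {
    if (!allow_reflection) d[2L, 2L] <- -1 else reflected <- TRUE
  }
  rotation <- sv$u %*% d %*% t(sv$v)
  list(rotation = rotation, s = sum(sv$d * diag(d)), reflected = reflected)
}

#' Optimal least-squares superimposition of one shape onto another
#'
#' Centers both configurations, scales both to unit centroid size, and
#' rotates the source to minimize the summed squared distances to the
#' target. By default the fitted transformation is a proper rotation
#' (determinant +1); set `allow_reflection = TRUE` to also allow an
#' improper one (useful before sides have been standardized).
#'
#' @param source,target k x 2 coordinate matrices (equal k).
#' @param allow_reflection permit an improper rotation.
#' @return A list with `aligned` (the transformed source), `rotation`
#'   (2 x 2), `residual` (the minimized sum of squared distances) and
#'   `reflected`.
#' @export
superimpose <- function(source, target, allow_reflection = FALSE) {
  source <- as_shape_matrix(source)
  target <- as_shape_matrix(target)
  if (nrow(source) != nrow(target))
    stop(sprintf("landmark count mismatch: %d vs %d", nrow(source),
                 nrow(target)))
  a <- preshape(source)
  b <- preshape(target)
  fit <- optimal_rotation(a, b, allow_reflection)
  aligned <- a %*% fit$rotation
  # both preshapes have unit norm, so the minimum is 2 - 2 * s
  residual <- max(0, 2 - 2 * fit$s)
  list(aligned = aligned, rotation = fit$rotation, residual = residual,
       reflected = fit$reflected)
}

#' Procrustes distance between two configurations
#'
#' Shape distance after optimal translation, scaling and rotation. The
#' default (`scale = "unit"`, the partial Procrustes distance) fixes both
#' configurations at unit centroid size and minimizes over rotation:
#' `sqrt(2 - 2 * s)` with `s` the sum of (sign-corrected) singular values
#' of the cross-product of the preshapes. `scale = "full"` additionally
#' minimizes over the relative scale (full Procrustes distance,
#' `sqrt(1 - s^2)`); `scale = "none"` superimposes without any rescaling
#' and returns the distance in the original units (used for raw-coordinate
#' digitization-error studies).
#'
#' @param a,b k x 2 coordinate matrices or [landmark_config()] objects.
#' @param scale `"unit"`, `"full"` or `"none"`.
#' @param allow_reflection permit an improper rotation.
#' @return A non-negative number; 0 iff the shapes are identical up to the
#'   similarity transform optimized over.
#' @export
procrustes_distance <- function(a, b, scale = c("unit", "full", "none"),
                                allow_reflection = FALSE) {
  scale <- match.arg(scale)
  if (inherits(a, "landmark_config")) a <- a$landmarks
  if (inherits(b, "landmark_config")) b <- b$landmarks
  a <- as_shape_matrix(a)
  b <- as_shape_matrix(b)
  if (nrow(a) != nrow(b))
    stop(sprintf("landmark count mismatch: %d vs %d", nrow(a), nrow(b)))
  if (scale == "none") {
    ac <- center_shape(a)
    bc <- center_shape(b)
    s <- optimal_rotation(ac, bc, allow_reflection)$s
    return(sqrt(max(0, sum(ac^2) + sum(bc^2) - 2 * s)))
  }
  s <- optimal_rotation(preshape(a), preshape(b), allow_reflection)$s
  s <- min(s, 1)
  if (scale == "unit") sqrt(max(0, 2 - 2 * s)) else sqrt(max(0, 1 - s^2))
}

#' Pairwise Procrustes distance matrix
#'
#' @param shapes a list of k x 2 matrices / [landmark_config()] objects, a
#'   [shape_dataset()], or a fitted [gpa()] object (its original shapes).
#' @inheritParams procrustes_distance
#' @return A symmetric `dist`-like square matrix with zero diagonal, with
#'   specimen ids as dimnames when available.
#' @export
procrustes_dist_matrix <- function(shapes, scale = c("unit", "full", "none"),
                                   allow_reflection = FALSE) {
  scale <- match.arg(scale)
  if (inherits(shapes, "shape_dataset")) shapes <- dataset_shapes(shapes)
  if (inherits(shapes, "gpa")) shapes <- shapes$shapes
  shapes <- lapply(shapes, function(s)
    if (inherits(s, "landmark_config")) s$landmarks else as_shape_matrix(s))
  n <- length(shapes)
  d <- matrix(0, n, n, dimnames = list(names(shapes), names(shapes)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- procrustes_distance(shapes[[i]], shapes[[j]],
                                                scale = scale,
                                                allow_reflection =
                                                  allow_reflection)
  d
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition of a sample of landmark
#' configurations: every configuration is centered and scaled to unit
#' centroid size, aligned to a provisional consensus (initially the first
#' specimen), after which the consensus is recomputed as the mean shape,
#' rescaled to unit centroid size, and the sample re-aligned, until the
#' consensus moves by less than `tol` (root summed squared displacement) or
#' `max_iter` is reached. After convergence the consensus is rotated to its
#' principal axes (with a deterministic sign rule: the landmark farthest
#' from the centroid along the first axis gets positive x), all specimens
#' are rotated with it, and the aligned coordinates are orthogonally
#' projected into the tangent space at the consensus.
#'
#' With `scale_mode = "full"` each specimen is additionally rescaled at
#' every alignment step by its optimal least-squares scale towards the
#' consensus (full Procrustes fit); the default keeps all specimens at unit
#' centroid size (partial Procrustes fit).
#'
#' @param x a [shape_dataset()], a list of k x 2 matrices, or a
#'   k x 2 x n array.
#' @param tol convergence tolerance on consensus displacement.
#' @param max_iter maximum number of update iterations.
#' @param allow_reflection permit improper rotations during alignment
#'   (normally `FALSE`: sides are standardized beforehand).
#' @param scale_mode `"unit"` (partial Procrustes, default) or `"full"`.
#' @return An object of class `"gpa"`: list with
#'   \item{consensus}{k x 2 mean shape, unit centroid size, principal-axis
#'     aligned;}
#'   \item{coords}{k x 2 x n array of aligned (Procrustes) coordinates;}
#'   \item{tangent}{n x 2k matrix of tangent-space deviations from the
#'     consensus (each row orthogonal to the flattened consensus);}
#'   \item{csize}{original centroid sizes;}
#'   \item{ids, info}{specimen metadata when `x` is a dataset;}
#'   \item{iterations, converged, objective}{iteration diagnostics
#'     (`objective` is the summed squared distance to the consensus after
#'     each iteration, a non-increasing sequence).}
#' @export
gpa <- function(x, tol = 1e-8, max_iter = 100L, allow_reflection = FALSE,
                scale_mode = c("unit", "full")) {
  scale_mode <- match.arg(scale_mode)
  info <- NULL
  dataset <- NULL
  if (inherits(x, "shape_dataset")) {
    dataset <- x
    info <- x$info
    shapes <- dataset_shapes(x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    shapes <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    names(shapes) <- dimnames(x)[[3]]
  } else {
    shapes <- lapply(x, function(s)
      if (inherits(s, "landmark_config")) s$landmarks else as_shape_matrix(s))
  }
  n <- length(shapes)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  k <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, integer(1)) == k))
    stop("all configurations must have the same landmark count")
  ids <- names(shapes) %||% sprintf("spec_%d", seq_len(n))
  csize <- vapply(shapes, centroid_size, numeric(1))
  aligned <- lapply(shapes, preshape)

  align_all <- function(aligned, consensus) {
    lapply(aligned, function(a) {
      fit <- optimal_rotation(a, consensus, allow_reflection)
      out <- a %*% fit$rotation
      if (scale_mode == "full") {
        beta <- sum(out * consensus) / sum(out^2)
        out <- out * beta
      }
      out
    })
  }
  consensus <- aligned[[1L]]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aligned <- align_all(aligned, consensus)
    new_consensus <- Reduce(`+`, aligned) / n
    new_consensus <- preshape(new_consensus)
    objective <- c(objective,
                   sum(vapply(aligned, function(a) sum((a - new_consensus)^2),
                              numeric(1))))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations", max_iter),
            call. = FALSE)
  # final alignment to the converged consensus
  aligned <- align_all(aligned, consensus)

  # principal-axis orientation of the consensus, applied to all specimens
  ev <- eigen(stats::cov(consensus), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 2L] <- -ev[, 2L]
  consensus_rot <- consensus %*% ev
  far <- which.max(abs(consensus_rot[, 1L]))
  if (consensus_rot[far, 1L] < 0) ev <- -ev      # rotate by pi, det stays +1
  consensus <- consensus %*% ev
  aligned <- lapply(aligned, function(a) a %*% ev)

  coords <- array(unlist(aligned), dim = c(k, 2L, n),
                  dimnames = list(NULL, c("x", "y"), ids))
  out <- structure(
    list(consensus = consensus, coords = coords, tangent = NULL,
         csize = stats::setNames(csize, ids), ids = ids, info = info,
         dataset = dataset, shapes = shapes, iterations = iter,
         converged = converged, objective = objective,
         scale_mode = scale_mode, k = k),
    class = "gpa"
  )
  tangent_project(out)
}

#' Project aligned coordinates into the tangent space at the consensus
#'
#' Each specimen's flattened aligned coordinates are orthogonally projected
#' onto the hyperplane through the consensus and orthogonal to it; the
#' stored tangent coordinates are the projected deviations from the
#' consensus, so every row has (numerically) zero inner product with the
#' flattened consensus. [gpa()] calls this automatically.
#'
#' @param object a fitted [gpa()] object.
#' @return The object with its `tangent` matrix (re)computed.
#' @export
tangent_project <- function(object) {
  stopifnot(inherits(object, "gpa"))
  cvec <- flatten_shape(object$consensus)       # unit norm by construction
  cvec <- cvec / sqrt(sum(cvec^2))
  n <- dim(object$coords)[3]
  tang <- t(vapply(seq_len(n), function(i) {
    xv <- flatten_shape(object$coords[, , i])
    xv - sum(xv * cvec) * cvec
  }, numeric(2L * object$k)))
  rownames(tang) <- object$ids
  colnames(tang) <- paste0(rep(c("x", "y"), object$k),
                           rep(seq_len(object$k), each = 2L))
  object$tangent <- tang
  object
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes analysis: %d configurations, %d landmarks\n",
              length(x$ids), x$k))
  cat(sprintf("  %s Procrustes fit, %d iterations (%s)\n",
              if (x$scale_mode == "unit") "partial" else "full",
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  total shape variation (sum of squares to consensus): %.6g\n",
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  d <- vapply(seq_along(object$ids), function(i)
    sqrt(sum((object$coords[, , i] - object$consensus)^2)), numeric(1))
  out <- list(n = length(object$ids), k = object$k,
              iterations = object$iterations, converged = object$converged,
              csize = summary(object$csize),
              dist_to_consensus = summary(d))
  class(out) <- "summary.gpa"
  out
}

#' @export
print.summary.gpa <- function(x, ...) {
  cat(sprintf("GPA of %d configurations, %d landmarks (%d iterations, %s)\n",
              x$n, x$k, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("Centroid sizes:\n"); print(x$csize)
  cat("Distances to consensus:\n"); print(x$dist_to_consensus)
  invisible(x)
}

#' Plot aligned shapes and consensus
#'
#' Scatter of all aligned landmark positions with the consensus overlaid.
#'
#' @param x a fitted [gpa()] object.
#' @param links optional two-column matrix of landmark indices to join
#'   (e.g. the crown outline).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gpa <- function(x, links = NULL, ...) {
  all_pts <- matrix(aperm(x$coords, c(1, 3, 2)), ncol = 2L)
  graphics::plot(all_pts, pch = 16, cex = 0.3,
                 col = grDevices::grey(0.6, 0.5), asp = 1,
                 xlab = "x", ylab = "y", ...)
  if (!is.null(links))
    graphics::segments(x$consensus[links[, 1], 1], x$consensus[links[, 1], 2],
                       x$consensus[links[, 2], 1], x$consensus[links[, 2], 2],
                       col = "grey40")
  graphics::points(x$consensus, pch = 21, bg = "firebrick", cex = 1.1)
  graphics::text(x$consensus, labels = seq_len(x$k), pos = 3, cex = 0.7)
  invisible(x)
}
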