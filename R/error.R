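#' Bundle repeated digitizations into a repetition study
#'
#' Container for an intra-observer digitization-error study: the same
#' specimens digitized several times, possibly across sessions (days).
#'
#' @param configs list of [landmark_config()] objects (one per
#'   digitization).
#' @param specimen character/factor: which specimen each configuration
#'   belongs to.
#' @param rep integer replicate index within specimen.
#' @param day optional session label per configuration.
#' @return An object of class `"repetition_study"`.
#' @export
repetition_study <- function(configs, specimen, rep, day = NULL) {
  stopifnot(length(configs) == length(specimen),
            length(configs) == length(rep))
  specimen <- as.character(specimen)
  rep <- as.integer(rep)
  counts <- table(specimen)
  if (any(counts < 2L))
    stop("every specimen needs at least 2 repetitions; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  if (length(unique(counts)) != 1L)
    stop("all specimens must have the same repetition count")
  structure(
    list(configs = configs,
         info = data.frame(specimen = specimen, rep = rep,
                           day = day %||% rep(NA, length(rep)),
                           stringsAsFactors = FALSE)),
    class = "repetition_study"
  )
}

#' @export
print.repetition_study <- function(x, ...) {
  cat(sprintf("Repetition study: %d specimens x %d digitizations\n",
              length(unique(x$info$specimen)), max(x$info$rep)))
  invisible(x)
}

#' Paired Procrustes distances between repeated digitizations
#'
#' For every specimen, the Procrustes distance between each unordered pair
#' of its repeated digitizations; the mean and standard deviation are
#' pooled across specimens. The default uses unit-centroid-size shapes
#' (the partial Procrustes distance); `scale = "none"` superimposes without
#' rescaling and reports distances in raw coordinate units.
#'
#' @param study a [repetition_study()].
#' @param scale passed to [procrustes_distance()].
#' @return A list with `mean`, `sd`, and `distances` (data frame with
#'   `specimen`, `rep_i`, `rep_j`, `distance`).
#' @export
repetition_distances <- function(study, scale = c("unit", "full", "none")) {
  stopifnot(inherits(study, "repetition_study"))
  scale <- match.arg(scale)
  out <- list()
  for (sp in unique(study$info$specimen)) {
    idx <- which(study$info$specimen == sp)
    if (length(idx) < 2L) stop("specimen ", sp, " has fewer than 2 repetitions")
    pairs <- utils::combn(idx, 2L)
    d <- apply(pairs, 2L, function(ij)
      procrustes_distance(study$configs[[ij[1]]]$landmarks,
                          study$configs[[ij[2]]]$landmarks, scale = scale))
    out[[sp]] <- data.frame(specimen = sp,
                            rep_i = study$info$rep[pairs[1, ]],
                            rep_j = study$info$rep[pairs[2, ]],
                            distance = d, stringsAsFactors = FALSE)
  }
  distances <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  list(mean = mean(distances$distance), sd = stats::sd(distances$distance),
       distances = distances)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' distance matrices over the same objects, with significance from joint
#' row/column permutations of the second matrix. The p-value uses the
#' `(b + 1) / (m + 1)` convention, counting the observed statistic among
#' the permutations.
#'
#' @param d1,d2 symmetric zero-diagonal matrices with matching dimnames
#'   (or both unnamed and equal-sized).
#' @param n_perm number of permutations.
#' @param seed optional integer; when given, permutations are drawn from a
#'   local RNG stream and the caller's RNG state is untouched.
#' @return A list with `r` (the Mantel correlation) and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices have mismatched ids")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt])
  with_seed(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      r_perm <- stats::cor(d1[lt], d2[pp, pp][lt])
      if (r_perm >= r_obs) ge <- ge + 1L
    }
    list(r = r_obs, p = (ge + 1L) / (n_perm + 1L))
  })
}

#' Average Mantel correlation across repeated digitizations
#'
#' Builds, for each repetition, the matrix of Procrustes distances among
#' the study's specimens, and returns the mean Mantel correlation over all
#' unordered pairs of repetition-specific distance matrices — a
#' repeatability summary: correlations near 1 mean the relative
#' arrangement of specimens in shape space is stable across digitizations.
#'
#' @param study a [repetition_study()].
#' @param scale passed to [procrustes_distance()].
#' @return A list with `mean_r`, `r` (per repetition pair), and
#'   `matrices` (the per-repetition distance matrices).
#' @export
repeatability_mantel <- function(study, scale = c("unit", "full", "none")) {
  stopifnot(inherits(study, "repetition_study"))
  scale <- match.arg(scale)
  reps <- sort(unique(study$info$rep))
  specs <- unique(study$info$specimen)
  mats <- lapply(reps, function(r) {
    idx <- vapply(specs, function(sp)
      which(study$info$specimen == sp & study$info$rep == r)[1], integer(1))
    m <- procrustes_dist_matrix(lapply(study$configs[idx], `[[`,
                                       "landmarks"), scale = scale)
    dimnames(m) <- list(specs, specs)
    m
  })
  pairs <- utils::combn(length(reps), 2L)
  lt <- lower.tri(mats[[1]])
  r <- apply(pairs, 2L, function(ij)
    stats::cor(mats[[ij[1]]][lt], mats[[ij[2]]][lt]))
  list(mean_r = mean(r), r = r, matrices = mats)
}

#' Permutational (distance-based) MANOVA
#'
#' Pseudo-F test of group differences computed from the pairwise Euclidean
#' distance matrix of multivariate observations:
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`, where
#' `SS_within` is the sum over groups of within-group squared distances
#' divided by group size and `SS_between = SS_total - SS_within`. With
#' Euclidean distances this pseudo-F equals the classical one-way F built
#' from per-coordinate sums of squares summed over coordinates. The
#' p-value is the proportion of label permutations (observed included,
#' `(b + 1) / (m + 1)`) with a pseudo-F at least as large.
#'
#' @param x numeric matrix of observations (rows) — e.g. tangent shape
#'   coordinates — or a precomputed distance matrix / `dist` object.
#' @param grouping factor of group labels.
#' @param n_perm number of permutations.
#' @param seed optional integer for a local RNG stream.
#' @return A list with `F`, `p`, `ss_between`, `ss_within`, `ss_total`,
#'   `df` (c(between, within)).
#' @export
perm_manova <- function(x, grouping, n_perm = 999L, seed = NULL) {
  grouping <- droplevels(factor(grouping))
  a <- nlevels(grouping)
  if (a < 2L) stop("need at least 2 groups")
  if (any(table(grouping) < 2L))
    stop("every group needs at least 2 observations")
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2
        else if (is.matrix(x) && isSymmetric(unname(x)) &&
                 all(abs(diag(x)) < 1e-12) && nrow(x) == length(grouping) &&
                 ncol(x) == length(grouping)) x^2
        else as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  if (n != length(grouping)) stop("grouping length does not match data")
  ss_total <- sum(d2[lower.tri(d2)]) / n
  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_within <- ss_within +
        sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- pseudo_f(grouping)
  with_seed(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      if (pseudo_f(grouping[sample.int(n)]) >= f_obs) ge <- ge + 1L
    }
    ss_within_obs <- ss_total * (1 / (1 + f_obs * (a - 1) / (n - a)))
    list(F = f_obs, p = (ge + 1L) / (n_perm + 1L),
         ss_between = ss_total - ss_within_obs,
         ss_within = ss_within_obs, ss_total = ss_total,
         df = c(between = a - 1L, within = n - a))
  })
}

#' Intra-observer digitization-error study
#'
#' Runs the full measurement-error assessment on a repetition study:
#' (1) mean and SD of paired Procrustes distances between repeated
#' digitizations of each specimen; (2) the average Mantel correlation
#' between repetition-specific specimen distance matrices
#' ([repeatability_mantel()]); (3) a permutational MANOVA of the tangent
#' shape coordinates (all digitizations superimposed jointly) against the
#' repetition (or day) factor — a non-significant pseudo-F means the
#' digitization replicates are statistically indistinguishable.
#'
#' @param study a [repetition_study()].
#' @param group_by `"repetition"` or `"day"`: the MANOVA grouping factor.
#' @param scale distance mode for (1) and (2); see
#'   [procrustes_distance()].
#' @param n_perm permutations for the MANOVA.
#' @param seed optional integer seed for the permutations.
#' @return An object of class `"error_study"`: list with
#'   `mean_pairwise`, `sd_pairwise`, `mantel_r_mean`, `manova_F`,
#'   `manova_p`, and the underlying component results.
#' @export
error_study <- function(study, group_by = c("repetition", "day"),
                        scale = c("unit", "full", "none"), n_perm = 999L,
                        seed = NULL) {
  stopifnot(inherits(study, "repetition_study"))
  group_by <- match.arg(group_by)
  scale <- match.arg(scale)
  paired <- repetition_distances(study, scale = scale)
  mant <- repeatability_mantel(study, scale = scale)
  g <- gpa(lapply(study$configs, `[[`, "landmarks"))
  labels <- if (group_by == "repetition") study$info$rep else study$info$day
  mnv <- perm_manova(g$tangent, labels, n_perm = n_perm, seed = seed)
  structure(
    list(mean_pairwise = paired$mean, sd_pairwise = paired$sd,
         mantel_r_mean = mant$mean_r,
         manova_F = mnv$F, manova_p = mnv$p,
         paired = paired, mantel = mant, manova = mnv,
         group_by = group_by, scale = scale),
    class = "error_study"
  )
}

#' @export
print.error_study <- function(x, ...) {
  cat("Intra-observer digitization-error study\n")
  cat(sprintf("  mean paired Procrustes distance: %.5f (sd %.5f, %s scaling)\n",
              x$mean_pairwise, x$sd_pairwise, x$scale))
  cat(sprintf("  mean Mantel r between repetition distance matrices: %.4f\n",
              x$mantel_r_mean))
  cat(sprintf("  permutational MANOVA (%s factor): F = %.5f, p = %.4f\n",
              x$group_by, x$manova_F, x$manova_p))
  invisible(x)
}
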