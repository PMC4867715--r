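# Core linear-discriminant computations shared by shape_lda() and the
# leave-one-out loop. Lenient about group sizes (folds may reduce a group
# to a single member); user-facing validation lives in shape_lda().
lda_core <- function(x, grouping, prior_mode = "equal") {
  grouping <- factor(grouping)
  grouping <- droplevels(grouping)
  lev <- levels(grouping)
  g <- length(lev)
  n <- nrow(x)
  p <- ncol(x)
  ng <- as.vector(table(grouping))
  means <- rowsum(x, grouping) / ng
  centered <- x - means[as.integer(grouping), , drop = FALSE]
  pooled <- crossprod(centered) / (n - g)
  ch <- tryCatch(chol(pooled), error = function(e)
    stop("singular pooled within-group covariance; retain fewer PCs",
         call. = FALSE))
  prior <- if (prior_mode == "equal") rep(1 / g, g) else ng / n
  list(levels = lev, ng = ng, means = means, pooled = pooled, chol = ch,
       prior = prior, n = n, p = p, grouping = grouping)
}

# Squared Mahalanobis distances of rows of x to every group mean under the
# pooled covariance (n x g matrix).
lda_mahalanobis <- function(core, x) {
  z <- x %*% chol2inv(core$chol)          # x Sigma^-1
  cross <- z %*% t(core$means)
  mh <- outer(rowSums(z * x), rep(1, nrow(core$means))) -
    2 * cross +
    outer(rep(1, nrow(x)), rowSums((core$means %*% chol2inv(core$chol)) *
                                     core$means))
  mh[mh < 0] <- 0
  colnames(mh) <- core$levels
  mh
}

# Posterior probabilities and predicted labels from Mahalanobis distances.
lda_classify <- function(core, x, warn_ties = TRUE) {
  mh <- lda_mahalanobis(core, x)
  lp <- sweep(-mh / 2, 2L, log(core$prior), `+`)
  lp <- lp - apply(lp, 1L, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  pred <- character(nrow(post))
  for (i in seq_len(nrow(post))) {
    top <- which(post[i, ] == max(post[i, ]))
    if (length(top) > 1L && warn_ties)
      warning("posterior tie broken lexicographically for case ",
              rownames(x)[i] %||% i, call. = FALSE)
    pred[i] <- core$levels[min(top)]
  }
  list(posterior = post, class = factor(pred, levels = core$levels),
       mahalanobis = mh)
}

#' Linear discriminant analysis of shape PC scores
#'
#' Fits a canonical discriminant analysis of the retained principal
#' component scores against a taxonomic grouping factor: the generalized
#' eigenproblem of the between-group covariance against the pooled
#' within-group covariance. Training specimens are classified by smallest
#' Mahalanobis distance to the group centroids under the pooled covariance;
#' posterior probabilities are proportional to
#' `prior * exp(-d^2 / 2)` (linear boundaries, as in classical LDA).
#'
#' The number of PCs retained defaults to all supplied columns, reduced
#' from the right until the pooled within-group covariance is
#' well-conditioned (condition number below `cond_max`) and has positive
#' degrees of freedom; the retained count is recorded in the fit.
#'
#' @param x numeric matrix of PC scores (rows = specimens, columns ordered
#'   by decreasing eigenvalue), or a [shape_pca()] fit (its scores).
#' @param grouping factor of group labels, one per row of `x`.
#' @param prior `"equal"` (default) or `"proportional"` to group size.
#' @param n_pcs number of leading score columns to retain; `NULL` for the
#'   automatic rule.
#' @param cond_max largest acceptable condition number of the pooled
#'   within-group covariance.
#' @return An object of class `"shape_lda"`: list with
#'   `eigenvalues` and `df_percent` (discriminant-function variance
#'   shares), `scaling` (retained-PC x function discriminant vectors,
#'   normalized to unit pooled within-group variance), `means` (group
#'   centroids in retained-PC space), `centroids_df` (in discriminant
#'   space), `confusion`, `pcc_original`, `prior`, `n_pcs`, plus the
#'   training data needed for cross-validation.
#' @export
shape_lda <- function(x, grouping, prior = c("equal", "proportional"),
                      n_pcs = NULL, cond_max = 1e8) {
  prior <- match.arg(prior)
  if (inherits(x, "shape_pca")) x <- x$scores
  x <- as.matrix(x)
  grouping <- droplevels(factor(grouping))
  if (nrow(x) != length(grouping))
    stop("'grouping' must have one label per row of 'x'")
  if (anyNA(grouping)) stop("missing group labels")
  tab <- table(grouping)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("every group needs at least 2 specimens; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  g <- length(tab)
  n <- nrow(x)
  p_max <- if (is.null(n_pcs)) ncol(x) else min(n_pcs, ncol(x))
  # keep a spare within-group degree of freedom so that leave-one-out
  # refits of the same retained PCs stay nonsingular
  p <- max(1L, min(p_max, n - g - 1L))
  repeat {
    xr <- x[, seq_len(p), drop = FALSE]
    core <- tryCatch(lda_core(xr, grouping, prior), error = function(e) NULL)
    if (!is.null(core)) {
      ev <- eigen(core$pooled, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0 && max(ev) / min(ev) < cond_max) break
    }
    if (p == 1L)
      stop("pooled within-group covariance singular even with 1 PC; ",
           "retain fewer PCs or check for constant coordinates")
    p <- p - 1L
  }
  # between-group covariance and the generalized eigenproblem
  grand <- colMeans(xr)
  dm <- sweep(core$means, 2L, grand)
  B <- crossprod(dm * sqrt(core$ng)) / (g - 1)
  Ci <- solve(core$chol)                  # pooled = t(chol) %*% chol
  sym <- t(Ci) %*% B %*% Ci
  ed <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  m <- min(g - 1L, p)
  eigvals <- pmax(ed$values[seq_len(m)], 0)
  scaling <- Ci %*% ed$vectors[, seq_len(m), drop = FALSE]
  colnames(scaling) <- paste0("DF", seq_len(m))
  rownames(scaling) <- colnames(xr)
  cls <- lda_classify(core, xr, warn_ties = FALSE)
  confusion <- table(truth = grouping, predicted = cls$class)
  pcc <- 100 * sum(diag(confusion)) / n
  structure(
    list(eigenvalues = eigvals,
         df_percent = 100 * eigvals / sum(eigvals),
         scaling = scaling,
         means = core$means,
         centroids_df = core$means %*% scaling,
         pooled = core$pooled,
         prior = stats::setNames(core$prior, core$levels),
         prior_mode = prior,
         levels = core$levels,
         confusion = confusion,
         pcc_original = pcc,
         n_pcs = p, n = n,
         x = xr, grouping = grouping,
         cond_max = cond_max),
    class = "shape_lda"
  )
}

#' @export
print.shape_lda <- function(x, ...) {
  cat(sprintf("Shape LDA: %d groups, %d specimens, %d PCs retained (%s priors)\n",
              length(x$levels), x$n, x$n_pcs, x$prior_mode))
  m <- min(length(x$df_percent), 2L)
  cat(sprintf("  DF%d: %5.1f%% of discriminant variance\n",
              seq_len(m), x$df_percent[seq_len(m)]), sep = "")
  cat(sprintf("  original correct classification: %.1f%%\n", x$pcc_original))
  invisible(x)
}

#' @export
summary.shape_lda <- function(object, ...) {
  cv <- loocv_pcc(object)
  out <- list(fit = object, pcc_crossval = cv$pcc,
              confusion_crossval = cv$confusion)
  class(out) <- "summary.shape_lda"
  out
}

#' @export
print.summary.shape_lda <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  cross-validated (LOO) correct classification: %.1f%%\n",
              x$pcc_crossval))
  cat("Cross-validated confusion matrix:\n")
  print(x$confusion_crossval)
  invisible(x)
}

#' Leave-one-out cross-validated correct classification
#'
#' For each specimen the discriminant model is refitted from scratch on the
#' remaining `n - 1` specimens (same retained PCs and prior mode as the
#' original fit) and the held-out specimen is classified; `pcc` is the
#' percentage classified into their true group. No fast update shortcut is
#' used: every fold is a full refit.
#'
#' @param x a [shape_lda()] fit, or a score matrix.
#' @param grouping group labels (only when `x` is a matrix).
#' @param prior,n_pcs,cond_max as in [shape_lda()] (only when `x` is a
#'   matrix).
#' @return A list with `pcc` (percent), `confusion` (truth x predicted
#'   table), and `predicted`.
#' @export
loocv_pcc <- function(x, grouping = NULL, prior = c("equal", "proportional"),
                      n_pcs = NULL, cond_max = 1e8) {
  if (inherits(x, "shape_lda")) {
    fit <- x
  } else {
    prior <- match.arg(prior)
    fit <- shape_lda(x, grouping, prior = prior, n_pcs = n_pcs,
                     cond_max = cond_max)
  }
  xr <- fit$x
  grouping <- fit$grouping
  n <- nrow(xr)
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(grouping[-i])
    if (nlevels(gi) < nlevels(droplevels(grouping)))
      warning("leaving out specimen ", i,
              " empties its group; classifying against remaining groups",
              call. = FALSE)
    core <- lda_core(xr[-i, , drop = FALSE], gi, fit$prior_mode)
    pred[i] <- as.character(lda_classify(core, xr[i, , drop = FALSE],
                                         warn_ties = FALSE)$class)
  }
  pred <- factor(pred, levels = fit$levels)
  confusion <- table(truth = grouping, predicted = pred)
  list(pcc = 100 * mean(pred == grouping), confusion = confusion,
       predicted = pred)
}

#' Classify unknown specimens against a fitted discriminant model
#'
#' Computes, for each unknown (e.g. fossil) specimen, the posterior
#' probability of membership in every training group,
#' `posterior_g = prior_g * exp(-d_g^2 / 2)` normalized over groups, with
#' `d_g` the Mahalanobis distance to the group centroid under the pooled
#' within-group covariance. Ties in the arg-max are broken towards the
#' first group in sorted label order, with a warning.
#'
#' @param object a [shape_lda()] fit.
#' @param newdata numeric vector or matrix of PC scores in the same space
#'   as the training scores (extra trailing columns beyond the retained
#'   PCs are dropped).
#' @param ... unused.
#' @return A list with `class` (predicted labels), `posterior`
#'   (rows summing to 1), `mahalanobis` (squared distances) and
#'   `df_scores` (discriminant-space coordinates).
#' @export
predict.shape_lda <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) < object$n_pcs)
    stop(sprintf("newdata has %d columns; fit retains %d PCs",
                 ncol(newdata), object$n_pcs))
  newdata <- newdata[, seq_len(object$n_pcs), drop = FALSE]
  core <- list(levels = object$levels, means = object$means,
               chol = chol(object$pooled), prior = object$prior)
  cls <- lda_classify(core, newdata)
  cls$df_scores <- newdata %*% object$scaling
  cls
}

#' Run the full four-factor discriminant analysis
#'
#' End-to-end classification study for one or both teeth: superimposition
#' ([gpa()]), shape PCA, then one discriminant analysis per taxonomic
#' grouping factor (family, the eight-subfamily scheme `subfamily_G`, the
#' five-subfamily scheme `subfamily_R`, and genus), each with original and
#' leave-one-out cross-validated correct classification, and posterior
#' classification of every fossil specimen present for that tooth.
#'
#' @param datasets a named list of [shape_dataset()] objects (e.g.
#'   `list(M1 = ..., M2 = ...)`), or a single dataset.
#' @param factors character vector of grouping factors to use (columns of
#'   the dataset taxonomy).
#' @param pca_scope passed to [shape_pca()]; `"all"` (default) fits the
#'   shape axes on extant and fossil specimens jointly, `"extant"` fits on
#'   extant specimens and projects fossils.
#' @param prior,n_pcs,cond_max passed to [shape_lda()].
#' @return An object of class `"lda_table"`: list with `table` (one row per
#'   tooth x factor: DF1/DF2 variance shares, original and cross-validated
#'   pcc, retained PCs, group count), `posteriors` (per tooth x factor, a
#'   fossil x group posterior matrix), `fits`, `pca`, `gpa`, and `config`.
#' @export
run_all_ldas <- function(datasets,
                         factors = c("family", "subfamily_G", "subfamily_R",
                                     "genus"),
                         pca_scope = c("all", "extant"),
                         prior = c("equal", "proportional"),
                         n_pcs = NULL, cond_max = 1e8) {
  pca_scope <- match.arg(pca_scope)
  prior <- match.arg(prior)
  if (inherits(datasets, "shape_dataset")) {
    datasets <- stats::setNames(list(datasets), datasets$tooth)
  }
  rows <- list()
  posteriors <- list()
  fits <- list()
  pcas <- list()
  gpas <- list()
  for (tooth in names(datasets)) {
    ds <- datasets[[tooth]]
    g <- gpa(ds)
    p <- shape_pca(g, scope = pca_scope)
    extant <- !g$info$fossil
    scores_extant <- if (p$scope == "all") p$scores[extant, , drop = FALSE]
                     else p$scores
    fossil_ids <- g$info$specimen_id[g$info$fossil]
    fossil_scores <- if (length(fossil_ids)) {
      if (p$scope == "all") p$scores[fossil_ids, , drop = FALSE]
      else predict(p, g$tangent[fossil_ids, , drop = FALSE])
    }
    if (!length(fossil_ids))
      message("note: no fossil specimens present for ", tooth)
    for (fac in factors) {
      labels <- g$info[[fac]][extant]
      fit <- shape_lda(scores_extant, labels, prior = prior, n_pcs = n_pcs,
                       cond_max = cond_max)
      cv <- loocv_pcc(fit)
      key <- paste(tooth, fac, sep = ".")
      fits[[key]] <- fit
      rows[[key]] <- data.frame(
        tooth = tooth, factor = fac,
        n_groups = length(fit$levels), n_pcs = fit$n_pcs,
        df1_percent = fit$df_percent[1],
        df2_percent = if (length(fit$df_percent) >= 2L)
          fit$df_percent[2] else NA_real_,
        pcc_original = fit$pcc_original,
        pcc_crossval = cv$pcc,
        stringsAsFactors = FALSE
      )
      if (length(fossil_ids)) {
        pr <- predict(fit, fossil_scores)
        post <- pr$posterior
        rownames(post) <- fossil_ids
        posteriors[[key]] <- post
      }
    }
    pcas[[tooth]] <- p
    gpas[[tooth]] <- g
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         posteriors = posteriors, fits = fits, pca = pcas, gpa = gpas,
         config = list(factors = factors, pca_scope = pca_scope,
                       prior = prior, n_pcs = n_pcs, cond_max = cond_max)),
    class = "lda_table"
  )
}

#' @export
print.lda_table <- function(x, digits = 1, ...) {
  cat("Discriminant classification summary\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$posteriors)) {
    cat(sprintf("\nFossil posteriors available for: %s\n",
                paste(names(x$posteriors), collapse = ", ")))
  }
  invisible(x)
}
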