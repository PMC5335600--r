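## SVM classifier-building pipeline: descriptor filtering, class
## balancing by Ward clustering, normalization, RBF grid search with
## stratified 10-fold cross-validation, and external evaluation.
## The SVM engine is libSVM (through e1071); filtering, balancing,
## normalization, fold assignment and all statistics are package code.

#' Class-separation F-score of each feature
#'
#' The standard feature-selection F-score for binary labels:
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'   {s^2_+ + s^2_-}}
#' where the denominators are the within-class sample variances.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @return Numeric vector of F-scores (Inf when both classes are
#'   constant but differ; NaN when identical constants).
#' @export
f_score <- function(x, y) {
  x <- as.matrix(x)
  pos <- x[y == 1L, , drop = FALSE]
  neg <- x[y == 0L, , drop = FALSE]
  mu <- colMeans(x)
  mup <- colMeans(pos)
  mun <- colMeans(neg)
  vp <- apply(pos, 2, stats::var)
  vn <- apply(neg, 2, stats::var)
  num <- (mup - mu)^2 + (mun - mu)^2
  num / (vp + vn)
}

#' Filter descriptors
#'
#' Rejects descriptors whose non-zero fraction is below
#' \code{min_nonzero}, whose coefficient of variation (sample SD over
#' |mean|) is below \code{min_cv}, and resolves pairwise correlations
#' above \code{max_cor} by keeping, from each offending pair, the
#' descriptor with the higher class-separation F-score.  Columns with
#' zero mean but positive SD are kept (their CV is taken as infinite).
#'
#' @param x Feature matrix (rows = molecules).
#' @param y 0/1 labels (used for the F-score tie-break).
#' @param min_nonzero Minimum non-zero fraction (default 0.20).
#' @param min_cv Minimum coefficient of variation (default 0.03).
#' @param max_cor Maximum absolute pairwise correlation (default 0.9).
#' @return Integer vector of surviving column indices (increasing).
#' @export
filter_descriptors <- function(x, y, min_nonzero = 0.20, min_cv = 0.03,
                               max_cor = 0.9) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 1L, length(y) == nrow(x))
  nonzero <- colMeans(x != 0)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  cv <- ifelse(mu == 0, ifelse(sdv > 0, Inf, 0), sdv / abs(mu))
  keep <- which(nonzero >= min_nonzero & cv >= min_cv)
  if (length(keep) == 0L) {
    adm_error("adm_all_rejected", "all descriptors rejected")
  }
  if (length(keep) >= 2L) {
    fs <- f_score(x[, keep, drop = FALSE], y)
    cm <- suppressWarnings(stats::cor(x[, keep, drop = FALSE]))
    cm[is.na(cm)] <- 0
    ## drop iteratively: for each violating pair keep the higher F-score
    alive <- rep(TRUE, length(keep))
    ord <- order(fs)   # consider weakest first for removal
    for (k in ord) {
      if (!alive[k]) next
      partners <- which(alive & abs(cm[k, ]) > max_cor)
      partners <- partners[partners != k]
      if (any(fs[partners] >= fs[k])) alive[k] <- FALSE
    }
    keep <- keep[alive]
  }
  sort(unname(keep))
}

#' Balance a dataset by Ward clustering
#'
#' Reduces the larger class to \code{target_size} members: the class is
#' clustered (Ward linkage on a dissimilarity matrix, by default
#' 1 - Tanimoto over fingerprints) into \code{target_size} clusters and
#' only each cluster's centre — the member with the smallest sum of
#' dissimilarities to the other members, ties broken by lowest input
#' index — is retained.  The smaller class is untouched.
#'
#' @param dataset \code{adm_dataset} (needs \code{fingerprints} unless
#'   \code{dissimilarity} is supplied).
#' @param target_size Desired size of the larger class.
#' @param dissimilarity Optional precomputed dissimilarity matrix for
#'   the whole dataset (rows/cols in dataset order).
#' @return A reduced \code{adm_dataset} (row order: retained rows in
#'   original order).
#' @export
cluster_balance <- function(dataset, target_size, dissimilarity = NULL) {
  stopifnot(inherits(dataset, "adm_dataset"), is_count(target_size))
  y <- dataset$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  large <- if (n1 >= n0) 1L else 0L
  idx_large <- which(y == large)
  if (target_size > length(idx_large)) {
    adm_error("adm_target_too_large",
              sprintf("target size %d exceeds larger class size %d",
                      target_size, length(idx_large)))
  }
  if (target_size == length(idx_large)) return(dataset)
  if (is.null(dissimilarity)) {
    fp <- dataset$fingerprints
    if (is.null(fp)) {
      adm_error("adm_missing_table",
                "no fingerprints and no dissimilarity matrix supplied")
    }
    dmat <- fingerprint_dissimilarity(fp[idx_large, , drop = FALSE])
  } else {
    dmat <- dissimilarity[idx_large, idx_large, drop = FALSE]
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "ward.D2")
  cl <- stats::cutree(hc, k = target_size)
  centres <- integer(target_size)
  for (k in seq_len(target_size)) {
    members <- which(cl == k)
    if (length(members) == 1L) {
      centres[k] <- members
    } else {
      sums <- rowSums(dmat[members, members, drop = FALSE])
      centres[k] <- members[which.min(sums)]   # which.min: lowest index tie-break
    }
  }
  keep <- sort(c(which(y != large), idx_large[centres]))
  out <- dataset
  out$x <- dataset$x[keep, , drop = FALSE]
  out$y <- dataset$y[keep]
  if (!is.null(dataset$fingerprints)) {
    out$fingerprints <- dataset$fingerprints[keep, , drop = FALSE]
  }
  out
}

#' Pairwise Tanimoto dissimilarity matrix
#' @param fp Logical fingerprint matrix (rows = molecules).
#' @return Symmetric dissimilarity matrix.
#' @export
fingerprint_dissimilarity <- function(fp) {
  fp <- as.matrix(fp) * 1
  common <- fp %*% t(fp)
  ones <- rowSums(fp)
  un <- outer(ones, ones, "+") - common
  d <- 1 - ifelse(un > 0, common / un, 1)
  diag(d) <- 0
  d
}

## ---------------------------------------------------------------------
## statistics
## ---------------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of decision scores against 0/1 labels;
#' ties contribute 1/2.
#' @param scores Numeric decision values (larger = more positive).
#' @param y 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    adm_error("adm_degenerate_labels", "need both classes for AUC")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

classification_stats <- function(pred, scores, y) {
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  list(
    ACC = (tp + tn) / length(y),
    AUC = auc_score(scores, y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

## stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

## ---------------------------------------------------------------------
## model fitting
## ---------------------------------------------------------------------

#' Default hyper-parameter grid
#'
#' Coarse log2-spaced grid for the soft-margin cost C and the RBF width
#' gamma, refined around the coarse winner in a second pass.
#' @return List with \code{log2C}, \code{log2gamma}, \code{refine_step}.
#' @export
svm_grid <- function() {
  list(log2C = seq(-5, 15, by = 4),
       log2gamma = seq(-15, 3, by = 4),
       refine_step = 4 / 3)
}

#' Fit an RBF-SVM classifier with grid search
#'
#' The full pipeline step: descriptors are filtered
#' (\code{\link{filter_descriptors}}), features are normalized to zero
#' mean / unit variance (training parameters stored for later use),
#' (C, gamma) are optimized by maximizing stratified 10-fold
#' cross-validated accuracy over a coarse-then-refined log2 grid (ties
#' broken by smaller C, then smaller gamma), the final model is
#' retrained on the whole training set, and cross-validated accuracy and
#' AUC at the winning parameters are recorded.
#'
#' @param dataset \code{adm_dataset} (training role).
#' @param grid Grid specification (see \code{\link{svm_grid}}).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param filter Apply descriptor filtering (default TRUE).
#' @return Object of class \code{adme_svm}: selected feature indices,
#'   normalization parameters, hyper-parameters, the fitted libSVM
#'   model, and \code{stats} with \code{ACC_CV} and \code{AUC_CV}.
#' @export
adme_svm_fit <- function(dataset, grid = svm_grid(), folds = 10L,
                         seed = 1L, filter = TRUE) {
  stopifnot(inherits(dataset, "adm_dataset"))
  x <- as.matrix(dataset$x)
  y <- dataset$y
  if (length(unique(y)) < 2L) {
    adm_error("adm_degenerate_labels", "training labels have a single class")
  }
  sel <- if (filter) filter_descriptors(x, y) else seq_len(ncol(x))
  xs <- x[, sel, drop = FALSE]
  centre <- colMeans(xs)
  scale_ <- apply(xs, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xn <- sweep(sweep(xs, 2, centre), 2, scale_, "/")

  fold_id <- stratified_folds(y, folds, seed)
  cv_acc <- function(log2c, log2g) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(xn[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "radial", cost = 2^log2c,
                        gamma = 2^log2g, scale = FALSE)
      pred <- stats::predict(fit, xn[!tr, , drop = FALSE])
      acc[f] <- mean(pred == factor(y[!tr], levels = levels(pred)))
    }
    mean(acc)
  }

  search <- function(cands) {
    best <- NULL
    for (cand in cands) {
      a <- cv_acc(cand[1], cand[2])
      if (is.null(best) || a > best$acc + 1e-12 ||
          (abs(a - best$acc) <= 1e-12 &&
             (cand[1] < best$log2c ||
                (cand[1] == best$log2c && cand[2] < best$log2g)))) {
        best <- list(acc = a, log2c = cand[1], log2g = cand[2])
      }
    }
    best
  }
  coarse <- expand.grid(C = grid$log2C, G = grid$log2gamma)
  best <- search(split(as.matrix(coarse), row(coarse)[, 1]))
  step <- grid$refine_step
  fine <- expand.grid(C = best$log2c + step * (-1:1),
                      G = best$log2g + step * (-1:1))
  best <- search(split(as.matrix(fine), row(fine)[, 1]))

  ## CV statistics at the winner (decision values for AUC)
  scores_cv <- numeric(length(y))
  pred_cv <- integer(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- e1071::svm(xn[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "radial", cost = 2^best$log2c,
                      gamma = 2^best$log2g, scale = FALSE,
                      decision.values = TRUE)
    pr <- stats::predict(fit, xn[!tr, , drop = FALSE],
                         decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    ## orient decision values so larger = class "1"
    if (grepl("^0", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
    scores_cv[!tr] <- dv
    pred_cv[!tr] <- as.integer(as.character(pr))
  }
  st <- classification_stats(pred_cv, scores_cv, y)

  final <- e1071::svm(xn, factor(y), kernel = "radial",
                      cost = 2^best$log2c, gamma = 2^best$log2g,
                      scale = FALSE, decision.values = TRUE)

  structure(list(
    selected = sel,
    feature_names = colnames(x)[sel],
    centre = centre,
    scale = scale_,
    cost = 2^best$log2c,
    gamma = 2^best$log2g,
    model = final,
    folds = folds,
    seed = seed,
    stats = list(ACC_CV = st$ACC, AUC_CV = st$AUC)
  ), class = "adme_svm")
}

#' @export
print.adme_svm <- function(x, ...) {
  cat(sprintf(
    "<adme_svm> RBF C=%.4g gamma=%.4g | %d features | ACC_CV=%.3f AUC_CV=%.3f\n",
    x$cost, x$gamma, length(x$selected), x$stats$ACC_CV, x$stats$AUC_CV))
  invisible(x)
}

#' @export
summary.adme_svm <- function(object, ...) {
  cat("RBF support-vector classifier\n")
  cat(sprintf("  features (%d): %s\n", length(object$selected),
              paste(object$feature_names, collapse = ", ")))
  cat(sprintf("  C = %.5g, gamma = %.5g, %d support vectors\n",
              object$cost, object$gamma, nrow(object$model$SV)))
  cat(sprintf("  10-fold CV: ACC = %.3f, AUC = %.3f\n",
              object$stats$ACC_CV, object$stats$AUC_CV))
  ext <- object$stats_external
  if (!is.null(ext)) {
    cat(sprintf("  external:  ACC = %.3f, AUC = %.3f, sens = %.3f, spec = %.3f\n",
                ext$ACC, ext$AUC, ext$sensitivity, ext$specificity))
  }
  invisible(object)
}

#' Predict method for adme_svm
#'
#' Applies the stored feature selection and training normalization, then
#' the fitted SVM.
#' @param object \code{adme_svm}.
#' @param newdata Feature matrix with the training columns, or an
#'   \code{adm_dataset}.
#' @param ... Unused.
#' @return data.frame with \code{class} (0/1) and \code{score} (decision
#'   value, larger = more positive).
#' @export
predict.adme_svm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "adm_dataset")) newdata$x else newdata
  x <- as.matrix(x)
  if (ncol(x) < max(object$selected)) {
    adm_error("adm_schema_mismatch",
              "newdata has fewer columns than the training matrix")
  }
  xs <- x[, object$selected, drop = FALSE]
  xn <- sweep(sweep(xs, 2, object$centre), 2, object$scale, "/")
  pr <- stats::predict(object$model, xn, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  if (grepl("^0", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  data.frame(class = as.integer(as.character(pr)), score = dv)
}

#' Evaluate a model on an external test set
#'
#' The test set is normalized with the training parameters stored in the
#' model (never refit) and external accuracy, AUC, sensitivity and
#' specificity are computed.
#'
#' @param model \code{adme_svm}.
#' @param test \code{adm_dataset} with the same feature schema.
#' @return List with \code{ACC}, \code{AUC}, \code{sensitivity},
#'   \code{specificity}.  Also stored in the model when assigned back.
#' @export
evaluate_external <- function(model, test) {
  stopifnot(inherits(model, "adme_svm"), inherits(test, "adm_dataset"))
  if (!is.null(test$feature_names) &&
      !all(model$feature_names %in% test$feature_names)) {
    adm_error("adm_schema_mismatch",
              "test set lacks descriptors used by the model")
  }
  pr <- predict(model, test)
  classification_stats(pr$class, pr$score, test$y)
}
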