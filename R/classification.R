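#' Fraction of the disease pool present in a profile
#'
#' The classifier score: the proportion of pool genes contained in the
#' subject's profile, ignoring perturbation direction.
#'
#' @param peep A [new_peep()] object.
#' @param pool A [build_pool()] result with a nonempty gene set.
#' @return A number in \[0, 1\].
#' @export
pool_fraction <- function(peep, pool) {
  stopifnot(inherits(pool, "disease_pool"))
  if (length(pool$genes) == 0) stop("empty disease pool")
  length(intersect(peep_genes(peep), pool$genes)) / length(pool$genes)
}

#' Fit the profile-based disease model on training subjects
#'
#' Computes the control reference (mean/sd per gene over the training
#' controls), the training case profiles and the combinatorial disease pool,
#' all strictly from the training subjects, so that prediction for held-out
#' subjects is completely blind to their data.
#'
#' @param train_data A [peep_dataset()] of training subjects.
#' @param z_thresh Profile z threshold.
#' @return Object of class `peep_classifier`: list with `ref_mean`,
#'   `ref_sd`, `universe`, `pool`, `z_thresh`, `train_ids`.
#' @export
fit_peep_model <- function(train_data, z_thresh = 2.5) {
  z <- compute_zscores(train_data)
  case_ids <- names(train_data$labels)[train_data$labels == "case"]
  if (length(case_ids) < 2) stop("need at least 2 training cases")
  peeps <- build_peeps(z, case_ids, z_thresh)
  pool <- build_pool(peeps, z$universe)
  structure(list(ref_mean = z$ref_mean, ref_sd = z$ref_sd,
                 universe = z$universe, pool = pool, z_thresh = z_thresh,
                 train_ids = sample_ids(train_data)),
            class = "peep_classifier")
}

#' @export
print.peep_classifier <- function(x, ...) {
  cat(sprintf("peep_classifier: pool of %d genes (X = %d), universe %d, z_thresh %g\n",
              length(x$pool$genes), x$pool$X, length(x$universe), x$z_thresh))
  invisible(x)
}

#' Predict pool fractions for new subjects
#'
#' New subjects are z-scored against the training control reference
#' (training mean/sd; held-out subjects never enter the reference),
#' thresholded into profiles, and scored by their [pool_fraction()].
#'
#' @param object A fitted [fit_peep_model()] classifier.
#' @param newdata Genes x subjects numeric matrix, or a `peep_dataset`.
#' @param ... Unused.
#' @return Named numeric vector of pool fractions.
#' @export
predict.peep_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "peep_dataset")) newdata <- newdata$values
  if (length(object$pool$genes) == 0) stop("empty disease pool")
  u <- object$universe
  zt <- object$z_thresh
  zm <- (newdata[u, , drop = FALSE] - object$ref_mean[u]) / object$ref_sd[u]
  vapply(colnames(zm), function(s) {
    col <- zm[, s]
    genes <- u[!is.na(col) & abs(col) > zt]
    length(intersect(genes, object$pool$genes)) / length(object$pool$genes)
  }, 0)
}

#' ROC curve from scores and labels
#'
#' Sweeps every observed score as a candidate threshold (plus a sentinel
#' above the maximum), classifying "case" when score >= threshold, so the
#' curve always spans (0,0) to (1,1).
#'
#' @param scores Numeric vector.
#' @param labels Factor/character with values `case`/`control`, aligned with
#'   `scores`.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  is_case <- as.character(labels) == "case"
  if (!any(is_case) || all(is_case))
    stop("ROC needs both cases and controls")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[is_case] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!is_case] >= t), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under a ROC curve (trapezoidal rule)
#'
#' @param roc A [roc_curve()] data frame.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  f <- roc$fpr[o]; t <- roc$tpr[o]
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

# Stratified fold assignment: shuffle each stratum, deal round-robin so
# remainders are spread one per fold.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in unique(as.character(labels))) {
    idx <- which(as.character(labels) == lv)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  split(seq_along(labels), fold)
}

.check_fold <- function(labels, train_idx) {
  if (sum(labels[train_idx] == "control") < 3 ||
      sum(labels[train_idx] == "case") < 2)
    stop("degenerate fold: training split needs >= 3 controls and >= 2 cases")
}

#' Repeated stratified cross-validation of the pool-fraction classifier
#'
#' Subjects are split into stratified folds (similar case/control proportions
#' per fold; remainders dealt round-robin). For each fold, the control
#' reference, profiles and disease pool — including the occurrence threshold
#' X — are rebuilt from the training subjects only; held-out subjects are
#' scored by the fraction of the training pool present in their profile.
#' All out-of-fold fractions of a repeat are used as candidate thresholds
#' for one ROC curve, and the AUC is aggregated over repeats (mean +/- sd).
#' Repeats in which some fold yields an empty training pool are skipped and
#' counted.
#'
#' @param data A [peep_dataset()].
#' @param z_thresh Profile z threshold (default 2.5).
#' @param n_folds Number of folds (default 5; use 2 for the
#'   half-data robustness check, see [twofold_robustness()]).
#' @param n_repeats Number of random re-splits (default 100).
#' @param seed Integer seed; repeat r uses stream `seed + r`, so extending
#'   `n_repeats` never changes earlier repeats.
#' @param folds Optional fixed fold assignment (list of test-index vectors)
#'   used for every repeat, mainly for reproducibility tests.
#' @return Object of class `peep_cv`: list with `auc` (per completed
#'   repeat), `auc_mean`, `auc_sd`, `roc` (list of per-repeat curves),
#'   `fractions` (subjects x repeats matrix of out-of-fold scores),
#'   `fold_info` (per repeat/fold pool size and X), `n_skipped`, `params`.
#' @export
cross_validate <- function(data, z_thresh = 2.5, n_folds = 5,
                           n_repeats = 100, seed = 1, folds = NULL) {
  .cv_engine(data, n_folds, n_repeats, seed, folds,
             method = "peep", z_thresh = z_thresh)
}

#' Correlation-based k-nearest-neighbour benchmark classifier
#'
#' For every held-out subject, Pearson correlation of its full expression
#' vector with every training subject is computed; the score is the fraction
#' of cases among the k most-correlated training subjects. Cross-validation,
#' ROC and AUC aggregation are identical to [cross_validate()], making the
#' two classifiers directly comparable.
#'
#' @inheritParams cross_validate
#' @param k Number of neighbours (default 15).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A `peep_cv` object (see [cross_validate()]).
#' @export
knn_classify <- function(data, k = 15, n_folds = 5, n_repeats = 100,
                         seed = 1, folds = NULL, method = "pearson") {
  .cv_engine(data, n_folds, n_repeats, seed, folds,
             method = "knn", k = k, cor_method = method)
}

#' Sweep the neighbourhood size of the knn benchmark
#'
#' @inheritParams knn_classify
#' @param ks Candidate k values.
#' @return Data frame with columns `k`, `auc_mean`, `auc_sd`.
#' @export
knn_sweep <- function(data, ks = c(3, 5, 10, 15, 20), n_folds = 5,
                      n_repeats = 10, seed = 1) {
  do.call(rbind, lapply(ks, function(k) {
    r <- knn_classify(data, k = k, n_folds = n_folds,
                      n_repeats = n_repeats, seed = seed)
    data.frame(k = k, auc_mean = r$auc_mean, auc_sd = r$auc_sd)
  }))
}

#' Half-data robustness check
#'
#' Re-runs the pool-fraction cross-validation with two folds, so only half
#' of the cases and controls are available to build the reference and pool;
#' a small drop in AUC relative to the five-fold run indicates robustness to
#' sample size.
#'
#' @inheritParams cross_validate
#' @return A `peep_cv` object.
#' @export
twofold_robustness <- function(data, z_thresh = 2.5, n_repeats = 100,
                               seed = 1) {
  cross_validate(data, z_thresh, n_folds = 2, n_repeats = n_repeats,
                 seed = seed)
}

#' knn scores of test subjects against a training set
#'
#' @param train_values,test_values Genes x subjects numeric matrices.
#' @param train_labels Labels (`case`/`control`) of the training columns.
#' @param k Number of neighbours.
#' @param cor_method Correlation type.
#' @return Named numeric vector: fraction of cases among the k nearest
#'   training subjects of each test subject.
#' @export
knn_scores <- function(train_values, train_labels, test_values, k = 15,
                       cor_method = "pearson") {
  if (k > ncol(train_values)) stop("k exceeds the training-set size")
  cc <- suppressWarnings(stats::cor(train_values, test_values,
                                    method = cor_method))
  is_case <- as.character(train_labels) == "case"
  vapply(seq_len(ncol(test_values)), function(j) {
    r <- cc[, j]
    ok <- which(!is.na(r))
    if (length(ok) == 0) {
      warning("constant expression vector; knn score undefined, using 0.5")
      return(0.5)
    }
    kk <- min(k, length(ok))
    nn <- ok[order(r[ok], decreasing = TRUE)][seq_len(kk)]
    mean(is_case[nn])
  }, 0, USE.NAMES = FALSE) |>
    stats::setNames(colnames(test_values))
}

.cv_engine <- function(data, n_folds, n_repeats, seed, folds, method,
                       z_thresh = 2.5, k = 15, cor_method = "pearson") {
  stopifnot(inherits(data, "peep_dataset"), n_folds >= 2, n_repeats >= 1)
  labels <- data$labels
  ids <- sample_ids(data)
  aucs <- numeric(0); rocs <- list(); fold_info <- list()
  fractions <- matrix(NA_real_, length(ids), 0, dimnames = list(ids, NULL))
  n_skipped <- 0L
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    test_sets <- if (is.null(folds)) .stratified_folds(labels, n_folds)
                 else folds
    scores <- stats::setNames(rep(NA_real_, length(ids)), ids)
    info <- list(); skipped <- FALSE
    for (fi in seq_along(test_sets)) {
      test_idx <- test_sets[[fi]]
      train_idx <- setdiff(seq_along(ids), test_idx)
      .check_fold(labels, train_idx)
      if (method == "peep") {
        train <- peep_dataset(data$values[, train_idx, drop = FALSE],
                              labels[train_idx])
        fit <- fit_peep_model(train, z_thresh)
        info[[fi]] <- data.frame(repeat_ = r, fold = fi,
                                 pool_size = length(fit$pool$genes),
                                 X = fit$pool$X, G = fit$pool$G)
        if (length(fit$pool$genes) == 0) { skipped <- TRUE; break }
        scores[test_idx] <-
          predict(fit, data$values[, test_idx, drop = FALSE])
      } else {
        perm <- sample(train_idx)  # seed-shuffled tie order at the k-th rank
        scores[test_idx] <- knn_scores(
          data$values[, perm, drop = FALSE], labels[perm],
          data$values[, test_idx, drop = FALSE], k, cor_method)
      }
    }
    if (skipped) { n_skipped <- n_skipped + 1L; next }
    roc <- roc_curve(scores, labels)
    aucs <- c(aucs, auc_trapezoid(roc))
    rocs[[length(rocs) + 1L]] <- roc
    fractions <- cbind(fractions, scores)
    fold_info <- c(fold_info, info)
  }
  if (length(aucs) == 0)
    stop("every repeat was skipped (empty training pools)")
  structure(list(auc = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), roc = rocs,
                 fractions = fractions,
                 fold_info = if (length(fold_info))
                   do.call(rbind, fold_info) else NULL,
                 n_skipped = n_skipped,
                 params = list(method = method, n_folds = n_folds,
                               n_repeats = n_repeats, seed = seed,
                               z_thresh = z_thresh, k = k)),
            class = "peep_cv")
}

#' @export
print.peep_cv <- function(x, ...) {
  cat(sprintf("peep_cv (%s, %d-fold x %d repeats): AUC = %.3f +/- %.3f%s\n",
              x$params$method, x$params$n_folds, length(x$auc),
              x$auc_mean, ifelse(is.na(x$auc_sd), 0, x$auc_sd),
              if (x$n_skipped) sprintf(" [%d repeats skipped]", x$n_skipped)
              else ""))
  invisible(x)
}

#' @export
plot.peep_cv <- function(x, ...) {
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  for (roc in x$roc)
    graphics::lines(roc$fpr, roc$tpr, col = grDevices::adjustcolor(4, 0.25))
  graphics::legend("bottomright",
                   sprintf("AUC %.3f +/- %.3f", x$auc_mean,
                           ifelse(is.na(x$auc_sd), 0, x$auc_sd)),
                   bty = "n")
  invisible(x)
}
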