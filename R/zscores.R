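#' Per-subject z-scores against the control reference
#'
#' For every gene i and subject j, computes
#' \deqn{z_i^j = (l_i^j - \langle l_i \rangle_{cont}) / \sigma_{cont}(l_i)}
#' where the mean and standard deviation are taken over the control subjects.
#' When subject j is itself a control, it is removed from the reference and
#' only the remaining controls are used (leave-one-out), so a control never
#' contributes to its own baseline. The sd is the sample estimator (ddof = 1),
#' appropriate for the small control groups this method targets.
#'
#' Genes whose reference sd is zero for the full control set or for any
#' leave-one-out subset are flagged as `excluded`: their z-scores are `NA`
#' and they never enter perturbation profiles or the downstream gene
#' universe.
#'
#' @param data A [peep_dataset()]. At least 3 controls are required so each
#'   control can be scored against the >= 2 remaining ones.
#' @return An object of class `peep_zscores`: list with `z` (genes x
#'   subjects matrix), `ref_mean`/`ref_sd` (full-control-set statistics),
#'   `labels`, `excluded` (gene ids), `universe` (non-excluded gene ids).
#' @export
compute_zscores <- function(data) {
  stopifnot(inherits(data, "peep_dataset"))
  ctrl <- data$values[, data$labels == "control", drop = FALSE]
  nc <- ncol(ctrl)
  if (nc < 3)
    stop("need at least 3 controls (leave-one-out requires 2 remaining)")
  m <- rowMeans(ctrl)
  s <- sqrt(rowSums((ctrl - m)^2) / (nc - 1))

  z <- matrix(NA_real_, nrow(data$values), ncol(data$values),
              dimnames = dimnames(data$values))
  is_ctrl <- data$labels == "control"
  z[, !is_ctrl] <- (data$values[, !is_ctrl, drop = FALSE] - m) / s

  loo_zero <- rep(FALSE, nrow(ctrl))
  for (j in seq_len(nc)) {
    sub <- ctrl[, -j, drop = FALSE]
    mj <- rowMeans(sub)
    sj <- sqrt(rowSums((sub - mj)^2) / (nc - 2))
    loo_zero <- loo_zero | sj == 0
    z[, colnames(ctrl)[j]] <- (ctrl[, j] - mj) / sj
  }

  excluded <- rownames(ctrl)[s == 0 | loo_zero]
  if (length(excluded) == nrow(ctrl))
    stop("every gene has a zero-variance control reference; degenerate data")
  z[excluded, ] <- NA_real_
  structure(list(z = z, ref_mean = m, ref_sd = s, labels = data$labels,
                 excluded = excluded,
                 universe = setdiff(rownames(ctrl), excluded)),
            class = "peep_zscores")
}

#' @export
print.peep_zscores <- function(x, ...) {
  cat(sprintf("peep_zscores: %d genes x %d subjects (%d excluded genes)\n",
              nrow(x$z), ncol(x$z), length(x$excluded)))
  invisible(x)
}

#' Construct a perturbation profile (PEEP) object
#'
#' @param subject_id Subject identifier.
#' @param up,down Character vectors of up-/down-regulated gene ids (disjoint).
#' @param z_thresh The z-score threshold the sets were called at.
#' @return An object of class `peep`.
#' @export
new_peep <- function(subject_id, up, down, z_thresh) {
  if (length(intersect(up, down)))
    stop("up and down sets overlap")
  structure(list(subject_id = subject_id, up = unique(up),
                 down = unique(down), z_thresh = z_thresh),
            class = "peep")
}

#' @export
print.peep <- function(x, ...) {
  cat(sprintf("peep '%s': %d up, %d down (|z| > %g)\n", x$subject_id,
              length(x$up), length(x$down), x$z_thresh))
  invisible(x)
}

#' Genes of a perturbation profile
#'
#' @param peep A [new_peep()] object.
#' @param direction_tagged If `TRUE`, prefix genes with `+`/`-` so that
#'   direction-aware set operations can be performed.
#' @return Character vector of gene ids (union of up and down sets).
#' @export
peep_genes <- function(peep, direction_tagged = FALSE) {
  if (direction_tagged)
    c(paste0("+", peep$up), paste0("-", peep$down))
  else
    c(peep$up, peep$down)
}

#' Threshold a z-score column into a perturbation profile
#'
#' Genes with z strictly above `z_thresh` are called up-regulated, strictly
#' below `-z_thresh` down-regulated; boundary-equal values are not called.
#' Excluded (zero-reference-sd) genes never appear.
#'
#' @param z A `peep_zscores` object.
#' @param subject_id Column to threshold.
#' @param z_thresh Positive z cutoff (default 2.5, the profile threshold
#'   used throughout the package).
#' @return A [new_peep()] object.
#' @export
build_peep <- function(z, subject_id, z_thresh = 2.5) {
  stopifnot(inherits(z, "peep_zscores"), z_thresh > 0)
  if (!subject_id %in% colnames(z$z))
    stop("unknown subject id: ", subject_id)
  col <- z$z[, subject_id]
  col <- col[!is.na(col)]
  new_peep(subject_id, names(col)[col > z_thresh],
           names(col)[col < -z_thresh], z_thresh)
}

#' @rdname build_peep
#' @param subjects Subjects to profile (default: all columns).
#' @return `build_peeps()`: a named list of `peep` objects.
#' @export
build_peeps <- function(z, subjects = colnames(z$z), z_thresh = 2.5) {
  stats::setNames(lapply(subjects, build_peep, z = z, z_thresh = z_thresh),
                  subjects)
}

#' Stability of z-scores under control-population subsampling
#'
#' For each gene, fixes the expression level that corresponds to z = 2.5
#' under the full control set, then repeatedly removes a random fraction of
#' controls, recomputes that level's z-score against the reduced reference
#' and reports the ratio to 2.5. Ratios near 1 indicate that the control
#' population is large enough for stable profiles.
#'
#' @param data A [peep_dataset()].
#' @param removal_fractions Fractions of controls to remove, each in
#'   \[0, 0.5\].
#' @param n_rep Random removals per fraction.
#' @param seed Integer seed.
#' @return A data frame with one row per fraction: quantiles (5/25/50/75/95)
#'   and IQR of the ratio distribution; the raw ratios (gene x rep, per
#'   fraction) are attached as attribute `"ratios"`.
#' @export
stability_analysis <- function(data, removal_fractions = seq(0, 0.5, 0.1),
                               n_rep = 100, seed = 1) {
  stopifnot(inherits(data, "peep_dataset"),
            all(removal_fractions >= 0), all(removal_fractions <= 0.5))
  ctrl <- data$values[, data$labels == "control", drop = FALSE]
  nc <- ncol(ctrl)
  m <- rowMeans(ctrl)
  s <- sqrt(rowSums((ctrl - m)^2) / (nc - 1))
  keep <- s > 0
  ref_level <- (m + 2.5 * s)[keep]
  set.seed(seed)
  ratios <- list()
  out <- lapply(removal_fractions, function(f) {
    n_rm <- round(f * nc)
    if (nc - n_rm < 2)
      stop(sprintf("removal fraction %g leaves fewer than 2 controls", f))
    r <- vapply(seq_len(n_rep), function(rep) {
      idx <- if (n_rm > 0) sample(nc, nc - n_rm) else seq_len(nc)
      sub <- ctrl[keep, idx, drop = FALSE]
      ms <- rowMeans(sub)
      ss <- sqrt(rowSums((sub - ms)^2) / (length(idx) - 1))
      ((ref_level - ms) / ss) / 2.5
    }, numeric(sum(keep)))
    ratios[[as.character(f)]] <<- r
    q <- stats::quantile(r, c(.05, .25, .5, .75, .95), na.rm = TRUE)
    data.frame(fraction = f, q05 = q[1], q25 = q[2], q50 = q[3],
               q75 = q[4], q95 = q[5], iqr = q[4] - q[2], row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "ratios") <- ratios
  res
}
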