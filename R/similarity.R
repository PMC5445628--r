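#' Jaccard index of two gene sets
#'
#' \eqn{J = |A \cap B| / |A \cup B|}; by convention 0 when both sets are
#' empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# One-sided (enrichment) Fisher's exact p for drawing `overlap` or more
# shared elements when sets of sizes `size_a`, `size_b` are sampled from a
# universe of `universe_size`: the hypergeometric survival function.
.overlap_p <- function(overlap, size_a, size_b, universe_size) {
  stats::phyper(overlap - 1, size_a, universe_size - size_a, size_b,
                lower.tail = FALSE)
}

#' Pairwise overlap of perturbation profiles with significance
#'
#' For every unordered pair of subjects, reports the profile overlap (by
#' default direction-agnostic: the union of up and down genes), its Jaccard
#' index, and a one-sided Fisher's exact p-value for enrichment of the
#' overlap relative to random draws from the gene universe, with optional
#' Bonferroni correction over the number of pairs tested.
#'
#' @param peeps List of [new_peep()] objects.
#' @param universe_size Number of genes in the sampling universe (all
#'   non-excluded genes of the dataset).
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (over the pairs tested here) or `"none"`.
#' @param direction_matters If `TRUE`, genes only overlap when perturbed in
#'   the same direction in both subjects.
#' @return Data frame of class `pairwise_overlap`: subject_a, subject_b,
#'   size_a, size_b, overlap, jaccard, p_value, significant.
#' @export
pairwise_overlap_significance <- function(peeps, universe_size, alpha = 0.05,
                                          correction = c("bonferroni", "none"),
                                          direction_matters = FALSE) {
  correction <- match.arg(correction)
  n <- length(peeps)
  if (n < 2) stop("need at least 2 profiles")
  sets <- lapply(peeps, peep_genes, direction_tagged = direction_matters)
  ids <- vapply(peeps, `[[`, "", "subject_id")
  pairs <- utils::combn(n, 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    if (length(union(a, b)) > universe_size)
      stop("universe_size smaller than an observed profile union")
    ov <- length(intersect(a, b))
    data.frame(subject_a = ids[ij[1]], subject_b = ids[ij[2]],
               size_a = length(a), size_b = length(b), overlap = ov,
               jaccard = jaccard(a, b),
               p_value = .overlap_p(ov, length(a), length(b), universe_size),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  thr <- if (correction == "bonferroni") alpha / nrow(res) else alpha
  res$significant <- res$p_value < thr
  class(res) <- c("pairwise_overlap", "data.frame")
  res
}

#' Pearson correlation of two subjects' continuous z-profiles
#'
#' Similarity of the full (unthresholded) z-score profiles over all
#' non-excluded genes with finite z in both subjects.
#'
#' @param z A `peep_zscores` object.
#' @param subject_a,subject_b Subject ids.
#' @return Pearson correlation coefficient.
#' @export
zprofile_correlation <- function(z, subject_a, subject_b) {
  stopifnot(inherits(z, "peep_zscores"))
  for (s in c(subject_a, subject_b))
    if (!s %in% colnames(z$z)) stop("unknown subject id: ", s)
  x <- z$z[z$universe, subject_a]
  y <- z$z[z$universe, subject_b]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 shared genes with finite z-scores")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop(sprintf("constant z-profile for pair (%s, %s); correlation undefined",
                 subject_a, subject_b))
  stats::cor(x[ok], y[ok])
}
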