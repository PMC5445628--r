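#' Group-wise differential expression (case vs control)
#'
#' Per-gene Welch two-sample t-test on log2 values with Benjamini-Hochberg
#' FDR control. This is the conventional comparator against which the
#' per-subject profiles are contrasted; the framework is agnostic to the DE
#' engine, so a plain two-sample test stands in for heavier moderated
#' statistics.
#'
#' @param data A [peep_dataset()] with >= 2 samples per group.
#' @param fdr_cutoff BH q-value cutoff for the selected DE set (default 0.2).
#' @return Object of class `peep_de`: list with `table` (data frame: gene,
#'   mean_case, mean_control, effect = mean case - mean control in log2
#'   units, fold_change = 2^effect, statistic, df, p_value, q_value) and
#'   `de_genes` (genes with q < `fdr_cutoff`).
#' @export
run_de <- function(data, fdr_cutoff = 0.2) {
  stopifnot(inherits(data, "peep_dataset"))
  case <- data$values[, data$labels == "case", drop = FALSE]
  ctrl <- data$values[, data$labels == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  eff <- m1 - m2
  stat <- eff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- se2 == 0  # both groups constant: effect 0 -> p 1, else p 0
  p[zero] <- ifelse(eff[zero] == 0, 1, 0)
  stat[zero] <- ifelse(eff[zero] == 0, 0, Inf * sign(eff[zero]))
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(data$values), mean_case = m1,
                    mean_control = m2, effect = eff, fold_change = 2^eff,
                    statistic = stat, df = df, p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, de_genes = tab$gene[q < fdr_cutoff],
                 fdr_cutoff = fdr_cutoff), class = "peep_de")
}

#' @export
print.peep_de <- function(x, ...) {
  cat(sprintf("peep_de: %d genes tested, %d selected at FDR < %g\n",
              nrow(x$table), length(x$de_genes), x$fdr_cutoff))
  invisible(x)
}

#' Overlap between group-wise DE genes and individual profiles
#'
#' Measures, per subject, the fraction of the group-wise DE set contained in
#' that subject's profile, and, per DE gene, the number of supplied profiles
#' containing it (pass case profiles to count case subjects).
#'
#' @param de_genes Character vector of DE gene ids (nonempty).
#' @param peeps List of [new_peep()] objects.
#' @return List with `fractions` (named per subject: |PEEP inter DE| / |DE|)
#'   and `gene_counts` (named per DE gene: number of profiles containing it).
#' @export
de_overlap_with_peeps <- function(de_genes, peeps) {
  if (length(de_genes) == 0) stop("empty DE gene set")
  de_genes <- unique(de_genes)
  fractions <- vapply(peeps, function(p)
    length(intersect(peep_genes(p), de_genes)) / length(de_genes), 0)
  names(fractions) <- vapply(peeps, `[[`, "", "subject_id")
  counts <- vapply(de_genes, function(g)
    sum(vapply(peeps, function(p) g %in% peep_genes(p), FALSE)), 0L)
  list(fractions = fractions, gene_counts = counts)
}

#' Individual-level consistency of group-wise DE calls
#'
#' For each selected DE gene, reports the fraction of case subjects whose
#' expression is effectively normal (|z| < 1, i.e. within one control sd of
#' the control mean) and the fraction perturbed in the direction opposite to
#' the group-wise effect (sign(z) != sign(effect) and |z| >= 1). The
#' remainder are concordant, so the three fractions partition the cases.
#'
#' @param de A `peep_de` result with a nonempty DE set.
#' @param z A `peep_zscores` object on the same dataset.
#' @return Data frame: gene, effect direction, normal_fraction,
#'   opposite_fraction, concordant_fraction.
#' @export
consistency_report <- function(de, z) {
  stopifnot(inherits(de, "peep_de"), inherits(z, "peep_zscores"))
  genes <- setdiff(de$de_genes, z$excluded)
  eff <- stats::setNames(de$table$effect, de$table$gene)[genes]
  genes <- genes[eff != 0]
  zc <- z$z[genes, z$labels == "case", drop = FALSE]
  normal <- rowMeans(abs(zc) < 1)
  opposite <- rowMeans(sign(zc) != sign(eff[genes]) & abs(zc) >= 1)
  data.frame(gene = genes, direction = ifelse(eff[genes] > 0, "up", "down"),
             normal_fraction = normal, opposite_fraction = opposite,
             concordant_fraction = 1 - normal - opposite,
             row.names = NULL, stringsAsFactors = FALSE)
}
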