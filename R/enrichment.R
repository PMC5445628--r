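#' Gene-set enrichment of one perturbation profile
#'
#' One-sided Fisher's exact test of each term against the profile
#' (direction-agnostic union of up and down genes) over the measured-gene
#' universe. Term genes are intersected with the universe first, so the
#' hypergeometric frame matches the sampling frame of profile membership;
#' terms that vanish after intersection are skipped. Significance is called
#' at `alpha` after Bonferroni correction over the number of terms actually
#' tested.
#'
#' @param peep A [new_peep()] object; its genes must lie in `universe`.
#' @param sets A [read_gmt()] collection (or named list of gene vectors).
#' @param universe Character vector of measured, non-excluded gene ids.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame of class `peep_enrichment`: subject_id, term_id,
#'   overlap, term_size, peep_size, universe_size, p_value, significant.
#' @export
enrich_peep <- function(peep, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  G <- length(universe)
  if (G == 0) stop("empty universe")
  genes <- unique(peep_genes(peep))
  stray <- setdiff(genes, universe)
  if (length(stray))
    stop("profile genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  terms <- lapply(sets, intersect, universe)
  empty <- lengths(terms) == 0
  if (any(empty)) {
    message(sum(empty), " term(s) with no universe genes skipped")
    terms <- terms[!empty]
  }
  if (length(terms) == 0) stop("no testable terms")
  rows <- lapply(names(terms), function(t) {
    tg <- terms[[t]]
    ov <- length(intersect(genes, tg))
    data.frame(subject_id = peep$subject_id, term_id = t, overlap = ov,
               term_size = length(tg), peep_size = length(genes),
               universe_size = G,
               p_value = .overlap_p(ov, length(tg), length(genes), G),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < alpha / nrow(res)
  class(res) <- c("peep_enrichment", "data.frame")
  res
}

#' @rdname enrich_peep
#' @param peeps List of [new_peep()] objects.
#' @return `enrich_peeps()`: row-bound enrichment records for all subjects
#'   (Bonferroni within each subject, over the tested terms).
#' @export
enrich_peeps <- function(peeps, sets, universe, alpha = 0.05) {
  do.call(rbind, lapply(peeps, enrich_peep, sets = sets,
                        universe = universe, alpha = alpha))
}

#' Pathway-level heterogeneity of perturbation profiles
#'
#' For every term significantly enriched (Bonferroni) in at least
#' `min_subjects` of the supplied profiles, computes the Jaccard index of
#' the term-restricted perturbed genes (profile intersected with the term)
#' for every pair of enriched subjects, then pools all pair values of all
#' qualifying terms into one distribution summarised by its
#' 5/25/50/75/95th percentiles. Low values with many enriched subjects mean
#' the same pathway is hit at different genes in different subjects.
#'
#' @inheritParams enrich_peep
#' @param peeps List of [new_peep()] objects (e.g. the case subjects).
#' @param min_subjects Minimum number of enriched subjects per term
#'   (default 3).
#' @return List with `per_term` (data frame: term_id, n_subjects, n_pairs,
#'   mean_jaccard, median_jaccard), `pooled` (all pairwise Jaccard values),
#'   and `quantiles` (5/25/50/75/95th percentiles of `pooled`).
#' @export
pathway_heterogeneity <- function(peeps, sets, universe, alpha = 0.05,
                                  min_subjects = 3) {
  enr <- enrich_peeps(peeps, sets, universe, alpha)
  by_id <- stats::setNames(peeps, vapply(peeps, `[[`, "", "subject_id"))
  per_term <- list(); pooled <- numeric(0)
  for (t in unique(enr$term_id)) {
    hit <- enr$subject_id[enr$term_id == t & enr$significant]
    if (length(hit) < min_subjects) next
    tg <- intersect(sets[[t]], universe)
    sub_sets <- lapply(by_id[hit], function(p) intersect(peep_genes(p), tg))
    pr <- utils::combn(length(hit), 2)
    js <- apply(pr, 2, function(ij) jaccard(sub_sets[[ij[1]]],
                                            sub_sets[[ij[2]]]))
    per_term[[t]] <- data.frame(term_id = t, n_subjects = length(hit),
                                n_pairs = length(js), mean_jaccard = mean(js),
                                median_jaccard = stats::median(js),
                                stringsAsFactors = FALSE)
    pooled <- c(pooled, js)
  }
  if (length(per_term) == 0) {
    warning("no term is enriched in at least ", min_subjects, " subjects")
    return(list(per_term = data.frame(), pooled = numeric(0),
                quantiles = stats::setNames(rep(NA_real_, 5),
                                            c("q05", "q25", "q50", "q75", "q95"))))
  }
  q <- stats::quantile(pooled, c(.05, .25, .5, .75, .95))
  list(per_term = do.call(rbind, c(per_term, make.row.names = FALSE)),
       pooled = pooled,
       quantiles = stats::setNames(q, c("q05", "q25", "q50", "q75", "q95")))
}

#' Per-pathway perturbation table
#'
#' Restricts the profiles to the genes of one term and tabulates the
#' direction of each perturbation: +1 up, -1 down, 0 absent. Row margins
#' count how many subjects have each gene up-/down-regulated; column margins
#' count perturbed term genes per subject.
#'
#' @param peeps List of [new_peep()] objects.
#' @param term Character vector of term gene ids.
#' @return List with `matrix` (term genes x subjects, values in
#'   \{-1, 0, 1\}), `gene_margins` (data frame: gene, n_up, n_down) and
#'   `subject_margins` (named counts of perturbed term genes).
#' @export
per_pathway_perturbation_table <- function(peeps, term) {
  term <- unique(term)
  ids <- vapply(peeps, `[[`, "", "subject_id")
  mat <- matrix(0L, length(term), length(peeps),
                dimnames = list(term, ids))
  for (p in peeps) {
    mat[intersect(p$up, term), p$subject_id] <- 1L
    mat[intersect(p$down, term), p$subject_id] <- -1L
  }
  list(matrix = mat,
       gene_margins = data.frame(gene = term,
                                 n_up = rowSums(mat == 1),
                                 n_down = rowSums(mat == -1),
                                 row.names = NULL),
       subject_margins = colSums(mat != 0))
}
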