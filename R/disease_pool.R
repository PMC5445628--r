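# Accept either `peep` objects or plain character vectors as gene sets.
.as_gene_sets <- function(peeps) {
  lapply(peeps, function(p)
    if (inherits(p, "peep")) unique(peep_genes(p)) else unique(as.character(p)))
}

#' Occupancy histogram of shared profile genes
#'
#' Tallies, over all genes of the universe, the number k of subjects whose
#' profile contains the gene (direction-agnostic), and compares it with the
#' analytic expectation under the null model in which each subject's g
#' perturbed genes are drawn uniformly at random from all G genes: the
#' expected number of genes seen in exactly k of n subjects is
#' \deqn{G \cdot f(k; n, p), \quad p = g/G,}
#' with f the binomial pmf and g the mean profile size.
#'
#' @param peeps List of [new_peep()] objects or character-vector gene sets.
#' @param universe Character vector of gene ids; all profile genes must
#'   belong to it.
#' @return Object of class `occupancy_histogram`: data frame with columns
#'   `k`, `observed`, `expected` (k = 0..n), with attributes `G`, `n`, `p`,
#'   `g_mean`.
#' @export
occupancy_histogram <- function(peeps, universe) {
  sets <- .as_gene_sets(peeps)
  G <- length(unique(universe))
  if (G == 0) stop("empty universe")
  n <- length(sets)
  if (n < 1) stop("need at least one profile")
  stray <- setdiff(unlist(sets), universe)
  if (length(stray))
    stop("profile genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  counts <- table(factor(unlist(sets), levels = universe))
  observed <- tabulate(factor(counts, levels = 0:n), nbins = n + 1)
  g_mean <- mean(lengths(sets))
  p <- g_mean / G
  expected <- G * stats::dbinom(0:n, n, p)
  structure(data.frame(k = 0:n, observed = observed, expected = expected),
            G = G, n = n, p = p, g_mean = g_mean,
            class = c("occupancy_histogram", "data.frame"))
}

#' @export
plot.occupancy_histogram <- function(x, log = "y", ...) {
  obs <- pmax(x$observed, if (grepl("y", log)) 0.5 else 0)
  graphics::plot(x$k, obs, type = "h", lwd = 3, log = log,
                 xlab = "subjects sharing a gene (k)",
                 ylab = "number of genes", ...)
  graphics::lines(x$k, pmax(x$expected, 1e-3), col = 2, lwd = 2)
  graphics::legend("topright", c("observed", "binomial null"),
                   col = c(1, 2), lwd = 2, bty = "n")
  invisible(x)
}

#' Minimal subject count with sub-unit null expectation
#'
#' Solves, by testing increasing values, for the smallest `X_rand` such that
#' the expected number of genes appearing in at least `X_rand` of `n`
#' subjects under the random-draw null falls below one:
#' \deqn{\sum_{k=X_{rand}}^{n} G f(k; n, p) < 1.}
#' The tail is evaluated through the binomial survival function, so it is
#' accurate even when individual terms underflow.
#'
#' @param G Universe size (>= 1).
#' @param n Number of subjects (>= 1).
#' @param p Per-subject gene inclusion probability, in (0, 1); p = g/G.
#' @return Integer in 0..(n + 1); n + 1 means even full sharing (k = n) is
#'   expected more than once.
#' @export
solve_x_rand <- function(G, n, p) {
  stopifnot(G >= 1, n >= 1)
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  for (x in 0:n) {
    # G * sf < 1 and cdf > (G-1)/G are the same condition; the survival form
    # is accurate when the tail is small, the cdf form when the tail is so
    # close to 1 that the survival function rounds up to exactly 1
    sf <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
    cdf <- stats::pbinom(x - 1, n, p)
    if (G * sf < 1 || cdf > (G - 1) / G) return(x)
  }
  n + 1L
}

#' Compile the combinatorial pool of disease-associated genes
#'
#' From the case subjects' profiles, determines the occurrence threshold
#' X = X_rand + 1 (one more than the maximal count expected under the random
#' null, see [solve_x_rand()]) and collects every gene present in at least X
#' case profiles. Membership is direction-agnostic: a gene counts once per
#' subject whether up- or down-regulated, and subjects need not agree on the
#' direction.
#'
#' @param case_peeps List of case [new_peep()] objects (>= 2) or gene sets.
#' @param universe Character vector of gene ids (the non-excluded genes).
#' @return Object of class `disease_pool`: list with `genes`, `X`, `X_rand`,
#'   `g_mean` (mean case profile size), `p` (= g_mean / G), `G`, `n`,
#'   `gene_counts` (per-gene number of case profiles).
#' @export
build_pool <- function(case_peeps, universe) {
  sets <- .as_gene_sets(case_peeps)
  if (length(sets) < 2) stop("need at least 2 case profiles")
  G <- length(unique(universe))
  if (G == 0) stop("empty universe")
  stray <- setdiff(unlist(sets), universe)
  if (length(stray))
    stop("profile genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  n <- length(sets)
  g_mean <- mean(lengths(sets))
  p <- g_mean / G
  if (p <= 0) stop("all case profiles are empty; cannot form a pool")
  if (p >= 1) stop("mean profile size equals the universe; null degenerate")
  X_rand <- solve_x_rand(G, n, p)
  X <- X_rand + 1L
  counts <- table(factor(unlist(sets), levels = universe))
  genes <- names(counts)[counts >= X]
  if (X > n && length(genes) == 0)
    warning("occurrence threshold X exceeds the number of cases; empty pool")
  structure(list(genes = genes, X = X, X_rand = X_rand, g_mean = g_mean,
                 p = p, G = G, n = n,
                 gene_counts = stats::setNames(as.integer(counts),
                                               names(counts))),
            class = "disease_pool")
}

#' @export
print.disease_pool <- function(x, ...) {
  cat(sprintf(
    "disease_pool: %d genes in >= %d of %d cases (X_rand = %d, g = %.1f, p = %.4g, G = %d)\n",
    length(x$genes), x$X, x$n, x$X_rand, x$g_mean, x$p, x$G))
  invisible(x)
}

#' Discrepancy between observed occupancy and the binomial null
#'
#' A chi-square-style descriptive statistic comparing the observed occupancy
#' tallies with their null expectation. Adjacent k-bins are pooled from the
#' left until each pooled bin has expected count >= 5 (the trailing
#' remainder is merged into the last bin); the statistic is
#' \eqn{\sum (O - E)^2 / E} over the pooled bins with df = bins - 1. For
#' profiles truly drawn at random the statistic is on the order of its df;
#' case groups sharing a disease module inflate it by orders of magnitude.
#'
#' @param hist An [occupancy_histogram()].
#' @param min_expected Minimum pooled expected count per bin (default 5).
#' @return List with `statistic`, `df`, and the pooled `bins` data frame.
#' @export
goodness_of_fit_null <- function(hist, min_expected = 5) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  if (all(hist$observed == 0)) stop("all-zero histogram")
  obs <- hist$observed; exp <- hist$expected
  bo <- numeric(0); be <- numeric(0); lab <- character(0)
  co <- 0; ce <- 0; start <- hist$k[1]
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + exp[i]
    if (ce >= min_expected) {
      bo <- c(bo, co); be <- c(be, ce)
      lab <- c(lab, paste0(start, "-", hist$k[i]))
      co <- 0; ce <- 0; start <- hist$k[i] + 1
    }
  }
  if (ce > 0 || co > 0) {  # trailing remainder into last bin
    if (length(bo)) {
      bo[length(bo)] <- bo[length(bo)] + co
      be[length(be)] <- be[length(be)] + ce
      lab[length(lab)] <- sub("-\\d+$", paste0("-", max(hist$k)),
                              lab[length(lab)])
    } else {
      bo <- co; be <- ce; lab <- paste0(start, "-", max(hist$k))
    }
  }
  stat <- sum((bo - be)^2 / be)
  list(statistic = stat, df = max(length(bo) - 1, 1),
       bins = data.frame(k = lab, observed = bo, expected = be))
}
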