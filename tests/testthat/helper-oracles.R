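# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Hypergeometric upper tail by direct enumeration of log-space terms:
# P(overlap >= ov) for sets of sizes sa, sb in a universe of size G.
hyper_tail_oracle <- function(ov, sa, sb, G) {
  if (ov <= 0) return(1)
  hi <- min(sa, sb)
  if (ov > hi) return(0)
  k <- ov:hi
  sum(exp(lchoose(sa, k) + lchoose(G - sa, sb - k) - lchoose(G, sb)))
}

# Binomial upper tail by summing pmf terms built from choose(); used to
# re-solve the occurrence threshold independently of pbinom().
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# G * tail(x) < 1 is equivalent to lower_sum(x-1) > (G-1)/G; the summed
# upper tail loses the deficit when it is below machine epsilon, the lower
# sum retains it, so the oracle accepts whichever regime is representable.
binom_lower_oracle <- function(x, n, p) {
  if (x < 0) return(0)
  k <- 0:min(x, n)
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

x_rand_oracle <- function(G, n, p) {
  for (x in 0:n) {
    if (G * binom_tail_oracle(x, n, p) < 1 ||
        binom_lower_oracle(x - 1, n, p) > (G - 1) / G) return(x)
  }
  n + 1L
}

# Benjamini-Hochberg step-up adjusted values, spelled out from the
# definition: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q[order(o)]
}

# AUC as the Mann-Whitney pairwise probability that a random case outscores
# a random control, ties counted one half.
mw_auc_oracle <- function(scores, labels) {
  cs <- scores[as.character(labels) == "case"]
  ct <- scores[as.character(labels) == "control"]
  cmp <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small Gaussian-baseline dataset for unit tests.
make_toy_dataset <- function(n_genes = 50, n_controls = 10, n_cases = 8,
                             seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  ids <- c(sprintf("c%02d", seq_len(n_controls)),
           sprintf("p%02d", seq_len(n_cases)))
  m <- matrix(rnorm(n_genes * length(ids), 8, 1), n_genes,
              dimnames = list(genes, ids))
  peep_dataset(m, setNames(rep(c("control", "case"),
                               c(n_controls, n_cases)), ids))
}

# Hand-built z-score container for tests that need exact z columns.
fake_zscores <- function(z, labels, excluded = character(0)) {
  structure(list(z = z, ref_mean = rowMeans(z), ref_sd = rep(1, nrow(z)),
                 labels = factor(labels, levels = c("control", "case")),
                 excluded = excluded,
                 universe = setdiff(rownames(z), excluded)),
            class = "peep_zscores")
}

random_peep <- function(universe, size, id) {
  genes <- sample(universe, size)
  n_up <- ceiling(size / 2)
  new_peep(id, genes[seq_len(n_up)],
           genes[setdiff(seq_len(size), seq_len(n_up))], 2.5)
}
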