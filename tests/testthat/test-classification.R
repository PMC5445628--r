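make_pool <- function(genes) {
  structure(list(genes = genes, X = 2L, X_rand = 1L, g_mean = length(genes),
                 p = 0.1, G = 100L, n = 4L,
                 gene_counts = setNames(rep(2L, length(genes)), genes)),
            class = "disease_pool")
}

test_that("pool fractions count direction-agnostic membership", {
  pool <- make_pool(c("a", "b", "c", "d"))
  expect_equal(pool_fraction(new_peep("s", c("a", "b"), c("c", "d"), 2.5),
                             pool), 1)
  expect_equal(pool_fraction(new_peep("s", "x", "y", 2.5), pool), 0)
  expect_equal(pool_fraction(new_peep("s", c("a", "b"), "c", 2.5), pool),
               0.75)
  expect_error(pool_fraction(new_peep("s", "a", "b", 2.5),
                             make_pool(character(0))), "empty")
})

test_that("trapezoidal ROC AUC equals the Mann-Whitney pairwise oracle", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    labels <- sample(rep(c("case", "control"), c(n, n)))
    scores <- sample(seq(0, 1, 0.1), 2 * n, replace = TRUE)  # heavy ties
    roc <- roc_curve(scores, labels)
    expect_equal(auc_trapezoid(roc), mw_auc_oracle(scores, labels),
                 tolerance = 1e-10)
    # ROC spans (0,0) to (1,1) and is monotone
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(max(roc$fpr), max(roc$tpr)), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    # AUC is invariant under monotone score transformations
    expect_equal(auc_trapezoid(roc_curve(exp(3 * scores), labels)),
                 auc_trapezoid(roc), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:3, rep("case", 3)), "both cases and controls")
})

test_that("cross-validation separates a strong planted module perfectly", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 1000, n_controls = 15, n_cases = 20, module_size = 100,
    case_module_fraction = 1, background_peep_size = 0, effect_size = 10,
    seed = 19))
  cv <- cross_validate(sim$data, n_repeats = 3, seed = 7)
  expect_equal(cv$auc, rep(1, 3))
  expect_equal(cv$auc_sd, 0)
  expect_identical(cv$n_skipped, 0L)
})

test_that("label permutation collapses the AUC to chance", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 800, n_controls = 16, n_cases = 24, module_size = 80,
    case_module_fraction = 0.5, background_peep_size = 40, effect_size = 4,
    seed = 23))
  set.seed(64)
  aucs <- unlist(lapply(1:8, function(i) {
    perm <- sample(as.character(sim$data$labels))
    d_perm <- peep_dataset(sim$data$values,
                           setNames(perm, sample_ids(sim$data)))
    # a permutation may leave no shared signal at all: the pool is then
    # empty by construction and the classifier abstains for that draw
    tryCatch(cross_validate(d_perm, n_repeats = 2, seed = 3 + i)$auc,
             error = function(e) NULL)
  }))
  expect_gte(length(aucs), 6)
  expect_lt(abs(mean(aucs) - 0.5), 2 * sd(aucs))
})

test_that("training artifacts are blind to held-out subjects", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 500, n_controls = 12, n_cases = 16, module_size = 60,
    case_module_fraction = 0.8, background_peep_size = 20, effect_size = 6,
    seed = 29))
  d <- sim$data
  labels <- d$labels
  set.seed(1); folds <- peepr:::.stratified_folds(labels, 4)

  # perturb the held-out subjects of fold 1 (all but one, kept as a probe),
  # leaving the training folds untouched
  d2 <- d
  touched <- folds[[1]][-1]; probe <- sample_ids(d)[folds[[1]][1]]
  d2$values[, touched] <- d2$values[, touched] +
    matrix(rnorm(length(touched) * nrow(d2$values), sd = 2),
           nrow(d2$values))

  train_idx <- setdiff(seq_along(labels), folds[[1]])
  f1 <- fit_peep_model(peep_dataset(d$values[, train_idx],
                                    labels[train_idx]))
  f2 <- fit_peep_model(peep_dataset(d2$values[, train_idx],
                                    labels[train_idx]))
  expect_identical(f1$ref_mean, f2$ref_mean)
  expect_identical(f1$ref_sd, f2$ref_sd)
  expect_identical(f1$pool$genes, f2$pool$genes)
  expect_identical(f1$pool$X, f2$pool$X)

  # the full CV run with fixed folds reports identical fold-1 training
  # artifacts, and the untouched probe subject gets the identical score
  cv1 <- cross_validate(d, n_repeats = 1, seed = 5, folds = folds)
  cv2 <- cross_validate(d2, n_repeats = 1, seed = 5, folds = folds)
  expect_identical(cv1$fold_info[cv1$fold_info$fold == 1,
                                 c("pool_size", "X", "G")],
                   cv2$fold_info[cv2$fold_info$fold == 1,
                                 c("pool_size", "X", "G")])
  expect_identical(cv1$fractions[probe, 1], cv2$fractions[probe, 1])
})

test_that("cross-validation is deterministic given the seed", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 400, n_controls = 12, n_cases = 12, module_size = 60,
    case_module_fraction = 0.8, background_peep_size = 10, effect_size = 8,
    seed = 37))
  a <- twofold_robustness(sim$data, n_repeats = 3, seed = 11)
  b <- twofold_robustness(sim$data, n_repeats = 3, seed = 11)
  expect_identical(a$auc, b$auc)
  expect_identical(a$fractions, b$fractions)
  # extending the repeats leaves the earlier repeats untouched
  c4 <- twofold_robustness(sim$data, n_repeats = 4, seed = 11)
  expect_identical(c4$auc[1:3], a$auc)
})

test_that("twofold training retains accuracy on a strong signal", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 1000, n_controls = 16, n_cases = 20, module_size = 100,
    case_module_fraction = 1, background_peep_size = 0, effect_size = 10,
    seed = 43))
  cv2 <- twofold_robustness(sim$data, n_repeats = 3, seed = 13)
  cv5 <- cross_validate(sim$data, n_folds = 5, n_repeats = 3, seed = 13)
  expect_gte(cv2$auc_mean, 0.95)
  expect_lte(cv2$auc_mean, cv5$auc_mean + 0.05)
})

test_that("knn scores behave on degenerate neighbourhoods", {
  set.seed(3)
  train <- matrix(rnorm(40), 10, 4,
                  dimnames = list(paste0("g", 1:10), paste0("t", 1:4)))
  labels <- c("case", "control", "control", "control")
  test <- train[, 1, drop = FALSE]
  colnames(test) <- "new"
  # identical to a training case at k = 1
  expect_equal(unname(knn_scores(train, labels, test, k = 1)), 1)
  # all-control training set: every score 0
  expect_equal(unname(knn_scores(train, rep("control", 4), test, k = 3)), 0)
  expect_error(knn_scores(train, labels, test, k = 9), "exceeds")
  # constant test vector: flagged, scored 0.5
  const <- matrix(5, 10, 1, dimnames = list(paste0("g", 1:10), "flat"))
  expect_warning(s <- knn_scores(train, labels, const, k = 2), "constant")
  expect_equal(unname(s), 0.5)
})

test_that("knn cross-validation tracks the pool classifier on easy data", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 600, n_controls = 14, n_cases = 18, module_size = 80,
    case_module_fraction = 1, background_peep_size = 0, effect_size = 10,
    seed = 53))
  kn <- knn_classify(sim$data, k = 5, n_repeats = 3, seed = 9)
  expect_gte(kn$auc_mean, 0.95)
  sw <- knn_sweep(sim$data, ks = c(3, 5), n_repeats = 2, seed = 9)
  expect_identical(sw$k, c(3, 5))
  expect_true(all(sw$auc_mean >= 0.9))
})
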