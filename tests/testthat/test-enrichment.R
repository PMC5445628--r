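test_that("enrichment p-values match hypergeometric enumeration", {
  u <- sprintf("u%d", 1:20)
  term5 <- u[1:5]
  sets <- structure(list(T1 = term5), class = "gene_set_collection")
  peep <- new_peep("s1", term5[1:3], term5[4:5], 2.5)  # overlap 5 of 5
  res <- enrich_peep(peep, sets, u)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)
  expect_identical(res$overlap, 5L)

  # zero overlap: one-sided p = 1, never significant
  p0 <- new_peep("s2", u[6:8], u[9:10], 2.5)
  sets0 <- structure(list(T1 = u[1:5]), class = "gene_set_collection")
  r0 <- enrich_peep(p0, sets0, u)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  # 200 random configurations against the enumeration oracle
  set.seed(71)
  for (i in 1:200) {
    G <- sample(30:150, 1)
    uu <- sprintf("x%d", seq_len(G))
    term <- sample(uu, sample(3:(G %/% 3), 1))
    pp <- random_peep(uu, sample(3:(G %/% 3), 1), "s")
    r <- enrich_peep(pp, list(T = term), uu)
    expect_equal(r$p_value,
                 hyper_tail_oracle(r$overlap, r$term_size, r$peep_size, G),
                 tolerance = 1e-10)
  }
})

test_that("enrichment is symmetric in the two sets and respects the frame", {
  u <- sprintf("u%d", 1:60)
  a <- u[1:12]; b <- u[c(1:5, 20:26)]
  pa <- enrich_peep(new_peep("s", a, character(0), 2.5), list(T = b), u)
  pb <- enrich_peep(new_peep("s", b, character(0), 2.5), list(T = a), u)
  expect_equal(pa$p_value, pb$p_value, tolerance = 1e-12)

  # term genes outside the universe are cut to the frame; empty terms skip
  expect_message(
    r <- enrich_peep(new_peep("s", a, character(0), 2.5),
                     list(T = c(b, "alien"), dead = c("z1", "z2")), u),
    "skipped")
  expect_identical(nrow(r), 1L)
  expect_identical(r$term_size, 12L)
  expect_error(enrich_peep(new_peep("s", "alien", character(0), 2.5),
                           list(T = b), u), "outside the universe")
})

test_that("Bonferroni significance shrinks as more terms are tested", {
  set.seed(8)
  u <- sprintf("u%d", 1:100)
  peep <- new_peep("s", u[1:10], u[11:20], 2.5)
  one <- enrich_peep(peep, list(T1 = u[1:20]), u)
  many <- enrich_peep(peep, c(list(T1 = u[1:20]),
                              lapply(1:20, function(i) sample(u, 10))), u)
  expect_true(many$significant[many$term_id == "T1"] <= one$significant)
  expect_equal(one$p_value, many$p_value[many$term_id == "T1"])
})

test_that("pathway heterogeneity pools term-restricted Jaccard indices", {
  u <- sprintf("u%d", 1:100)
  term <- u[1:6]  # {a..f}
  sets <- list(PATH = term)
  # subject1 hits {a,b,c}, subject2 hits {b,c,d}: J = 2/4
  p1 <- new_peep("s1", term[1:3], character(0), 2.5)
  p2 <- new_peep("s2", term[2:4], character(0), 2.5)
  het <- pathway_heterogeneity(list(p1, p2), sets, u, min_subjects = 2)
  expect_equal(het$pooled, 0.5)
  expect_equal(het$per_term$n_subjects, 2)

  # identical term-subsets: all J = 1; disjoint halves: J = 0
  q1 <- new_peep("s1", term[1:3], character(0), 2.5)
  q2 <- new_peep("s2", character(0), term[1:3], 2.5)
  expect_equal(
    pathway_heterogeneity(list(q1, q2), sets, u, min_subjects = 2)$pooled, 1)
  r2 <- new_peep("s2", term[4:6], character(0), 2.5)
  expect_equal(
    pathway_heterogeneity(list(q1, r2), sets, u, min_subjects = 2)$pooled, 0)

  # no qualifying term: empty result with a warning
  lone <- list(new_peep("s1", u[50:52], character(0), 2.5))
  expect_warning(empty <- pathway_heterogeneity(lone, sets, u,
                                                min_subjects = 3),
                 "at least 3")
  expect_length(empty$pooled, 0)
})

test_that("per-pathway tables carry direction and exact margins", {
  term <- c("a", "b", "c")
  peeps <- list(new_peep("s1", c("a", "z"), "b", 2.5),
                new_peep("s2", "a", character(0), 2.5),
                new_peep("s3", character(0), "a", 2.5),
                new_peep("s4", "q", "r", 2.5))
  tab <- per_pathway_perturbation_table(peeps, term)
  expect_identical(dim(tab$matrix), c(3L, 4L))
  # gene a: up in 2 subjects, down in 1
  expect_equal(tab$gene_margins[tab$gene_margins$gene == "a",
                                c("n_up", "n_down")],
               data.frame(n_up = 2, n_down = 1, row.names = 1L),
               ignore_attr = TRUE)
  # subject with no term genes perturbed: all-zero column
  expect_true(all(tab$matrix[, "s4"] == 0))
  expect_equal(unname(tab$subject_margins), c(2, 1, 1, 0))
  # margin conservation: up + down counts equal nonzero entries
  expect_equal(sum(tab$gene_margins$n_up) + sum(tab$gene_margins$n_down),
               sum(tab$matrix != 0))
})
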