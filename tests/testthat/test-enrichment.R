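test_that("ontology construction validates edges and acyclicity", {
  expect_error(ontology(c("a", "b"),
                        data.frame(child = "a", parent = "c", type = "is_a")),
               "not declared")
  expect_error(ontology(c("a", "b"),
                        data.frame(child = c("a", "b"), parent = c("b", "a"),
                                   type = "is_a")),
               "acyclic")
  expect_error(ontology(c("a", "b"),
                        data.frame(child = "a", parent = "b", type = "regulates")),
               "edge types")
})

test_that("annotation closure propagates to all ancestors and is idempotent", {
  onto <- ontology(c("root", "p1", "p2", "child"),
                   data.frame(child = c("p1", "p2", "child", "child"),
                              parent = c("root", "root", "p1", "p2"),
                              type = c("is_a", "part_of", "is_a",
                                       "develops_from")))
  r <- rel(g1 = "child", g2 = "p1")
  closed <- annotation_closure(r, onto)
  expect_setequal(closed$g1, c("child", "p1", "p2", "root"))  # diamond
  expect_setequal(closed$g2, c("p1", "root"))
  again <- annotation_closure(closed, onto)
  expect_identical(lapply(again, sort), lapply(closed, sort))
})

test_that("hypergeometric p-value matches the combinatorial tail", {
  ids <- paste0("e", 1:20)
  r <- annotation_relation(stats::setNames(
    lapply(1:20, function(i) if (i <= 4) "tA" else character()), ids))
  expect_equal(term_enrichment_p(paste0("e", c(1, 2, 3, 10, 11)), ids,
                                 "tA", r),
               496 / 15504, tolerance = 1e-12)
  # term annotating everything is never enriched
  rall <- annotation_relation(stats::setNames(rep(list("tA"), 20), ids))
  expect_equal(term_enrichment_p(ids[1:5], ids, "tA", rall), 1)
  # zero in-set hits: vacuous tail
  expect_equal(term_enrichment_p(paste0("e", 10:12), ids, "tA", r), 1)
  expect_error(term_enrichment_p("eX", ids, "tA", r), "contained")
})

test_that("adding an annotated entity never increases the p-value", {
  ids <- paste0("e", 1:15)
  r <- annotation_relation(stats::setNames(
    lapply(1:15, function(i) if (i <= 6) "tA" else character()), ids))
  for (n in 2:6) {
    with_term <- term_enrichment_p(ids[c(1:n, 8:9)], ids, "tA", r)
    without <- term_enrichment_p(ids[c(1:(n - 1), 7:9)], ids, "tA", r)
    expect_lte(with_term, without)
  }
})

test_that("bicluster annotation keeps significant terms with weight 1 - p", {
  em <- em_from(matrix(0L, 10, 6))
  rg <- annotation_relation(stats::setNames(
    lapply(1:10, function(i) if (i <= 3) "tA" else "tB"), genes(em)))
  rs <- annotation_relation(stats::setNames(
    lapply(1:6, function(j) if (j <= 3) "u1" else "u2"), situations(em)))
  bc <- bicluster(paste0("g", 1:3), paste0("s", 1:3))
  sb <- annotate_bicluster(bc, em, rg, rs, alpha_g = 0.05, alpha_s = 0.1)
  expect_identical(sb$gene_terms$term, "tA")
  p <- term_enrichment_p(bc$genes, genes(em), "tA", rg)
  expect_equal(sb$gene_terms$weight, 1 - p)
  expect_identical(sb$situation_terms$term, "u1")

  expect_null(annotate_bicluster(bicluster("g1", paste0("s", 1:3)),
                                 em, rg, rs))
  empty <- annotate_bicluster(bc, em, rg, rs, alpha_g = 0, alpha_s = 0)
  expect_identical(nrow(empty$gene_terms), 0L)
  expect_identical(nrow(empty$situation_terms), 0L)
})

test_that("uniformly random terms are retained at about the alpha rate", {
  set.seed(18)
  ids <- paste0("g", 1:60)
  em <- em_from(matrix(0L, 60, 4), ids)
  bc <- bicluster(sample(ids, 20), situations(em)[1:2])
  alpha <- 0.3
  hits <- 0L; total <- 0L
  for (i in 1:150) {
    r <- random_relation(ids, "tA", p = 0.5)
    p <- term_enrichment_p(bc$genes, ids, "tA", r)
    hits <- hits + (p <= alpha); total <- total + 1L
  }
  expect_lt(abs(hits / total - alpha), 3 * sqrt(alpha * (1 - alpha) / total) +
              0.05)  # slack for the discrete hypergeometric support
})

test_that("permutation calibration keeps real signal and rejects noise", {
  set.seed(4)
  pd <- plant_biclusters(small_gen(fp_noise = 0, fn_noise = 0,
                                   background_density = 0.02, seed = 21))
  sys <- greedy_bicluster(pd$matrix, search_config(rho = 1))
  cg <- annotation_closure(pd$r_gene, pd$gene_ontology)
  alpha <- permutation_alpha(pd$matrix, sys, cg, "gene", n_perms = 20,
                             target_fdr = 0.05, seed = 3)
  expect_gt(alpha, 0)

  # random annotations: no sizeable threshold can pass the FDR bound, so the
  # calibrated alpha collapses towards 0 (small nonzero values remain
  # possible at finite permutation counts)
  rand <- random_relation(genes(pd$matrix),
                          pd$gene_ontology$terms$id, p = 0.1)
  alpha_rand <- permutation_alpha(pd$matrix, sys, rand, "gene", n_perms = 50,
                                  target_fdr = 0.05, seed = 3)
  expect_lt(alpha_rand, 0.01)

  expect_error(permutation_alpha(pd$matrix, bicluster_system(list()), cg,
                                 "gene"), "at least one")
})

test_that("system annotation drops term-free biclusters, keeps one-sided", {
  em <- em_from(matrix(0L, 12, 8))
  rg <- annotation_relation(stats::setNames(
    lapply(1:12, function(i) if (i <= 4) "tA" else character()), genes(em)))
  rs <- annotation_relation(stats::setNames(
    rep(list(character()), 8), situations(em)))
  sys <- bicluster_system(
    bicluster(paste0("g", 1:4), paste0("s", 1:3)),   # gene-side signal only
    bicluster(paste0("g", 5:7), paste0("s", 4:6)),   # nothing enriched
    bicluster("g1", paste0("s", 1:3)))               # trivial
  res <- annotate_system(sys, em, rg, rs, alpha_g = 0.05, alpha_s = 0.05)
  expect_length(res$system, 1L)
  expect_identical(res$source_index, 1L)
  expect_identical(res$system[[1]]$gene_terms$term, "tA")
  expect_identical(nrow(res$system[[1]]$situation_terms), 0L)

  trivial_only <- bicluster_system(bicluster("g1", paste0("s", 1:4)))
  expect_length(annotate_system(trivial_only, em, rg, rs)$system, 0L)
})

test_that("planted terms are recovered across seeded runs", {
  recovered <- vapply(1:10, function(run) {
    pd <- plant_biclusters(small_gen(fp_noise = 0.03, fn_noise = 0.03,
                                     background_density = 0.02, seed = run))
    cg <- annotation_closure(pd$r_gene, pd$gene_ontology)
    cs <- annotation_closure(pd$r_situation, pd$situation_ontology)
    sys <- greedy_bicluster(pd$matrix, search_config(rho = 1))
    res <- annotate_system(sys, pd$matrix, cg, cs,
                           alpha_g = 0.05, alpha_s = 0.1)
    kept <- res$table$term[res$table$kept & res$table$p_value <= 0.05]
    planted <- unlist(c(pd$truth$gene_terms, pd$truth$situation_terms))
    all(planted %in% kept)
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})
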