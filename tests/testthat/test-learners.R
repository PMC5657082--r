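test_that("unrolling has one instance per cell in row-major order", {
  em <- em_from(matrix(c(1L), 1, 1))
  d <- unroll(em, rel(g1 = "tA"), rel(s1 = "uB"), "tA", "uB")
  expect_identical(length(d$class), 1L)
  expect_identical(ncol(d$features) + 1L, 3L)

  em2 <- em_from(matrix(c(1, 0, 0, 1), 2, 2))
  d2 <- unroll(em2, rel(g1 = "tA", g2 = "tB"), rel(s1 = "u1"),
               c("tA", "tB"), "u1")
  expect_identical(length(d2$class), 4L)
  expect_identical(ncol(d2$features) + 1L, 4L)
  expect_identical(d2$gene, c("g1", "g1", "g2", "g2"))
  expect_identical(d2$situation, c("s1", "s2", "s1", "s2"))
  # class column equals the matrix cell of each back-reference
  expect_identical(d2$class,
                   em2$values[cbind(d2$gene, d2$situation)])
  expect_error(unroll(em2, rel(g1 = "tA"), rel(s1 = "tA"), "tA", "tA"),
               "disjoint")
})

test_that("unrolling then regrouping reconstructs the matrix", {
  set.seed(14)
  em <- em_from(matrix(rbinom(35, 1, 0.4), 7, 5))
  gv <- paste0("t", 1:4); sv <- paste0("u", 1:3)
  d <- unroll(em, random_relation(genes(em), gv),
              random_relation(situations(em), sv), gv, sv)
  rebuilt <- matrix(0L, 7, 5, dimnames = dimnames(em$values))
  rebuilt[cbind(d$gene, d$situation)] <- d$class
  expect_identical(rebuilt, em$values)
})

test_that("feature selection drops features below the ceiling threshold", {
  feats <- cbind(a = c(1, rep(0, 999)), b = rep(0, 1000),
                 c = rep(c(1, 0), 500)) == 1
  d <- structure(list(features = feats, class = rep(0:1, 500),
                      gene = rep("g", 1000), situation = rep("s", 1000),
                      gene_vocab = c("a", "b"), situation_vocab = "c"),
                 class = "unrolled_dataset")
  kept <- select_features(d, 0.001)              # ceiling(1) = 1
  expect_identical(colnames(kept$features), c("a", "c"))
  expect_identical(colnames(select_features(d, 0)$features),
                   c("a", "b", "c"))
  expect_warning(select_features(d, 0.999), "all features dropped")
})

# noiseless fixture: cell is 1 exactly where the gene has tA and the
# situation has sB
pattern_fixture <- function(n_g = 12, n_s = 8, seed = 2) {
  set.seed(seed)
  gids <- paste0("g", seq_len(n_g)); sids <- paste0("s", seq_len(n_s))
  rg <- annotation_relation(stats::setNames(lapply(seq_len(n_g), function(i)
    if (i %% 3 == 0) c("tA", "tC") else "tC"), gids))
  rs <- annotation_relation(stats::setNames(lapply(seq_len(n_s), function(j)
    if (j %% 2 == 0) "sB" else "sD"), sids))
  A <- outer(vapply(gids, function(g) "tA" %in% rg[[g]], logical(1)),
             vapply(sids, function(s) "sB" %in% rs[[s]], logical(1)), "&")
  em <- expression_matrix(A * 1L, gids, sids)
  list(em = em, rg = rg, rs = rs,
       data = unroll(em, rg, rs, c("tA", "tC"), c("sB", "sD")))
}

test_that("rule learning separates noiseless conjunctive patterns exactly", {
  fx <- pattern_fixture()
  rl <- learn_rules(fx$data, seed = 1)
  expect_length(rl, 1L)
  expect_setequal(rl[[1]]$gene_literals$term, "tA")
  expect_setequal(rl[[1]]$situation_literals$term, "sB")
  conf <- predict_confidence(rl, fx$data$gene, fx$data$situation,
                             fx$rg, fx$rs)
  expect_identical(as.integer(conf > 0.5), fx$data$class)

  allneg <- fx$data; allneg$class <- rep(0L, length(allneg$class))
  expect_length(learn_rules(allneg, seed = 1), 0L)
})

test_that("two disjoint noiseless patterns give a jointly exact rule set", {
  set.seed(8)
  gids <- paste0("g", 1:18); sids <- paste0("s", 1:10)
  rg <- annotation_relation(stats::setNames(lapply(1:18, function(i)
    c(if (i <= 6) "tA", if (i > 12) "tB")), gids))
  rs <- annotation_relation(stats::setNames(lapply(1:10, function(j)
    c(if (j <= 4) "u1", if (j > 7) "u2")), sids))
  A <- matrix(0L, 18, 10, dimnames = list(gids, sids))
  A[1:6, 1:4] <- 1L; A[13:18, 8:10] <- 1L
  em <- expression_matrix(A)
  d <- unroll(em, rg, rs, c("tA", "tB"), c("u1", "u2"))
  rl <- learn_rules(d, seed = 3)
  expect_length(rl, 2L)
  conf <- predict_confidence(rl, d$gene, d$situation, rg, rs)
  expect_identical(as.integer(conf > 0.5), d$class)
})

test_that("rule confidence is Laplace-corrected coverage", {
  r <- rule(data.frame(term = "tA", sign = 1L), NULL, p = 9L, n = 0L)
  expect_equal(r$confidence, 10 / 11)
})

test_that("tree learning handles pure, planted and feature-free data", {
  fx <- pattern_fixture()
  pure <- fx$data; pure$class <- rep(1L, length(pure$class))
  tr <- learn_tree(pure, seed = 1)
  expect_true(tr$root$leaf)
  expect_identical(tr$root$class, 1L)

  tr2 <- learn_tree(fx$data, seed = 1)
  conf <- predict_confidence(tr2, fx$data$gene, fx$data$situation,
                             fx$rg, fx$rs)
  expect_identical(as.integer(conf > 0.5), fx$data$class)

  nofeat <- fx$data
  nofeat$features <- nofeat$features[, 0, drop = FALSE]
  nofeat$gene_vocab <- character(); nofeat$situation_vocab <- character()
  tr3 <- learn_tree(nofeat, seed = 1)
  expect_true(tr3$root$leaf)
  expect_identical(tr3$root$class,
                   as.integer(mean(nofeat$class) > 0.5))
})

test_that("pruning simplifies noise-fitted trees without hurting the holdout", {
  set.seed(77)
  n <- 400
  feats <- matrix(runif(n * 6) < 0.5, n, 6,
                  dimnames = list(NULL, paste0("t", 1:6)))
  y <- as.integer(feats[, 1] & (runif(n) < 0.9))   # t1 drives, rest noise
  d <- structure(list(features = feats, class = y,
                      gene = paste0("g", seq_len(n)),
                      situation = rep("s1", n),
                      gene_vocab = paste0("t", 1:6),
                      situation_vocab = character()),
                 class = "unrolled_dataset")
  unpruned <- learn_tree(d, seed = 2, holdout_fraction = 0)
  pruned <- learn_tree(d, seed = 2, holdout_fraction = 0.2)
  count_leaves <- function(node) if (node$leaf) 1L else
    count_leaves(node$left) + count_leaves(node$right)
  expect_lte(count_leaves(pruned$root), count_leaves(unpruned$root))
})

test_that("tree paths convert to signed rules", {
  fx <- pattern_fixture()
  inv <- fx$data
  inv$class <- 1L - inv$class          # positive iff NOT (tA and sB)
  tr <- learn_tree(inv, seed = 1)
  rl <- tree_to_rules(tr)
  expect_gt(length(rl), 0L)
  signs <- unlist(lapply(rl, function(r)
    c(r$gene_literals$sign, r$situation_literals$sign)))
  expect_true(any(signs == -1L))
  conf <- predict_confidence(rl, inv$gene, inv$situation, fx$rg, fx$rs)
  expect_identical(as.integer(conf > 0.5), inv$class)

  allneg <- fx$data; allneg$class <- rep(0L, length(allneg$class))
  expect_length(tree_to_rules(learn_tree(allneg, seed = 1)), 0L)
})

test_that("rules map to crisp rectangles, vacuous and negated sides included", {
  r1 <- rule(data.frame(term = "tA", sign = 1L),
             data.frame(term = "sB", sign = 1L))
  r2 <- rule(data.frame(term = "tA", sign = 1L), NULL)
  r3 <- rule(data.frame(term = "tA", sign = -1L),
             data.frame(term = "sB", sign = 1L))
  sbs <- rules_to_semantic_biclusters(
    structure(list(r1, r2, r3), class = "rule_list"))
  gids <- paste0("g", 1:4); sids <- paste0("s", 1:4)
  rg <- rel(g1 = "tA", g2 = "tA", g3 = character(), g4 = character())
  rs <- rel(s1 = "sB", s2 = character(), s3 = "sB", s4 = character())
  bc1 <- induce_bicluster(sbs[[1]], gids, sids, rg, rs)
  expect_setequal(bc1$genes, c("g1", "g2"))
  expect_setequal(bc1$situations, c("s1", "s3"))
  bc2 <- induce_bicluster(sbs[[2]], gids, sids, rg, rs)
  expect_setequal(bc2$situations, sids)          # vacuous side: all
  bc3 <- induce_bicluster(sbs[[3]], gids, sids, rg, rs)
  expect_setequal(bc3$genes, c("g3", "g4"))      # tA-free genes
  expect_setequal(bc3$situations, c("s1", "s3"))
})

test_that("first matching rule supplies the confidence, default is zero", {
  r1 <- rule(data.frame(term = "tA", sign = 1L), NULL, p = 9, n = 0)
  r2 <- rule(data.frame(term = "tB", sign = 1L), NULL, p = 1, n = 1)
  rl <- structure(list(r1, r2), class = "rule_list")
  rg <- rel(gBoth = c("tA", "tB"), gB = "tB", gNone = character())
  rs <- rel(s1 = character())
  conf <- predict_confidence(rl, c("gBoth", "gB", "gNone"), "s1", rg, rs)
  expect_equal(conf, c(10 / 11, 2 / 4, 0))
})
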