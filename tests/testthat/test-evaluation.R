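test_that("rectangular splits retain sqrt-f of each dimension", {
  set.seed(3)
  em <- em_from(matrix(rbinom(200, 1, 0.5), 20, 10))
  sp <- split_matrix(em, 0.7, seed = 5)
  expect_identical(dim(sp$train), as.integer(c(round(20 * sqrt(0.7)),
                                               round(10 * sqrt(0.7)))))
  # region partition sizes
  n_tg <- length(sp$train_genes); n_ts <- length(sp$train_situations)
  tc <- sp$test_cells
  expect_identical(sum(tc$region == "kG"), n_tg * (10L - n_ts))
  expect_identical(sum(tc$region == "kL"), (20L - n_tg) * n_ts)
  expect_identical(sum(tc$region == "bd"), (20L - n_tg) * (10L - n_ts))
  expect_identical(nrow(tc) + n_tg * n_ts, 200L)
  # labels match the source matrix
  expect_identical(tc$label,
                   em$values[cbind(tc$gene, tc$situation)])

  full <- split_matrix(em, 1, seed = 1)
  expect_identical(dim(full$train), dim(em))
  expect_identical(nrow(full$test_cells), 0L)
  expect_error(split_matrix(em, 1e-6, seed = 1), "zero")
})

test_that("hold-out accuracy scores a classifier cell by cell", {
  tc <- data.frame(gene = c("a", "b", "c"), situation = "s",
                   label = c(1L, 0L, 1L), stringsAsFactors = FALSE)
  expect_equal(test_accuracy(function(g, s) c(1L, 0L, 1L), tc), 1)
  expect_equal(test_accuracy(function(g, s) rep(0L, length(g)), tc), 1 / 3)
  f <- function(g, s) as.integer(g == "a")
  g <- function(g_, s) 1L - f(g_, s)
  expect_equal(test_accuracy(g, tc), 1 - test_accuracy(f, tc))
  expect_error(test_accuracy(f, tc[0, ]), "empty")
})

test_that("the default theta grids give 16 operating points and a hull", {
  set.seed(10)
  gv <- paste0("t", 1:4); sv <- paste0("u", 1:3)
  ids_g <- paste0("g", 1:30); ids_s <- paste0("s", 1:10)
  rg <- random_relation(ids_g, gv, 0.4)
  rs <- random_relation(ids_s, sv, 0.4)
  sbs <- random_semantic_system(2, gv, sv)
  tc <- data.frame(gene = sample(ids_g, 200, TRUE),
                   situation = sample(ids_s, 200, TRUE),
                   label = rbinom(200, 1, 0.5), stringsAsFactors = FALSE)
  roc <- roc_grid(sbs, rg, rs, tc)
  expect_identical(nrow(roc$points), 16L)
  expect_equal(roc$hull$fpr[1], 0)
  expect_equal(utils::tail(roc$hull$fpr, 1), 1)
  expect_true(all(diff(roc$hull$tpr) >= 0))

  one_class <- tc; one_class$label <- 1L
  expect_error(roc_grid(sbs, rg, rs, one_class), "both classes")
})

test_that("grid operating points are monotone in the match thresholds", {
  set.seed(23)
  gv <- paste0("t", 1:5); sv <- paste0("u", 1:5)
  ids_g <- paste0("g", 1:25); ids_s <- paste0("s", 1:12)
  rg <- random_relation(ids_g, gv, 0.5)
  rs <- random_relation(ids_s, sv, 0.5)
  sbs <- random_semantic_system(3, gv, sv, max_terms = 3)
  tc <- data.frame(gene = rep(ids_g, each = 12), situation = rep(ids_s, 25),
                   label = rbinom(300, 1, 0.4), stringsAsFactors = FALSE)
  roc <- roc_grid(sbs, rg, rs, tc, theta_grid_g = c(0.5, 1, 2),
                  theta_grid_s = 1)
  pts <- roc$points[order(roc$points$theta_g), ]
  expect_true(all(diff(pts$fpr) <= 0))
  expect_true(all(diff(pts$tpr) <= 0))
})

test_that("a perfect grid classifier reaches AUROC 1", {
  rg <- rel(gIn = "tA", gOut = character())
  rs <- rel(sIn = "uB", sOut = character())
  sbs <- semantic_bicluster_system(
    semantic_bicluster(weighted_terms("tA"), weighted_terms("uB")))
  tc <- expand.grid(gene = c("gIn", "gOut"), situation = c("sIn", "sOut"),
                    stringsAsFactors = FALSE)
  tc$label <- as.integer(tc$gene == "gIn" & tc$situation == "sIn")
  roc <- roc_grid(sbs, rg, rs, tc, theta_grid_g = 1, theta_grid_s = 1)
  expect_equal(roc$auroc, 1)
})

test_that("confidence sweep reproduces rank statistics and agrees with pROC", {
  tc <- data.frame(gene = paste0("g", 1:4), situation = "s1",
                   label = c(1L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  conf <- c(g1 = 0.9, g2 = 0.8, g3 = 0.4, g4 = 0.2)
  model <- structure(list(conf = conf), class = "fixed_conf")
  roc <- roc_confidence(model, rel(), rel(), tc)
  expect_equal(roc$auroc, 0.75)

  const <- structure(list(conf = c(g1 = 0.5, g2 = 0.5, g3 = 0.5, g4 = 0.5)),
                     class = "fixed_conf")
  expect_equal(roc_confidence(const, rel(), rel(), tc)$auroc, 0.5)

  set.seed(6)
  tc2 <- data.frame(gene = paste0("g", 1:80), situation = "s1",
                    label = rbinom(80, 1, 0.5), stringsAsFactors = FALSE)
  cf <- stats::setNames(runif(80), tc2$gene)
  m2 <- structure(list(conf = cf), class = "fixed_conf")
  ours <- roc_confidence(m2, rel(), rel(), tc2)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(tc2$label, cf, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("per-region evaluation flags degenerate regions as absent", {
  tc <- data.frame(gene = paste0("g", 1:6), situation = "s1",
                   label = c(1L, 0L, 1L, 0L, 1L, 1L),
                   region = c("kG", "kG", "kL", "kL", "bd", "bd"),
                   stringsAsFactors = FALSE)
  cf <- stats::setNames(c(0.9, 0.1, 0.8, 0.2, 0.7, 0.6), tc$gene)
  m <- structure(list(conf = cf), class = "fixed_conf")
  out <- region_auroc(tc, function(cells) roc_confidence(m, rel(), rel(),
                                                         cells))
  expect_equal(out$kG$auroc, 1)
  expect_equal(out$kL$auroc, 1)
  expect_identical(out$bd, NA)      # single-class region
})

test_that("enriched proportion counts bi-directionally enriched biclusters", {
  em <- em_from(matrix(0L, 12, 10))
  rg <- annotation_relation(stats::setNames(
    lapply(1:12, function(i) if (i <= 4) "tA" else character()), genes(em)))
  rs <- annotation_relation(stats::setNames(
    lapply(1:10, function(j) if (j <= 4) "u1" else character()),
    situations(em)))
  sys <- bicluster_system(
    bicluster(paste0("g", 1:4), paste0("s", 1:4)),      # both enriched
    bicluster(paste0("g", 5:8), paste0("s", 5:8)))      # neither
  expect_equal(enriched_proportion(sys, em, rg, rs, alpha = 0.05), 0.5)
  expect_equal(enriched_proportion(sys, em, rg, rs, alpha = 0), 0)
  expect_error(enriched_proportion(bicluster_system(list()), em, rg, rs),
               "at least one")
})

test_that("a label-independent classifier scores near AUROC one half", {
  set.seed(9)
  n <- 4000
  tc <- data.frame(gene = paste0("g", 1:n), situation = "s1",
                   label = rbinom(n, 1, 0.4), stringsAsFactors = FALSE)
  cf <- stats::setNames(runif(n), tc$gene)
  m <- structure(list(conf = cf), class = "fixed_conf")
  expect_lt(abs(roc_confidence(m, rel(), rel(), tc)$auroc - 0.5), 0.05)
})
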