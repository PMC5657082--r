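#' Rectangular train/test split of an expression matrix
#'
#' Randomly retains `round(|G| * sqrt(f))` genes and `round(|S| * sqrt(f))`
#' situations, so that the training submatrix holds about the fraction `f` of
#' the matrix elements with equal per-dimension retention.  All cells outside
#' the training submatrix become labeled test cells, tagged by region:
#' `kG` (train gene x unseen situation), `kL` (unseen gene x train
#' situation) and `bd` (unseen x unseen).
#'
#' @param matrix an `expression_matrix`.
#' @param element_fraction fraction of matrix elements to train on, in (0;1].
#' @param seed integer RNG seed.
#' @return An object of class `evaluation_split` with fields `train`
#'   (`expression_matrix`), `test_cells` (data frame `gene`, `situation`,
#'   `label`, `region`), `train_genes`, `train_situations`,
#'   `element_fraction`, `seed`.
#' @export
split_matrix <- function(matrix, element_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (element_fraction <= 0 || element_fraction > 1)
    stop("`element_fraction` must be in (0;1]")
  g <- genes(matrix); s <- situations(matrix)
  keep_g <- min(length(g), round(length(g) * sqrt(element_fraction)))
  keep_s <- min(length(s), round(length(s) * sqrt(element_fraction)))
  if (keep_g < 1L || keep_s < 1L)
    stop("retention rounds to zero rows or columns")
  set.seed(seed)
  tg <- sort(sample(length(g), keep_g))
  ts <- sort(sample(length(s), keep_s))
  train <- expression_matrix(matrix$values[tg, ts, drop = FALSE])
  in_g <- seq_along(g) %in% tg
  in_s <- seq_along(s) %in% ts
  gi <- rep(seq_along(g), times = length(s))
  si <- rep(seq_along(s), each = length(g))
  outside <- !(in_g[gi] & in_s[si])
  region <- ifelse(in_g[gi[outside]], "kG",
                   ifelse(in_s[si[outside]], "kL", "bd"))
  test_cells <- data.frame(gene = g[gi[outside]],
                           situation = s[si[outside]],
                           label = as.integer(matrix$values[cbind(gi[outside],
                                                                 si[outside])]),
                           region = region, stringsAsFactors = FALSE)
  structure(list(train = train, test_cells = test_cells,
                 train_genes = g[tg], train_situations = s[ts],
                 element_fraction = element_fraction, seed = as.integer(seed)),
            class = "evaluation_split")
}

#' @export
print.evaluation_split <- function(x, ...) {
  cat(sprintf(
    "evaluation_split: train %d x %d; %d test cells (kG %d, kL %d, bd %d)\n",
    nrow(x$train$values), ncol(x$train$values), nrow(x$test_cells),
    sum(x$test_cells$region == "kG"), sum(x$test_cells$region == "kL"),
    sum(x$test_cells$region == "bd")))
  invisible(x)
}

#' Hold-out accuracy of a cell classifier
#'
#' @param classifier function taking (`gene`, `situation`) character vectors
#'   and returning 0/1 calls.
#' @param test_cells data frame with columns `gene`, `situation`, `label`.
#' @return Fraction of test cells classified correctly.
#' @export
test_accuracy <- function(classifier, test_cells) {
  if (nrow(test_cells) == 0L) stop("test set is empty")
  mean(test_cells$label == classifier(test_cells$gene, test_cells$situation))
}

# upper convex hull over ROC points incl. (0,0) and (1,1); returns the hull
# vertices ordered by FPr
.roc_hull <- function(fpr, tpr) {
  x <- c(fpr, 0, 1); y <- c(tpr, 0, 1)
  o <- order(x, -y)
  x <- x[o]; y <- y[o]
  keep <- !duplicated(x)                  # per x keep the highest TPr
  x <- x[keep]; y <- y[keep]
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      k <- length(hx)
      cross <- (hx[k] - hx[k - 1]) * (y[i] - hy[k - 1]) -
        (hy[k] - hy[k - 1]) * (x[i] - hx[k - 1])
      if (cross >= 0) { hx <- hx[-k]; hy <- hy[-k] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  if (hx[1] > 0 || hy[1] > 0) { hx <- c(0, hx); hy <- c(0, hy) }
  data.frame(fpr = hx, tpr = hy)
}

.trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                              utils::tail(y, -1)) / 2)

.rates <- function(calls, labels) {
  pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  c(fpr = sum(calls == 1L & labels == 0L) / neg,
    tpr = sum(calls == 1L & labels == 1L) / pos)
}

#' Threshold-grid ROC of a soft semantic bicluster system
#'
#' Evaluates [soft_classify()] at every pair of gene/situation match
#' thresholds in the grids (default 4 x 4 = 16 binary classifiers), turning
#' each pair into one (FPr, TPr) operating point, and aggregates them by the
#' upper convex hull, whose trapezoid area is the AUROC.
#'
#' @param system a `semantic_bicluster_system`.
#' @param r_gene,r_situation closed annotation relations.
#' @param test_cells data frame with `gene`, `situation`, `label`.
#' @param theta_grid_g,theta_grid_s numeric threshold grids.
#' @return An object of class `roc_result`: `points` (one row per theta
#'   pair: `theta_g`, `theta_s`, `fpr`, `tpr`), `hull`, `auroc` and
#'   `hull_auroc` (identical here).
#' @export
roc_grid <- function(system, r_gene, r_situation, test_cells,
                     theta_grid_g = c(1, 5, 10, 50),
                     theta_grid_s = c(1, 5, 10, 50)) {
  if (length(theta_grid_g) == 0L || length(theta_grid_s) == 0L)
    stop("threshold grids must be non-empty")
  if (nrow(test_cells) == 0L || length(unique(test_cells$label)) < 2L)
    stop("test set must contain both classes")
  grid <- expand.grid(theta_g = theta_grid_g, theta_s = theta_grid_s,
                      KEEP.OUT.ATTRS = FALSE)
  rates <- t(apply(grid, 1L, function(th) {
    calls <- soft_classify(system, test_cells$gene, test_cells$situation,
                           r_gene, r_situation,
                           theta_g = th[["theta_g"]],
                           theta_s = th[["theta_s"]])
    .rates(calls, test_cells$label)
  }))
  points <- cbind(grid, as.data.frame(rates))
  hull <- .roc_hull(points$fpr, points$tpr)
  auc <- .trapezoid(hull$fpr, hull$tpr)
  structure(list(points = points, hull = hull, auroc = auc,
                 hull_auroc = auc), class = "roc_result")
}

#' Confidence-sweep ROC of a rule list or decision tree
#'
#' Sweeps the decision threshold over all distinct predicted confidences
#' (ties grouped), yielding the standard ranked ROC curve; `auroc` is its
#' plain trapezoid area and `hull_auroc` the area under its convex hull.
#'
#' @param model a `rule_list` or `decision_tree`.
#' @param r_gene,r_situation closed annotation relations.
#' @param test_cells data frame with `gene`, `situation`, `label`.
#' @return An object of class `roc_result` with `points` (`threshold`,
#'   `fpr`, `tpr`), `hull`, `auroc`, `hull_auroc`.
#' @export
roc_confidence <- function(model, r_gene, r_situation, test_cells) {
  if (nrow(test_cells) == 0L || length(unique(test_cells$label)) < 2L)
    stop("test set must contain both classes")
  conf <- predict_confidence(model, test_cells$gene, test_cells$situation,
                             r_gene, r_situation)
  labels <- test_cells$label
  o <- order(conf, decreasing = TRUE)
  conf_o <- conf[o]; lab_o <- labels[o]
  pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  last <- !duplicated(conf_o, fromLast = TRUE)      # group confidence ties
  tp <- cumsum(lab_o == 1L)[last]
  fp <- cumsum(lab_o == 0L)[last]
  points <- data.frame(threshold = c(Inf, conf_o[last]),
                       fpr = c(0, fp / neg), tpr = c(0, tp / pos))
  auc <- .trapezoid(points$fpr, points$tpr)
  hull <- .roc_hull(points$fpr, points$tpr)
  structure(list(points = points, hull = hull, auroc = auc,
                 hull_auroc = .trapezoid(hull$fpr, hull$tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d operating point(s), AUROC %.4f (hull %.4f)\n",
              nrow(x$points), x$auroc, x$hull_auroc))
  invisible(x)
}

#' Per-region ROC analysis
#'
#' Applies a ROC constructor separately to each test region (`kG`: seen
#' genes, unseen situations; `kL`: unseen genes, seen situations; `bd`: both
#' unseen).  Regions that are empty or single-class cannot carry a ROC curve
#' and are reported as `NA` rather than raising an error.
#'
#' @param test_cells data frame with `gene`, `situation`, `label`, `region`.
#' @param roc_fun function mapping a test-cell data frame to a `roc_result`
#'   (e.g. a closure around [roc_grid()] or [roc_confidence()]).
#' @return A list with entries `kG`, `kL`, `bd`, each a `roc_result` or `NA`.
#' @export
region_auroc <- function(test_cells, roc_fun) {
  out <- lapply(c(kG = "kG", kL = "kL", bd = "bd"), function(r) {
    cells <- test_cells[test_cells$region == r, , drop = FALSE]
    if (nrow(cells) == 0L || length(unique(cells$label)) < 2L) return(NA)
    roc_fun(cells)
  })
  out
}

#' Proportion of biclusters enriched in both dimensions
#'
#' The fraction of biclusters carrying at least one annotation term enriched
#' at significance level `alpha` in each dimension, a measure of the
#' biological homogeneity of a bicluster system.
#'
#' @param system a `bicluster_system` (non-empty).
#' @param matrix the host `expression_matrix`.
#' @param r_gene,r_situation closed annotation relations.
#' @param alpha significance level.
#' @return A fraction in \[0;1\].
#' @export
enriched_proportion <- function(system, matrix, r_gene, r_situation,
                                alpha = 0.05) {
  if (length(system) == 0L) stop("system must contain at least one bicluster")
  g_bg <- relation_terms(r_gene, genes(matrix))
  s_bg <- relation_terms(r_situation, situations(matrix))
  both <- vapply(system, function(bc) {
    gp <- .dimension_enrichment(match(bc$genes, genes(matrix)), g_bg)$p_value
    sp <- .dimension_enrichment(match(bc$situations, situations(matrix)),
                                s_bg)$p_value
    any(gp <= alpha) && any(sp <= alpha)
  }, logical(1))
  mean(both)
}
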