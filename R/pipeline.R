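#' End-to-end semantic biclustering pipeline
#'
#' Splits the matrix rectangularly, learns semantic biclusters on the
#' training submatrix with the chosen strategy, and evaluates the resulting
#' classifier on the held-out cells, overall and per region.
#'
#' Strategies: `"enrich"` runs the greedy bicluster search (with `rho`
#' selected unsupervised over `candidate_rhos` when not given) followed by
#' bi-directional enrichment, producing soft semantic biclusters evaluated on
#' a grid of match thresholds; `"rules"` and `"tree"` unroll the training
#' matrix into one instance per cell, select features by frequency, learn a
#' rule list or decision tree, and are evaluated by a confidence sweep.
#'
#' @param matrix an `expression_matrix`.
#' @param r_gene,r_situation raw (leaf-level) annotation relations.
#' @param gene_ontology,situation_ontology [ontology()] objects; annotations
#'   are transitively closed over them before use.
#' @param strategy `"enrich"`, `"rules"` or `"tree"`.
#' @param element_fraction training fraction of matrix elements.
#' @param seed integer seed driving the split and all stochastic stages.
#' @param rho greedy-search noise parameter; `NULL` selects it from
#'   `candidate_rhos` by minimal training cost.
#' @param candidate_rhos candidates for the unsupervised `rho` choice.
#' @param max_biclusters cap on extracted biclusters.
#' @param alpha_g,alpha_s fixed enrichment thresholds, used only when
#'   `permute = NULL`.
#' @param permute `"auto"` (default) calibrates both thresholds by
#'   [permutation_alpha()] with 100 permutations at FDR 0.05; a list
#'   (`n_perms`, `target_fdr`, `seed`) customizes the calibration; `NULL`
#'   uses the fixed `alpha_g`/`alpha_s`.
#' @param theta_grid_g,theta_grid_s match-threshold grids for the soft
#'   classifier ROC.
#' @param min_fraction feature-selection threshold for the learners.
#' @return A list of class `pipeline_result`: `strategy`, `split`, `model`
#'   (an `enrichment_result`, `rule_list` or `decision_tree`), `system` (the
#'   semantic bicluster system), `ordinary` (the induced ordinary system on
#'   the training matrix), `training_accuracy`, `roc`, `regions`, `params`.
#' @export
run_pipeline <- function(matrix, r_gene, r_situation,
                         gene_ontology, situation_ontology,
                         strategy = c("enrich", "rules", "tree"),
                         element_fraction = 0.7, seed = 1L,
                         rho = NULL, candidate_rhos = c(0.5, 1, 2),
                         max_biclusters = 50L,
                         alpha_g = 0.05, alpha_s = 0.1, permute = "auto",
                         theta_grid_g = c(1, 5, 10, 50),
                         theta_grid_s = c(1, 5, 10, 50),
                         min_fraction = 0.001) {
  strategy <- match.arg(strategy)
  cg <- annotation_closure(r_gene, gene_ontology)
  cs <- annotation_closure(r_situation, situation_ontology)
  split <- split_matrix(matrix, element_fraction, seed = seed)
  train <- split$train
  model <- NULL
  if (strategy == "enrich") {
    cfg <- search_config(rho = 1, max_biclusters = max_biclusters,
                         seed = seed)
    if (is.null(rho)) rho <- select_rho(train, candidate_rhos, cfg)
    cfg$rho <- rho
    if (identical(permute, "auto"))
      permute <- list(n_perms = 100L, target_fdr = 0.05, seed = seed)
    found <- greedy_bicluster(train, cfg)
    model <- annotate_system(found, train, cg, cs,
                             alpha_g = alpha_g, alpha_s = alpha_s,
                             permute = permute)
    system <- model$system
    roc_fun <- function(cells)
      roc_grid(system, cg, cs, cells, theta_grid_g, theta_grid_s)
  } else {
    data <- unroll(train, cg, cs,
                   gene_vocab = gene_ontology$terms$id,
                   situation_vocab = situation_ontology$terms$id)
    data <- select_features(data, min_fraction)
    model <- if (strategy == "rules") learn_rules(data, seed = seed)
             else learn_tree(data, seed = seed)
    rules <- if (strategy == "rules") model else tree_to_rules(model)
    system <- rules_to_semantic_biclusters(rules)
    roc_fun <- function(cells) roc_confidence(model, cg, cs, cells)
  }
  ordinary <- bicluster_system(lapply(system, induce_bicluster,
                                      genes = genes(train),
                                      situations = situations(train),
                                      r_gene = cg, r_situation = cs))
  tacc <- training_accuracy(ordinary, train)
  roc <- if (nrow(split$test_cells) > 0 &&
             length(unique(split$test_cells$label)) > 1L)
    roc_fun(split$test_cells) else NA
  regions <- if (nrow(split$test_cells) > 0)
    region_auroc(split$test_cells, roc_fun) else
      list(kG = NA, kL = NA, bd = NA)
  structure(list(strategy = strategy, split = split, model = model,
                 system = system, ordinary = ordinary,
                 training_accuracy = tacc, roc = roc, regions = regions,
                 closed_gene = cg, closed_situation = cs,
                 params = list(element_fraction = element_fraction,
                               seed = seed, rho = rho,
                               alpha_g = alpha_g, alpha_s = alpha_s,
                               theta_grid_g = theta_grid_g,
                               theta_grid_s = theta_grid_s,
                               min_fraction = min_fraction,
                               max_biclusters = max_biclusters)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  auc <- if (inherits(x$roc, "roc_result")) x$roc$hull_auroc else NA
  cat(sprintf(
    "pipeline_result (%s): %d semantic bicluster(s), train acc %.3f, hull AUROC %s\n",
    x$strategy, length(x$system), x$training_accuracy,
    ifelse(is.na(auc), "NA", sprintf("%.3f", auc))))
  invisible(x)
}

.wts_json <- function(wts) {
  lapply(seq_len(nrow(wts)), function(i)
    list(term = wts$term[i], weight = wts$weight[i],
         negated = wts$sign[i] < 0L))
}

#' JSON report of a semantic bicluster system
#'
#' Writes per-bicluster gene/situation term lists with weights (and p-values
#' when an `enrichment_result` is given) plus the row/column identifiers each
#' bicluster induces on the supplied matrix.
#'
#' @param system a `semantic_bicluster_system`, or an `enrichment_result`.
#' @param matrix the host `expression_matrix`.
#' @param r_gene,r_situation closed annotation relations.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_bicluster_report <- function(system, matrix, r_gene, r_situation,
                                   path) {
  enr <- NULL
  if (inherits(system, "enrichment_result")) { enr <- system
                                               system <- system$system }
  report <- list(
    n_biclusters = length(system),
    alpha_g = if (is.null(enr)) NULL else enr$alpha_g,
    alpha_s = if (is.null(enr)) NULL else enr$alpha_s,
    biclusters = lapply(seq_along(system), function(k) {
      sb <- system[[k]]
      bc <- induce_bicluster(sb, genes(matrix), situations(matrix),
                             r_gene, r_situation)
      pv <- NULL
      if (!is.null(enr)) {
        tab <- enr$table[enr$table$bicluster == enr$source_index[k] &
                           enr$table$kept, , drop = FALSE]
        pv <- lapply(seq_len(nrow(tab)), function(i)
          list(term = tab$term[i], dimension = tab$dimension[i],
               p_value = tab$p_value[i]))
      }
      list(gene_terms = .wts_json(sb$gene_terms),
           situation_terms = .wts_json(sb$situation_terms),
           p_values = pv,
           induced_genes = bc$genes, induced_situations = bc$situations)
    }))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.roc_json <- function(roc) {
  if (!inherits(roc, "roc_result")) return(NULL)
  list(auroc = roc$auroc, hull_auroc = roc$hull_auroc,
       points = roc$points, hull = roc$hull)
}

#' JSON report of a pipeline evaluation
#'
#' Overall and per-region AUROC with operating points, the split seed and
#' region sizes, and the run parameters.
#'
#' @param result a `pipeline_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  tc <- result$split$test_cells
  report <- list(
    strategy = result$strategy,
    seed = result$params$seed,
    params = result$params,
    train_genes = length(result$split$train_genes),
    train_situations = length(result$split$train_situations),
    region_sizes = as.list(table(tc$region)),
    n_biclusters = length(result$system),
    training_accuracy = result$training_accuracy,
    roc = .roc_json(result$roc),
    regions = lapply(result$regions, .roc_json))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
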