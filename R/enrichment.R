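#' Ontology term hierarchy
#'
#' A minimal ontology: term identifiers with names and directed child-to-
#' parent edges typed `is_a`, `part_of` or `develops_from`.  The edge graph
#' must be acyclic; all three edge types are treated as transitive for
#' annotation propagation.
#'
#' @param terms data frame with columns `id` and `name` (or a character
#'   vector of ids, used as their own names).
#' @param edges data frame with columns `child`, `parent`, `type`; may have
#'   zero rows.
#' @return An object of class `ontology` with fields `terms` and `edges`.
#' @export
ontology <- function(terms, edges = NULL) {
  if (is.character(terms))
    terms <- data.frame(id = terms, name = terms, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicated term ids")
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(child = character(), parent = character(),
                        type = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "type") %in% names(edges)))
  bad <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(bad) > 0)
    stop(sprintf("edge endpoint(s) not declared as terms: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (!all(edges$type %in% c("is_a", "part_of", "develops_from")))
    stop("edge types must be is_a, part_of or develops_from")
  onto <- structure(list(terms = terms[, c("id", "name")], edges = edges),
                    class = "ontology")
  if (nrow(edges) > 0L && !igraph::is_dag(.onto_graph(onto)))
    stop("ontology edges must form an acyclic graph")
  onto
}

.onto_graph <- function(onto) {
  igraph::graph_from_data_frame(
    onto$edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = onto$terms$id))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Ancestors of every ontology term
#'
#' @param onto an `ontology`.
#' @return Named list: for each term id, the character vector of its proper
#'   ancestors (following edges of any type to the roots).
#' @export
term_ancestors <- function(onto) {
  g <- .onto_graph(onto)
  ids <- onto$terms$id
  out <- lapply(ids, function(t)
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t))
  names(out) <- ids
  out
}

#' Leaf terms of an ontology
#' @param onto an `ontology`.
#' @return Character vector of terms that are no edge's parent.
#' @export
term_leaves <- function(onto) setdiff(onto$terms$id, onto$edges$parent)

#' Transitive closure of an annotation relation over an ontology
#'
#' Propagates every annotation up the hierarchy: an entity annotated with a
#' term is implicitly annotated with all of the term's ancestors.  All edge
#' types are treated as transitive.  The operation is idempotent.
#'
#' @param relation an `annotation_relation`.
#' @param onto the `ontology` supplying the hierarchy; every annotated term
#'   must be declared in it.
#' @return A closed `annotation_relation`.
#' @export
annotation_closure <- function(relation, onto) {
  stopifnot(inherits(relation, "annotation_relation"),
            inherits(onto, "ontology"))
  used <- unique(unlist(relation, use.names = FALSE))
  check_known_ids(used, onto$terms$id, "term")
  anc <- term_ancestors(onto)
  annotation_relation(lapply(unclass(relation), function(tt)
    unique(c(tt, unlist(anc[tt], use.names = FALSE)))))
}

#' One-sided hypergeometric enrichment p-value
#'
#' Over-representation test of one term in a set of entities against a
#' background: with `N` background entities of which `K` carry the term, and
#' `n` selected entities of which `k` carry it, returns
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param in_set character vector of selected entity ids (subset of
#'   `background`).
#' @param background character vector of background entity ids.
#' @param term a term id.
#' @param relation `annotation_relation` (normally closed).
#' @return p-value in \[0;1\].
#' @export
term_enrichment_p <- function(in_set, background, term, relation) {
  if (length(background) == 0L) stop("background must be non-empty")
  if (length(setdiff(in_set, background)) > 0)
    stop("`in_set` must be contained in `background`")
  tsets <- relation_terms(relation, background)
  has <- vapply(tsets, function(tt) term %in% tt, logical(1))
  K <- sum(has)
  k <- sum(has[match(in_set, background)])
  stats::phyper(k - 1, K, length(background) - K, length(in_set),
                lower.tail = FALSE)
}

# p-values for every term annotating at least one in-set entity.
# bg_sets: precomputed relation_terms(relation, background).
.dimension_enrichment <- function(in_idx, bg_sets) {
  N <- length(bg_sets)
  n <- length(in_idx)
  bg_counts <- table(unlist(bg_sets, use.names = FALSE))
  in_counts <- table(unlist(bg_sets[in_idx], use.names = FALSE))
  if (length(in_counts) == 0L)
    return(data.frame(term = character(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  terms <- names(in_counts)
  K <- as.integer(bg_counts[terms])
  k <- as.integer(in_counts)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms, p_value = p, stringsAsFactors = FALSE)
}

#' Bi-directional enrichment of one bicluster
#'
#' Tests every gene-side term annotating at least one of the bicluster's
#' genes for over-representation against all the matrix's genes, and
#' analogously on the situation side.  Terms passing the significance
#' threshold are retained with weight `max(1e-6, 1 - p)`, so that more
#' significant terms weigh more and all weights stay in (0;1].
#'
#' Trivial biclusters (at most one gene or one situation) cannot be
#' meaningfully enriched and yield `NULL` (a skip signal, not an error).
#'
#' @param bc a `bicluster`.
#' @param matrix the host `expression_matrix` (defines the backgrounds).
#' @param r_gene,r_situation closed annotation relations.
#' @param alpha_g,alpha_s per-dimension significance thresholds.
#' @return A `semantic_bicluster` whose attribute `"enrichment"` holds the
#'   per-dimension candidate-term tables (columns `term`, `p_value`,
#'   `weight`, `kept`), or `NULL` for a trivial bicluster.
#' @export
annotate_bicluster <- function(bc, matrix, r_gene, r_situation,
                               alpha_g = 0.05, alpha_s = 0.1) {
  stopifnot(inherits(bc, "bicluster"), inherits(matrix, "expression_matrix"))
  if (length(bc$genes) <= 1L || length(bc$situations) <= 1L) return(NULL)
  g_bg <- relation_terms(r_gene, genes(matrix))
  s_bg <- relation_terms(r_situation, situations(matrix))
  gt <- .dimension_enrichment(match(bc$genes, genes(matrix)), g_bg)
  st <- .dimension_enrichment(match(bc$situations, situations(matrix)), s_bg)
  gt$weight <- pmax(1e-6, 1 - gt$p_value)
  st$weight <- pmax(1e-6, 1 - st$p_value)
  gt$kept <- gt$p_value <= alpha_g
  st$kept <- st$p_value <= alpha_s
  sb <- semantic_bicluster(
    weighted_terms(gt$term[gt$kept], gt$weight[gt$kept]),
    weighted_terms(st$term[st$kept], st$weight[st$kept]))
  attr(sb, "enrichment") <- list(gene = gt, situation = st)
  sb
}

#' Permutation-calibrated significance threshold
#'
#' Chooses a per-dimension enrichment threshold `alpha` without fixing it by
#' hand: entity-to-annotation assignments on the tested dimension are
#' shuffled `n_perms` times, all bicluster term p-values are recomputed on
#' the identical index sets, and the estimated false discovery rate of a
#' candidate threshold is the mean permuted count of p-values at or below it
#' divided by the real count.  The largest candidate (over the sorted real
#' p-values) with estimated FDR at most `target_fdr` is returned, or 0 when
#' no candidate qualifies (no term passes).
#'
#' @param matrix the host `expression_matrix`.
#' @param system a non-empty `bicluster_system`.
#' @param relation closed `annotation_relation` of the tested dimension.
#' @param dimension `"gene"` or `"situation"`.
#' @param n_perms number of permutations (>= 1).
#' @param target_fdr acceptable false discovery rate, in (0;1).
#' @param seed integer RNG seed.
#' @return A single number: the calibrated `alpha`.
#' @export
permutation_alpha <- function(matrix, system, relation,
                              dimension = c("gene", "situation"),
                              n_perms = 100L, target_fdr = 0.05, seed = 1L) {
  dimension <- match.arg(dimension)
  if (length(system) == 0L) stop("system must contain at least one bicluster")
  if (n_perms < 1L) stop("`n_perms` must be >= 1")
  if (target_fdr <= 0 || target_fdr >= 1) stop("`target_fdr` must be in (0;1)")
  entities <- if (dimension == "gene") genes(matrix) else situations(matrix)
  idx_sets <- lapply(system, function(bc) {
    ids <- if (dimension == "gene") bc$genes else bc$situations
    if (length(bc$genes) <= 1L || length(bc$situations) <= 1L) return(NULL)
    match(ids, entities)
  })
  idx_sets <- Filter(Negate(is.null), idx_sets)
  if (length(idx_sets) == 0L) return(0)
  bg_sets <- relation_terms(relation, entities)
  all_p <- function(sets) unlist(lapply(idx_sets, function(ii)
    .dimension_enrichment(ii, sets)$p_value), use.names = FALSE)
  real_p <- all_p(bg_sets)
  if (length(real_p) == 0L) return(0)
  perm_p <- local({
    set.seed(seed)
    lapply(seq_len(n_perms), function(i) {
      shuffled <- bg_sets[sample.int(length(bg_sets))]
      names(shuffled) <- entities
      all_p(shuffled)
    })
  })
  candidates <- sort(unique(real_p))
  fdr <- vapply(candidates, function(a) {
    r <- sum(real_p <= a)
    v <- mean(vapply(perm_p, function(p) sum(p <= a), numeric(1)))
    v / r
  }, numeric(1))
  ok <- fdr <= target_fdr
  if (!any(ok)) 0 else max(candidates[ok])
}

#' Bi-directional enrichment of a whole bicluster system
#'
#' Applies [annotate_bicluster()] to every non-trivial bicluster of the
#' system.  Per-dimension thresholds are either given explicitly or
#' calibrated by [permutation_alpha()].  Biclusters yielding no significant
#' term on either side are dropped; a single empty side is allowed (the
#' bicluster is then described solely by the other dimension's terms and
#' induces all entities on the empty side).
#'
#' @param system a `bicluster_system`.
#' @param matrix the host `expression_matrix`.
#' @param r_gene,r_situation closed annotation relations.
#' @param alpha_g,alpha_s significance thresholds; ignored when `permute`
#'   is supplied.
#' @param permute `NULL`, or a list with elements `n_perms`, `target_fdr`
#'   and `seed` requesting permutation calibration of both thresholds.
#' @return A list of class `enrichment_result` with fields `system` (the
#'   `semantic_bicluster_system`), `table` (per bicluster/dimension/term:
#'   `p_value`, `weight`, `kept`), `alpha_g`, `alpha_s` and `source_index`
#'   (which input bicluster each semantic bicluster came from).
#' @export
annotate_system <- function(system, matrix, r_gene, r_situation,
                            alpha_g = 0.05, alpha_s = 0.1, permute = NULL) {
  stopifnot(inherits(system, "bicluster_system"))
  if (!is.null(permute)) {
    alpha_g <- permutation_alpha(matrix, system, r_gene, "gene",
                                 n_perms = permute$n_perms,
                                 target_fdr = permute$target_fdr,
                                 seed = permute$seed)
    alpha_s <- permutation_alpha(matrix, system, r_situation, "situation",
                                 n_perms = permute$n_perms,
                                 target_fdr = permute$target_fdr,
                                 seed = permute$seed + 1L)
  }
  sbs <- list(); rows <- list(); src <- integer()
  for (i in seq_along(system)) {
    sb <- annotate_bicluster(system[[i]], matrix, r_gene, r_situation,
                             alpha_g = alpha_g, alpha_s = alpha_s)
    if (is.null(sb)) next
    enr <- attr(sb, "enrichment")
    for (dim_name in c("gene", "situation")) {
      tab <- enr[[dim_name]]
      if (nrow(tab) > 0)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(bicluster = i, dimension = dim_name,
                           stringsAsFactors = FALSE), tab)
    }
    if (nrow(sb$gene_terms) == 0L && nrow(sb$situation_terms) == 0L) next
    attr(sb, "enrichment") <- NULL
    sbs[[length(sbs) + 1L]] <- sb
    src <- c(src, i)
  }
  table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(bicluster = integer(), dimension = character(),
               term = character(), p_value = numeric(), weight = numeric(),
               kept = logical(), stringsAsFactors = FALSE)
  structure(list(system = semantic_bicluster_system(sbs), table = table,
                 alpha_g = alpha_g, alpha_s = alpha_s, source_index = src),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d semantic bicluster(s), alpha_g=%.4g alpha_s=%.4g\n",
    length(x$system), x$alpha_g, x$alpha_s))
  invisible(x)
}
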