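#' Binary expression matrix
#'
#' Wraps a binary (0/1) matrix whose rows are genes and whose columns are
#' situations (samples, locations, developmental stages...).  Row and column
#' identifiers are opaque strings and must be unique.
#'
#' @param values matrix (numeric, integer or logical) with every cell 0 or 1.
#' @param gene_ids,situation_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return An object of class `expression_matrix` with fields `values`
#'   (integer matrix with dimnames), and accessors [genes()] and
#'   [situations()].
#' @export
expression_matrix <- function(values, gene_ids = NULL, situation_ids = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values == 0L | values == 1L))
    stop("expression matrix cells must all be 0 or 1")
  storage.mode(values) <- "integer"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(situation_ids)) colnames(values) <- situation_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene and situation identifiers are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicated situation identifiers")
  structure(list(values = values), class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_matrix: %d genes x %d situations, %.1f%% positive\n",
              d[1], d[2], 100 * mean(x$values)))
  invisible(x)
}

#' Gene and situation identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname genes
#' @export
situations <- function(x) colnames(x$values)

#' Ordinary bicluster
#'
#' A bicluster is a submatrix given extensionally by a subset of genes (rows)
#' and a subset of situations (columns).  Either set may be empty, giving a
#' degenerate bicluster with empty extension.
#'
#' @param genes,situations character vectors of identifiers.
#' @return An object of class `bicluster`.
#' @export
bicluster <- function(genes = character(), situations = character()) {
  genes <- as.character(genes); situations <- as.character(situations)
  if (anyDuplicated(genes) || anyDuplicated(situations))
    stop("bicluster gene/situation sets must not contain duplicates")
  structure(list(genes = genes, situations = situations), class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d genes x %d situations\n",
              length(x$genes), length(x$situations)))
  invisible(x)
}

#' System of ordinary biclusters
#'
#' @param ... `bicluster` objects, or a single list of them.
#' @return An object of class `bicluster_system` (a list of biclusters).
#' @export
bicluster_system <- function(...) {
  bcs <- list(...)
  if (length(bcs) == 1L && !inherits(bcs[[1L]], "bicluster")) bcs <- bcs[[1L]]
  ok <- vapply(bcs, inherits, logical(1), what = "bicluster")
  if (!all(ok)) stop("all elements must be bicluster objects")
  structure(bcs, class = "bicluster_system")
}

#' @export
print.bicluster_system <- function(x, ...) {
  cat(sprintf("bicluster_system of %d bicluster(s)\n", length(x)))
  invisible(x)
}

#' Weighted (optionally signed) ontology term set
#'
#' One side of a semantic bicluster: a set of ontology terms, each carrying a
#' weight in (0;1].  Crisp biclusters use weight 1 throughout.  Terms may be
#' negated (`sign = -1`), which is the language of decision-tree paths: a
#' negated term matches an entity when the term is absent from its (closed)
#' annotation, and its weight counts towards the matched sum in that case.
#'
#' @param term character vector of term identifiers (unique).
#' @param weight numeric weights in (0;1], recycled.
#' @param sign +1 (presence literal) or -1 (absence literal), recycled.
#' @return A data frame of class `weighted_terms` with columns `term`,
#'   `weight`, `sign`.
#' @export
weighted_terms <- function(term = character(), weight = 1, sign = 1L) {
  term <- as.character(term)
  n <- length(term)
  weight <- rep_len(as.numeric(weight), n)
  sign <- rep_len(as.integer(sign), n)
  if (anyDuplicated(term)) stop("term ids must be unique within a term set")
  if (n > 0 && (any(weight <= 0) || any(weight > 1)))
    stop("weights must lie in (0;1]")
  if (n > 0 && !all(sign %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  structure(data.frame(term = term, weight = weight, sign = sign,
                       stringsAsFactors = FALSE),
            class = c("weighted_terms", "data.frame"))
}

#' Semantic bicluster
#'
#' A bicluster described intensionally: a conjunction of gene-side terms and
#' a conjunction of situation-side terms.  On any gene/situation universe it
#' induces the ordinary bicluster of entities complying with all terms of the
#' respective side; an empty side is a vacuous conjunction and induces all
#' entities of that dimension.
#'
#' @param gene_terms,situation_terms `weighted_terms` objects.
#' @return An object of class `semantic_bicluster`.
#' @export
semantic_bicluster <- function(gene_terms = weighted_terms(),
                               situation_terms = weighted_terms()) {
  stopifnot(inherits(gene_terms, "weighted_terms"),
            inherits(situation_terms, "weighted_terms"))
  structure(list(gene_terms = gene_terms, situation_terms = situation_terms),
            class = "semantic_bicluster")
}

#' @export
print.semantic_bicluster <- function(x, ...) {
  cat(sprintf("semantic_bicluster: %d gene term(s), %d situation term(s)\n",
              nrow(x$gene_terms), nrow(x$situation_terms)))
  invisible(x)
}

#' System of semantic biclusters
#'
#' @param ... `semantic_bicluster` objects, or one list of them.
#' @return An object of class `semantic_bicluster_system`.
#' @export
semantic_bicluster_system <- function(...) {
  bcs <- list(...)
  if (length(bcs) == 1L && !inherits(bcs[[1L]], "semantic_bicluster"))
    bcs <- bcs[[1L]]
  ok <- vapply(bcs, inherits, logical(1), what = "semantic_bicluster")
  if (!all(ok)) stop("all elements must be semantic_bicluster objects")
  structure(bcs, class = "semantic_bicluster_system")
}

#' @export
print.semantic_bicluster_system <- function(x, ...) {
  cat(sprintf("semantic_bicluster_system of %d bicluster(s)\n", length(x)))
  invisible(x)
}

#' Entity-to-term annotation relation
#'
#' A named list mapping entity identifiers (genes or situations) to character
#' vectors of ontology term identifiers.  Entities missing from the relation
#' are treated as annotated with no terms.
#'
#' @param x named list of character vectors.
#' @return An object of class `annotation_relation`.
#' @export
annotation_relation <- function(x = list()) {
  if (length(x) > 0 && (is.null(names(x)) || any(names(x) == "")))
    stop("annotation relation must be a named list")
  if (anyDuplicated(names(x))) stop("duplicated entity ids in relation")
  x <- lapply(x, function(v) unique(as.character(v)))
  structure(x, class = "annotation_relation")
}

#' @export
print.annotation_relation <- function(x, ...) {
  cat(sprintf("annotation_relation: %d entities, %d term(s) used\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

# term sets for a vector of entity ids; missing entities -> character(0)
relation_terms <- function(relation, ids) {
  out <- unclass(relation)[ids]
  names(out) <- ids
  out[vapply(out, is.null, logical(1))] <- list(character())
  out
}

check_known_ids <- function(ids, universe, what) {
  bad <- setdiff(ids, universe)
  if (length(bad) > 0)
    stop(sprintf("unknown %s identifier(s): %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")))
}

#' Extension of an ordinary bicluster system
#'
#' The extension is the union, over the system's biclusters, of the Cartesian
#' products genes x situations: the set of all matrix cells covered by at
#' least one bicluster.
#'
#' @param system a `bicluster_system`.
#' @param matrix an `expression_matrix` hosting the system.
#' @return A data frame with character columns `gene` and `situation`, one
#'   row per covered cell (no duplicates), ordered by gene then situation.
#' @export
bicluster_extension <- function(system, matrix) {
  stopifnot(inherits(system, "bicluster_system"),
            inherits(matrix, "expression_matrix"))
  ind <- extension_indicator(system, matrix)
  w <- which(ind, arr.ind = TRUE)
  out <- data.frame(gene = rownames(ind)[w[, 1L]],
                    situation = colnames(ind)[w[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$situation), , drop = FALSE]
}

#' Coverage indicator of a bicluster system
#'
#' @inheritParams bicluster_extension
#' @return A logical matrix of the host matrix's shape, TRUE on covered cells.
#' @export
extension_indicator <- function(system, matrix) {
  stopifnot(inherits(system, "bicluster_system"),
            inherits(matrix, "expression_matrix"))
  g <- genes(matrix); s <- situations(matrix)
  ind <- base::matrix(FALSE, length(g), length(s), dimnames = list(g, s))
  for (bc in system) {
    check_known_ids(bc$genes, g, "gene")
    check_known_ids(bc$situations, s, "situation")
    ind[bc$genes, bc$situations] <- TRUE
  }
  ind
}

#' Training (in-sample) accuracy of a bicluster system
#'
#' Treats the system's coverage indicator as a binary classifier of matrix
#' cells and scores it against the observed 0/1 values: the fraction of cells
#' that are 1 inside the extension or 0 outside it.
#'
#' @inheritParams bicluster_extension
#' @return A number in \[0;1\].
#' @export
training_accuracy <- function(system, matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (any(dim(matrix) == 0L)) stop("matrix must have at least one cell")
  ind <- extension_indicator(system, matrix)
  mean((matrix$values == 1L) == ind)
}

#' Regularized bicluster-system score
#'
#' Training accuracy plus `lambda / |B|`, rewarding systems that reach their
#' accuracy with few biclusters and thereby discouraging the trivial solution
#' of one single-cell bicluster per 1 in the matrix.
#'
#' @inheritParams bicluster_extension
#' @param lambda non-negative trade-off between accuracy and system size.
#' @return A number.
#' @export
regularized_score <- function(system, matrix, lambda = 0) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  acc <- training_accuracy(system, matrix)
  if (lambda == 0) return(acc)
  if (length(system) == 0L)
    stop("regularizer lambda/|B| is undefined for an empty system")
  acc + lambda / length(system)
}

# matched weight sums of one weighted term set against entity term sets.
# term_sets: list of character vectors (closed annotations), one per entity.
matched_weights <- function(wts, term_sets) {
  if (nrow(wts) == 0L) return(rep(0, length(term_sets)))
  vapply(term_sets, function(tt) {
    present <- wts$term %in% tt
    sum(wts$weight[(wts$sign > 0L & present) | (wts$sign < 0L & !present)])
  }, numeric(1))
}

# entities complying with ALL literals of a term set (vacuously all if empty)
comply_all <- function(wts, ids, relation) {
  if (nrow(wts) == 0L) return(ids)
  tsets <- relation_terms(relation, ids)
  keep <- vapply(tsets, function(tt) {
    present <- wts$term %in% tt
    all(present == (wts$sign > 0L))
  }, logical(1))
  ids[keep]
}

#' Ordinary bicluster induced by a semantic bicluster
#'
#' On a universe of gene and situation identifiers, a semantic bicluster
#' induces the ordinary bicluster of exactly those genes complying with all
#' its gene-side literals and situations complying with all its
#' situation-side literals.  An empty term set is a vacuous conjunction and
#' selects the whole universe on its side.
#'
#' @param sb a `semantic_bicluster`.
#' @param genes,situations character vectors: the entity universes.
#' @param r_gene,r_situation `annotation_relation`s for the two dimensions
#'   (normally transitively closed over the ontology, see
#'   [annotation_closure()]).
#' @return A `bicluster`.
#' @export
induce_bicluster <- function(sb, genes, situations, r_gene, r_situation) {
  stopifnot(inherits(sb, "semantic_bicluster"))
  bicluster(comply_all(sb$gene_terms, genes, r_gene),
            comply_all(sb$situation_terms, situations, r_situation))
}

#' Extension of a semantic bicluster system
#'
#' Unlike an ordinary system, a semantic system is not confined to the matrix
#' it was learned on: its extension on any gene/situation universe is the
#' union over biclusters of the induced gene set x induced situation set.
#' Restricted to the training universe it coincides with the extension of the
#' induced ordinary system.
#'
#' @param system a `semantic_bicluster_system`.
#' @inheritParams induce_bicluster
#' @return A data frame with columns `gene` and `situation` (unique rows).
#' @export
semantic_extension <- function(system, genes, situations, r_gene, r_situation) {
  stopifnot(inherits(system, "semantic_bicluster_system"))
  ind <- base::matrix(FALSE, length(genes), length(situations),
                      dimnames = list(genes, situations))
  for (sb in system) {
    bc <- induce_bicluster(sb, genes, situations, r_gene, r_situation)
    ind[bc$genes, bc$situations] <- TRUE
  }
  w <- which(ind, arr.ind = TRUE)
  out <- data.frame(gene = genes[w[, 1L]], situation = situations[w[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$situation), , drop = FALSE]
}

#' Soft semantic classification of (gene, situation) pairs
#'
#' A pair is classified positive when at least one semantic bicluster
#' supports it: the weights of the bicluster's gene-side literals matched by
#' the gene's annotation sum to at least `theta_g`, and likewise the
#' situation-side matched weights reach `theta_s`.  With crisp (weight-1)
#' systems and thresholds equal to the term-set sizes this reduces to the
#' conjunctive induced-bicluster semantics.
#'
#' @param system a `semantic_bicluster_system`.
#' @param gene,situation character vectors of equal length (recycled): the
#'   pairs to classify.
#' @param r_gene,r_situation annotation relations (closed).
#' @param theta_g,theta_s real match thresholds.
#' @return Integer vector of 0/1 calls, one per pair.
#' @export
soft_classify <- function(system, gene, situation, r_gene, r_situation,
                          theta_g = 1, theta_s = 1) {
  stopifnot(inherits(system, "semantic_bicluster_system"),
            is.finite(theta_g), is.finite(theta_s))
  n <- max(length(gene), length(situation))
  gene <- rep_len(as.character(gene), n)
  situation <- rep_len(as.character(situation), n)
  if (n == 0L || length(system) == 0L) return(integer(n))
  ug <- unique(gene); us <- unique(situation)
  gsets <- relation_terms(r_gene, ug)
  ssets <- relation_terms(r_situation, us)
  out <- logical(n)
  gi <- match(gene, ug); si <- match(situation, us)
  for (sb in system) {
    # an empty side is a vacuous conjunction: it supports every entity,
    # matching the induced-bicluster semantics of one-sided descriptions
    gok <- if (nrow(sb$gene_terms) == 0L) rep(TRUE, length(ug)) else
      matched_weights(sb$gene_terms, gsets) >= theta_g
    sok <- if (nrow(sb$situation_terms) == 0L) rep(TRUE, length(us)) else
      matched_weights(sb$situation_terms, ssets) >= theta_s
    out <- out | (gok[gi] & sok[si])
    if (all(out)) break
  }
  as.integer(out)
}
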