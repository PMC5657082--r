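#' Unroll an expression matrix into an instance-per-cell dataset
#'
#' Transforms the m x n matrix into m*n learning instances, one per cell, in
#' row-major order (gene varies slowest).  Each instance carries binary
#' indicators for all gene-vocabulary terms (1 iff the term annotates the
#' cell's gene), then for all situation-vocabulary terms, and the 0/1
#' expression value as class label.
#'
#' @param matrix an `expression_matrix`.
#' @param r_gene,r_situation annotation relations (normally closed).
#' @param gene_vocab,situation_vocab term vocabularies (character vectors);
#'   default to the sorted terms used by each relation.  The two vocabularies
#'   must be disjoint.
#' @return An object of class `unrolled_dataset` with fields `features`
#'   (logical matrix, columns named by term), `class` (integer 0/1), `gene`
#'   and `situation` (back-references per row), `gene_vocab`,
#'   `situation_vocab`.
#' @export
unroll <- function(matrix, r_gene, r_situation,
                   gene_vocab = NULL, situation_vocab = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (is.null(gene_vocab))
    gene_vocab <- sort(unique(unlist(r_gene, use.names = FALSE)))
  if (is.null(situation_vocab))
    situation_vocab <- sort(unique(unlist(r_situation, use.names = FALSE)))
  if (length(intersect(gene_vocab, situation_vocab)) > 0)
    stop("gene and situation vocabularies must be disjoint")
  g <- genes(matrix); s <- situations(matrix)
  m <- length(g); n <- length(s)
  gsets <- relation_terms(r_gene, g)
  ssets <- relation_terms(r_situation, s)
  fg <- t(vapply(gsets, function(tt) gene_vocab %in% tt,
                 logical(length(gene_vocab))))
  fs <- t(vapply(ssets, function(tt) situation_vocab %in% tt,
                 logical(length(situation_vocab))))
  dim(fg) <- c(m, length(gene_vocab))     # vapply drops dims for 1-term vocab
  dim(fs) <- c(n, length(situation_vocab))
  features <- cbind(fg[rep(seq_len(m), each = n), , drop = FALSE],
                    fs[rep.int(seq_len(n), m), , drop = FALSE])
  colnames(features) <- c(gene_vocab, situation_vocab)
  structure(list(features = features,
                 class = as.integer(t(matrix$values)),
                 gene = rep(g, each = n),
                 situation = rep.int(s, m),
                 gene_vocab = gene_vocab,
                 situation_vocab = situation_vocab),
            class = "unrolled_dataset")
}

#' @export
print.unrolled_dataset <- function(x, ...) {
  cat(sprintf("unrolled_dataset: %d instances x %d features (+class)\n",
              length(x$class), ncol(x$features)))
  invisible(x)
}

#' Frequency-based feature selection on an unrolled dataset
#'
#' Drops every feature whose positive (term-present) count falls below
#' `ceiling(min_fraction * n_instances)`; the class column and the
#' back-references are always retained.  The default threshold of one per
#' mille removes terms too rare to generalize over a reasonable number of
#' cells.
#'
#' @param data an `unrolled_dataset`.
#' @param min_fraction minimal fraction of instances a feature must occur in.
#' @return The filtered `unrolled_dataset`.
#' @export
select_features <- function(data, min_fraction = 0.001) {
  stopifnot(inherits(data, "unrolled_dataset"),
            min_fraction >= 0, min_fraction < 1)
  keep <- colSums(data$features) >= ceiling(min_fraction * length(data$class))
  if (!any(keep)) warning("all features dropped by frequency selection")
  data$features <- data$features[, keep, drop = FALSE]
  data$gene_vocab <- intersect(data$gene_vocab, colnames(data$features))
  data$situation_vocab <- intersect(data$situation_vocab,
                                    colnames(data$features))
  data
}

#' Conjunctive decision rule
#'
#' @param gene_literals,situation_literals data frames with columns `term`
#'   and `sign` (+1 presence, -1 absence).
#' @param p,n positive/negative training coverage counts.
#' @return An object of class `rule`; its Laplace-corrected confidence is
#'   `(p + 1) / (p + n + 2)`.
#' @export
rule <- function(gene_literals = NULL, situation_literals = NULL,
                 p = 0L, n = 0L) {
  empty <- data.frame(term = character(), sign = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(gene_literals)) gene_literals <- empty
  if (is.null(situation_literals)) situation_literals <- empty
  structure(list(gene_literals = gene_literals,
                 situation_literals = situation_literals,
                 p = as.integer(p), n = as.integer(n),
                 confidence = (p + 1) / (p + n + 2)),
            class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  lit <- function(df) if (nrow(df) == 0L) "TRUE" else
    paste(ifelse(df$sign > 0, df$term, paste0("!", df$term)), collapse = " & ")
  cat(sprintf("rule: [%s] x [%s] -> expression (conf %.3f, p=%d n=%d)\n",
              lit(x$gene_literals), lit(x$situation_literals),
              x$confidence, x$p, x$n))
  invisible(x)
}

# literals as (feature index, sign) -> row coverage on a feature matrix
.covers <- function(features, idx, sign) {
  out <- rep(TRUE, nrow(features))
  for (i in seq_along(idx))
    out <- out & (features[, idx[i]] == (sign[i] > 0L))
  out
}

.split_literals <- function(data, idx, sign) {
  term <- colnames(data$features)[idx]
  gside <- term %in% data$gene_vocab
  bad <- term[!gside & !(term %in% data$situation_vocab)]
  if (length(bad) > 0)
    stop(sprintf("term(s) in neither vocabulary: %s",
                 paste(bad, collapse = ", ")))
  list(gene = data.frame(term = term[gside], sign = sign[gside],
                         stringsAsFactors = FALSE),
       situation = data.frame(term = term[!gside], sign = sign[!gside],
                              stringsAsFactors = FALSE))
}

# stratified two-way split; returns logical: TRUE -> first part
.stratified_split <- function(class, fraction) {
  first <- logical(length(class))
  for (cl in unique(class)) {
    idx <- which(class == cl)
    k <- round(fraction * length(idx))
    first[sample(idx, k)] <- TRUE
  }
  first
}

#' Separate-and-conquer rule learning
#'
#' Learns an ordered list of conjunctive rules predicting expression = 1,
#' following the incremental-reduced-error-pruning family: the (still
#' active) instances are split 2:1 into a growing and a pruning set; a rule
#' is grown by repeatedly adding the presence literal with the best FOIL
#' information gain until it covers no negatives or no literal gains;
#' the rule is then pruned back to the final-literal prefix maximizing
#' `(p - n) / (p + n)` on the pruning set.  Rule addition stops when the last
#' rule's pruning-set error exceeds 50% or no positives remain; accepted
#' rules have their covered positives removed.  Prediction falls back to
#' no-expression when no rule fires.
#'
#' @param data an `unrolled_dataset`.
#' @param seed integer seed for the grow/prune splits.
#' @return An object of class `rule_list` (list of [rule()]s in learning
#'   order; first-match semantics).
#' @export
learn_rules <- function(data, seed = 1L) {
  stopifnot(inherits(data, "unrolled_dataset"))
  set.seed(seed)
  X <- data$features
  y <- data$class
  active <- rep(TRUE, length(y))
  rules <- list()
  while (sum(y[active] == 1L) > 0L) {
    act_idx <- which(active)
    grow_first <- .stratified_split(y[act_idx], 2 / 3)
    grow <- act_idx[grow_first]
    prune <- act_idx[!grow_first]
    if (sum(y[grow] == 1L) == 0L) break
    lit_idx <- integer(); lit_sign <- integer()
    cov <- rep(TRUE, length(grow))
    yg <- y[grow]
    repeat {
      p0 <- sum(cov & yg == 1L); n0 <- sum(cov & yg == 0L)
      if (n0 == 0L) break
      cand <- setdiff(seq_len(ncol(X)), lit_idx)
      if (length(cand) == 0L) break
      Xc <- X[grow[cov], cand, drop = FALSE]
      p1 <- colSums(Xc[yg[cov] == 1L, , drop = FALSE])
      n1 <- colSums(Xc[yg[cov] == 0L, , drop = FALSE])
      gain <- ifelse(p1 > 0,
                     p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0))),
                     -Inf)
      best <- which.max(gain)                       # ties: feature order
      if (!is.finite(gain[best]) || gain[best] <= 1e-12) break
      lit_idx <- c(lit_idx, cand[best])
      lit_sign <- c(lit_sign, 1L)
      cov <- cov & (X[grow, cand[best]] == TRUE)
    }
    if (length(lit_idx) == 0L) break
    # prune: best final-literal prefix by (p - n) / (p + n) on the prune set
    yp <- y[prune]
    pcov <- rep(TRUE, length(prune))
    val <- numeric(length(lit_idx))
    perr <- numeric(length(lit_idx))
    for (i in seq_along(lit_idx)) {
      pcov <- pcov & (X[prune, lit_idx[i]] == TRUE)
      pp <- sum(pcov & yp == 1L); nn <- sum(pcov & yp == 0L)
      val[i] <- if (pp + nn == 0L) -1 else (pp - nn) / (pp + nn)
      perr[i] <- if (pp + nn == 0L) 0 else nn / (pp + nn)
    }
    keep_len <- max(which(val == max(val)))         # ties: keep more literals
    if (perr[keep_len] > 0.5) break
    lit_idx <- lit_idx[seq_len(keep_len)]
    lit_sign <- lit_sign[seq_len(keep_len)]
    rcov <- .covers(X, lit_idx, lit_sign) & active
    p <- sum(rcov & y == 1L); n <- sum(rcov & y == 0L)
    lits <- .split_literals(data, lit_idx, lit_sign)
    rules[[length(rules) + 1L]] <- rule(lits$gene, lits$situation, p, n)
    active[rcov & y == 1L] <- FALSE                 # remove covered positives
  }
  structure(rules, class = "rule_list")
}

#' @export
print.rule_list <- function(x, ...) {
  cat(sprintf("rule_list of %d rule(s)\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

.entropy <- function(p, n) {
  tot <- p + n
  if (tot == 0L) return(0)
  f <- c(p, n) / tot
  f <- f[f > 0]
  -sum(f * log2(f))
}

.tree_node <- function(idx, y, path_used, X, min_leaf) {
  p <- sum(y[idx] == 1L); n <- length(idx) - p
  leaf <- list(leaf = TRUE, class = as.integer(p > n), p = p, n = n,
               confidence = (p + 1) / (p + n + 2))
  if (p == 0L || n == 0L || length(idx) < min_leaf) return(leaf)
  cand <- setdiff(seq_len(ncol(X)), path_used)
  if (length(cand) == 0L) return(leaf)
  h <- .entropy(p, n)
  best <- 0L; best_ratio <- 0
  for (f in cand) {
    right <- X[idx, f]
    nr <- sum(right); nl <- length(idx) - nr
    if (nr == 0L || nl == 0L) next
    pr <- sum(y[idx][right] == 1L); pl <- p - pr
    gain <- h - (nl * .entropy(pl, nl - pl) + nr * .entropy(pr, nr - pr)) /
      length(idx)
    if (gain <= 1e-12) next
    si <- .entropy(nl, nr)                 # split info on a binary split
    ratio <- gain / si
    if (ratio > best_ratio + 1e-12) { best_ratio <- ratio; best <- f }
  }
  if (best == 0L) return(leaf)
  right <- X[idx, best]
  list(leaf = FALSE, feature = best, p = p, n = n,
       class = as.integer(p > n), confidence = (p + 1) / (p + n + 2),
       left = .tree_node(idx[!right], y, c(path_used, best), X, min_leaf),
       right = .tree_node(idx[right], y, c(path_used, best), X, min_leaf))
}

# reduced-error pruning: replace a subtree by a leaf when the leaf makes
# strictly fewer holdout errors, or ties while the subtree already errs on
# the build set (a tie between a perfect subtree and a leaf only reflects
# holdout sparsity, so the exact subtree is kept).
.prune_node <- function(node, hold_idx, y, X) {
  if (node$leaf) {
    node$hold_err <- sum(y[hold_idx] != node$class)
    node$build_err <- min(node$p, node$n)
    return(node)
  }
  right <- X[hold_idx, node$feature]
  node$left <- .prune_node(node$left, hold_idx[!right], y, X)
  node$right <- .prune_node(node$right, hold_idx[right], y, X)
  sub_err <- node$left$hold_err + node$right$hold_err
  sub_build <- node$left$build_err + node$right$build_err
  leaf_err <- sum(y[hold_idx] != node$class)
  if (leaf_err < sub_err || (leaf_err == sub_err && sub_build > 0L))
    return(list(leaf = TRUE, class = node$class, p = node$p, n = node$n,
                confidence = node$confidence, hold_err = leaf_err,
                build_err = min(node$p, node$n)))
  node$hold_err <- sub_err
  node$build_err <- sub_build
  node
}

#' Decision-tree learning on binary term features
#'
#' Top-down induction of a binary tree in the classic gain-ratio style:
#' each internal node tests presence of one term not already fixed on its
#' path; growth stops on class purity, on fewer than `min_leaf` instances,
#' or when no split has positive information gain.  The tree is then
#' simplified by reduced-error pruning against an internal stratified
#' holdout.  Leaves carry training counts and the Laplace-corrected
#' confidence of the positive class.
#'
#' @param data an `unrolled_dataset`.
#' @param seed integer seed for the build/holdout split.
#' @param min_leaf minimal node size that may still be split.
#' @param holdout_fraction fraction of instances reserved for pruning.
#' @return An object of class `decision_tree` (nested node lists, plus the
#'   vocabularies needed for prediction).
#' @export
learn_tree <- function(data, seed = 1L, min_leaf = 2L,
                       holdout_fraction = 0.2) {
  stopifnot(inherits(data, "unrolled_dataset"), length(data$class) > 0L)
  set.seed(seed)
  y <- data$class
  X <- data$features
  hold <- .stratified_split(y, holdout_fraction)
  build_idx <- which(!hold)
  if (length(build_idx) == 0L) build_idx <- seq_along(y)
  root <- .tree_node(build_idx, y, integer(), X, min_leaf)
  if (any(hold)) root <- .prune_node(root, which(hold), y, X)
  structure(list(root = root, feature_names = colnames(X),
                 gene_vocab = data$gene_vocab,
                 situation_vocab = data$situation_vocab),
            class = "decision_tree")
}

.tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(.tree_depth(node$left), .tree_depth(node$right))
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("decision_tree: depth %d\n", .tree_depth(x$root)))
  invisible(x)
}

#' Rewrite a decision tree as a list of rules
#'
#' One rule per positive leaf: the path literals, signed by branch direction
#' (the 0-branch contributes a negated term), with the leaf's counts and
#' confidence.
#'
#' @param tree a `decision_tree`.
#' @return A `rule_list` (empty when the tree has no positive leaf).
#' @export
tree_to_rules <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  fake_data <- list(gene_vocab = tree$gene_vocab,
                    situation_vocab = tree$situation_vocab,
                    features = base::matrix(
                      logical(), 0, length(tree$feature_names),
                      dimnames = list(NULL, tree$feature_names)))
  rules <- list()
  walk <- function(node, idx, sign) {
    if (node$leaf) {
      if (node$class == 1L) {
        lits <- .split_literals(fake_data, idx, sign)
        r <- rule(lits$gene, lits$situation, node$p, node$n)
        r$confidence <- node$confidence
        rules[[length(rules) + 1L]] <<- r
      }
      return(invisible())
    }
    walk(node$left, c(idx, node$feature), c(sign, -1L))
    walk(node$right, c(idx, node$feature), c(sign, 1L))
  }
  walk(tree$root, integer(), integer())
  structure(rules, class = "rule_list")
}

#' Convert rules to a crisp semantic bicluster system
#'
#' Each rule becomes a semantic bicluster whose term sets are the rule's
#' literals with weight 1 (signs preserved).  On any matrix the cells covered
#' by a rule therefore form a rectangle: the product of the genes satisfying
#' its gene literals and the situations satisfying its situation literals.
#'
#' @param rules a `rule_list`.
#' @return A `semantic_bicluster_system`.
#' @export
rules_to_semantic_biclusters <- function(rules) {
  stopifnot(inherits(rules, "rule_list"))
  semantic_bicluster_system(lapply(rules, function(r)
    semantic_bicluster(
      weighted_terms(r$gene_literals$term, 1, r$gene_literals$sign),
      weighted_terms(r$situation_literals$term, 1,
                     r$situation_literals$sign))))
}

# does a set of signed literals hold for each entity's (closed) term set?
.literals_hold <- function(literals, term_sets) {
  if (nrow(literals) == 0L) return(rep(TRUE, length(term_sets)))
  vapply(term_sets, function(tt) {
    present <- literals$term %in% tt
    all(present == (literals$sign > 0L))
  }, logical(1))
}

#' Prediction confidence of a rule list or decision tree
#'
#' For a rule list, the confidence of the first rule (in learning order)
#' matching the pair, or 0 when no rule fires (the no-expression default).
#' For a tree, the positive-class confidence of the leaf the pair reaches.
#'
#' @param model a `rule_list` or `decision_tree`.
#' @param gene,situation character vectors (recycled to equal length).
#' @param r_gene,r_situation annotation relations (closed).
#' @return Numeric vector of confidences in \[0;1\].
#' @export
predict_confidence <- function(model, gene, situation, r_gene, r_situation) {
  UseMethod("predict_confidence")
}

#' @export
predict_confidence.rule_list <- function(model, gene, situation,
                                         r_gene, r_situation) {
  n <- max(length(gene), length(situation))
  gene <- rep_len(as.character(gene), n)
  situation <- rep_len(as.character(situation), n)
  ug <- unique(gene); us <- unique(situation)
  gsets <- relation_terms(r_gene, ug)
  ssets <- relation_terms(r_situation, us)
  gi <- match(gene, ug); si <- match(situation, us)
  conf <- numeric(n)
  open <- rep(TRUE, n)
  for (r in model) {
    gok <- .literals_hold(r$gene_literals, gsets)
    sok <- .literals_hold(r$situation_literals, ssets)
    hit <- open & gok[gi] & sok[si]
    conf[hit] <- r$confidence
    open <- open & !hit
    if (!any(open)) break
  }
  conf
}

#' @export
predict_confidence.decision_tree <- function(model, gene, situation,
                                            r_gene, r_situation) {
  n <- max(length(gene), length(situation))
  gene <- rep_len(as.character(gene), n)
  situation <- rep_len(as.character(situation), n)
  ug <- unique(gene); us <- unique(situation)
  gsets <- relation_terms(r_gene, ug)
  ssets <- relation_terms(r_situation, us)
  gi <- match(gene, ug); si <- match(situation, us)
  conf <- numeric(n)
  descend <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) { conf[idx] <<- node$confidence; return(invisible()) }
    term <- model$feature_names[node$feature]
    has <- if (term %in% model$gene_vocab)
      vapply(gsets[gi[idx]], function(tt) term %in% tt, logical(1))
    else
      vapply(ssets[si[idx]], function(tt) term %in% tt, logical(1))
    descend(node$left, idx[!has])
    descend(node$right, idx[has])
  }
  descend(model$root, seq_len(n))
  conf
}
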