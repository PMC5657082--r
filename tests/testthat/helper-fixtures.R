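# shared fixtures, all built in code

em_from <- function(vals, genes = NULL, situations = NULL) {
  m <- as.matrix(vals)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(situations)) situations <- paste0("s", seq_len(ncol(m)))
  expression_matrix(m, gene_ids = genes, situation_ids = situations)
}

rel <- function(...) annotation_relation(list(...))

# random annotation relation over `ids` drawing from `vocab`
random_relation <- function(ids, vocab, p = 0.3) {
  annotation_relation(stats::setNames(
    lapply(ids, function(i) vocab[stats::runif(length(vocab)) < p]), ids))
}

# random crisp semantic bicluster system over two vocabularies
random_semantic_system <- function(n, gene_vocab, situation_vocab,
                                   max_terms = 2L) {
  semantic_bicluster_system(lapply(seq_len(n), function(k)
    semantic_bicluster(
      weighted_terms(sample(gene_vocab, sample.int(max_terms + 1L, 1L) - 1L)),
      weighted_terms(sample(situation_vocab,
                            sample.int(max_terms + 1L, 1L) - 1L)))))
}

# small planted configuration for fast end-to-end checks
small_gen <- function(...) {
  generator_config(n_genes = 120L, n_situations = 24L, gene_terms = 40L,
                   situation_terms = 25L, dag_depth = 3L, n_planted = 2L,
                   terms_per_side = 2L, gene_fraction = 0.25,
                   situation_fraction = 0.3, ...)
}

# stub model with fixed per-gene confidences, for ROC machinery tests
predict_confidence.fixed_conf <- function(model, gene, situation,
                                          r_gene, r_situation) {
  unname(model$conf[gene])
}
registerS3method("predict_confidence", "fixed_conf",
                 predict_confidence.fixed_conf,
                 envir = asNamespace("sembic"))

# brute-force hypergeometric upper tail via binomial coefficients
hyper_tail_oracle <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
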