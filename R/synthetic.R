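#' Configuration of the planted-bicluster generator
#'
#' Describes the simulated study: matrix shape, ontology vocabulary sizes and
#' depth, number of planted semantic biclusters and terms defining each side,
#' annotation background density, and expression flip-noise rates.  Defaults
#' are sized to the scale of a typical imaginal-disc style dataset (about a
#' thousand genes by 72 situations) with low noise.
#'
#' @param n_genes,n_situations matrix dimensions.
#' @param gene_terms,situation_terms ontology vocabulary sizes.
#' @param dag_depth maximal depth of the random ontology DAGs.
#' @param n_planted number of planted semantic biclusters.
#' @param terms_per_side leaf terms defining each side of each bicluster.
#' @param fp_noise,fn_noise probabilities of flipping a 0 to 1 and a 1 to 0.
#' @param background_density probability with which any leaf term annotates
#'   an entity outside the planting scheme.
#' @param gene_fraction,situation_fraction fraction of entities belonging to
#'   each planted bicluster.
#' @param seed integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 1000L, n_situations = 72L,
                             gene_terms = 150L, situation_terms = 60L,
                             dag_depth = 4L, n_planted = 3L,
                             terms_per_side = 3L,
                             fp_noise = 0.02, fn_noise = 0.02,
                             background_density = 0.02,
                             gene_fraction = 0.15, situation_fraction = 0.2,
                             seed = 1L) {
  stopifnot(n_genes >= 2, n_situations >= 2, gene_terms >= 1,
            situation_terms >= 1, dag_depth >= 1, n_planted >= 1,
            terms_per_side >= 1)
  if (fp_noise < 0 || fp_noise >= 0.5 || fn_noise < 0 || fn_noise >= 0.5)
    stop("noise rates must lie in [0;0.5)")
  if (background_density < 0 || background_density >= 1)
    stop("`background_density` must lie in [0;1)")
  structure(as.list(environment()), class = "generator_config")
}

#' Random rooted ontology DAG
#'
#' Builds an acyclic term hierarchy: a single root, every other term placed
#' on a random level in `1:dag_depth` and attached to one or two parents
#' drawn from strictly shallower levels, so the graph is acyclic by
#' construction.  Edge types are drawn with realistic frequencies
#' (mostly `is_a`).
#'
#' @param n_terms number of terms (>= 1).
#' @param dag_depth maximal level.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param prefix string prefix for generated term ids.
#' @return An [ontology()].
#' @export
random_ontology <- function(n_terms, dag_depth = 3L, seed = NULL,
                            prefix = "T") {
  if (n_terms < 1L) stop("`n_terms` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n_terms))
  terms <- data.frame(id = ids, name = paste("term", ids),
                      stringsAsFactors = FALSE)
  if (n_terms == 1L) return(ontology(terms))
  level <- c(0L, sample.int(dag_depth, n_terms - 1L, replace = TRUE))
  child <- character(); parent <- character()
  for (i in seq_len(n_terms)[-1L]) {
    shallower <- which(level < level[i])
    k <- min(length(shallower), sample(1:2, 1L))
    pp <- if (length(shallower) == 1L) shallower else sample(shallower, k)
    child <- c(child, rep(ids[i], length(pp)))
    parent <- c(parent, ids[pp])
  }
  type <- sample(c("is_a", "part_of", "develops_from"), length(child),
                 replace = TRUE, prob = c(0.7, 0.2, 0.1))
  ontology(terms, data.frame(child = child, parent = parent, type = type,
                             stringsAsFactors = FALSE))
}

# sample annotation relation: members get `planted` term sets; every
# (entity, leaf) pair not thereby fixed is annotated with prob `bg`
.sample_relation <- function(entity_ids, leaves, planted_terms, members, bg) {
  n <- length(entity_ids)
  sets <- stats::setNames(vector("list", n), entity_ids)
  sets[] <- list(character())
  if (bg > 0 && length(leaves) > 0) {
    hits <- base::matrix(stats::runif(n * length(leaves)) < bg, n)
    for (i in seq_len(n)) sets[[i]] <- leaves[hits[i, ]]
  }
  for (k in seq_along(planted_terms))
    for (e in members[[k]])
      sets[[e]] <- union(sets[[e]], planted_terms[[k]])
  annotation_relation(sets)
}

#' Simulate a matrix with planted semantic biclusters
#'
#' Generates two random ontologies, entity annotations and a binary
#' expression matrix in which the 1-cells are exactly the extension induced
#' by a set of planted crisp semantic biclusters (before noise).  Each
#' planted bicluster is defined by `terms_per_side` leaf terms on both sides;
#' those terms are assigned to the bicluster's member entities and, at rate
#' `background_density`, elsewhere, so the induced rectangles may pick up
#' occasional extra entities, exactly as the semantic model dictates.
#' Expression values are then flipped 1 to 0 with probability `fn_noise` and
#' 0 to 1 with probability `fp_noise`.  Everything is reproducible from the
#' configuration seed.
#'
#' @param config a [generator_config()].
#' @return A list of class `planted_data` with fields `matrix`
#'   (`expression_matrix`), `r_gene`, `r_situation` (leaf-level annotation
#'   relations, not closed), `gene_ontology`, `situation_ontology`, `truth`
#'   (list: `system` — the planted `semantic_bicluster_system`, `extension`
#'   — its induced cell set, `clean` — the noise-free 0/1 matrix,
#'   `member_genes`, `member_situations`) and `config`.
#' @export
plant_biclusters <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  gids <- sprintf("g%05d", seq_len(config$n_genes))
  sids <- sprintf("s%03d", seq_len(config$n_situations))
  g_onto <- random_ontology(config$gene_terms, config$dag_depth, prefix = "GT")
  s_onto <- random_ontology(config$situation_terms, config$dag_depth,
                            prefix = "ST")
  g_leaves <- term_leaves(g_onto)
  s_leaves <- term_leaves(s_onto)
  need <- config$n_planted * config$terms_per_side
  if (length(g_leaves) < need || length(s_leaves) < need)
    stop("ontologies have too few leaf terms for the requested planting")
  g_pick <- sample(g_leaves, need)
  s_pick <- sample(s_leaves, need)
  idx <- split(seq_len(need),
               rep(seq_len(config$n_planted), each = config$terms_per_side))
  g_terms <- lapply(idx, function(i) g_pick[i])
  s_terms <- lapply(idx, function(i) s_pick[i])
  n_mg <- max(2L, round(config$gene_fraction * config$n_genes))
  n_ms <- max(2L, round(config$situation_fraction * config$n_situations))
  member_g <- lapply(seq_len(config$n_planted), function(k)
    sort(sample(gids, n_mg)))
  member_s <- lapply(seq_len(config$n_planted), function(k)
    sort(sample(sids, n_ms)))
  r_gene <- .sample_relation(gids, g_leaves, g_terms, member_g,
                             config$background_density)
  r_situation <- .sample_relation(sids, s_leaves, s_terms, member_s,
                                  config$background_density)
  system <- semantic_bicluster_system(lapply(seq_len(config$n_planted),
    function(k) semantic_bicluster(weighted_terms(g_terms[[k]], 1),
                                   weighted_terms(s_terms[[k]], 1))))
  for (k in seq_len(config$n_planted)) {
    bc <- induce_bicluster(system[[k]], gids, sids, r_gene, r_situation)
    if (length(bc$genes) == 0L || length(bc$situations) == 0L)
      stop("planted bicluster induces an empty rectangle")   # cannot happen
  }
  ext <- semantic_extension(system, gids, sids, r_gene, r_situation)
  clean <- base::matrix(0L, length(gids), length(sids),
                        dimnames = list(gids, sids))
  clean[cbind(match(ext$gene, gids), match(ext$situation, sids))] <- 1L
  noisy <- clean
  flip1 <- clean == 1L & stats::runif(length(clean)) < config$fn_noise
  flip0 <- clean == 0L & stats::runif(length(clean)) < config$fp_noise
  noisy[flip1] <- 0L
  noisy[flip0] <- 1L
  structure(list(matrix = expression_matrix(noisy),
                 r_gene = r_gene, r_situation = r_situation,
                 gene_ontology = g_onto, situation_ontology = s_onto,
                 truth = list(system = system, extension = ext,
                              clean = clean, member_genes = member_g,
                              member_situations = member_s,
                              gene_terms = g_terms, situation_terms = s_terms),
                 config = config),
            class = "planted_data")
}

#' @export
print.planted_data <- function(x, ...) {
  cat(sprintf(
    "planted_data: %d x %d matrix, %d planted bicluster(s), seed %d\n",
    nrow(x$matrix$values), ncol(x$matrix$values), length(x$truth$system),
    x$config$seed))
  invisible(x)
}
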