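.format_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read and write a binary expression matrix as TSV
#'
#' The TSV layout has a header row of situation identifiers (with a corner
#' label in the first field) and one row per gene, the gene identifier first.
#' Cells must be strictly 0 or 1; ragged or non-binary rows raise a format
#' error naming the offending line.
#'
#' @param path file path.
#' @return [read_matrix_tsv()] returns an `expression_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) .format_error(path, 1L, "expected header and data")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sids <- header[-1L]
  n <- length(sids)
  vals <- base::matrix(0L, length(lines) - 1L, n)
  gids <- character(length(lines) - 1L)
  for (i in seq_along(lines)[-1L]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 1L)
      .format_error(path, i, sprintf("expected %d fields, found %d",
                                     n + 1L, length(f)))
    cells <- suppressWarnings(as.integer(f[-1L]))
    if (anyNA(cells) || !all(cells %in% c(0L, 1L)))
      .format_error(path, i, "cells must be 0 or 1")
    gids[i - 1L] <- f[1L]
    vals[i - 1L, ] <- cells
  }
  expression_matrix(vals, gene_ids = gids, situation_ids = sids)
}

#' @rdname read_matrix_tsv
#' @param matrix an `expression_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  header <- paste(c("gene", situations(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix$values)), function(i)
    paste(c(genes(matrix)[i], matrix$values[i, ]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write the FIMI sparse transaction format
#'
#' One line per matrix row listing the whitespace-separated 0-based column
#' indices of its 1-cells; empty rows emit an empty line.  The format stores
#' no identifiers, so they may be supplied (or are synthesized as
#' `g1..`/`s1..`).
#'
#' @param path file path.
#' @param n_situations number of columns; inferred from the largest index
#'   when omitted.
#' @param gene_ids,situation_ids optional identifier vectors.
#' @return [read_fimi()] returns an `expression_matrix`.
#' @export
read_fimi <- function(path, n_situations = NULL, gene_ids = NULL,
                      situation_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  idx <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    f <- f[nzchar(f)]
    if (length(f) == 0L) return(integer())
    v <- suppressWarnings(as.integer(f))
    if (anyNA(v) || any(v < 0L))
      .format_error(path, i, "indices must be non-negative integers")
    v
  })
  if (is.null(n_situations))
    n_situations <- max(c(unlist(idx), -1L)) + 1L
  if (!is.null(situation_ids)) n_situations <- length(situation_ids)
  vals <- base::matrix(0L, length(lines), n_situations)
  for (i in seq_along(idx)) {
    if (length(idx[[i]]) > 0 && max(idx[[i]]) >= n_situations)
      .format_error(path, i, "column index out of range")
    vals[i, idx[[i]] + 1L] <- 1L
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(vals)))
  if (is.null(situation_ids))
    situation_ids <- paste0("s", seq_len(n_situations))
  expression_matrix(vals, gene_ids = gene_ids, situation_ids = situation_ids)
}

#' @rdname read_fimi
#' @param matrix an `expression_matrix`.
#' @export
write_fimi <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  body <- vapply(seq_len(nrow(matrix$values)), function(i)
    paste(which(matrix$values[i, ] == 1L) - 1L, collapse = " "), character(1))
  writeLines(body, path)
  invisible(path)
}

#' Read and write a minimal OBO ontology subset
#'
#' Supports `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of` / `relationship: develops_from` lines; everything
#' else is ignored.
#'
#' @param path file path.
#' @return [read_obo()] returns an [ontology()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ids <- character(); nms <- character()
  child <- character(); parent <- character(); type <- character()
  cur <- NA_character_
  in_term <- FALSE
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (l == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", l)) { in_term <- FALSE; next }
    if (!in_term || l == "") next
    if (grepl("^id:", l)) {
      cur <- trimws(sub("^id:", "", l))
      ids <- c(ids, cur); nms <- c(nms, cur)
    } else if (grepl("^name:", l)) {
      if (is.na(cur)) .format_error(path, i, "name before id")
      nms[length(nms)] <- trimws(sub("^name:", "", l))
    } else if (grepl("^is_a:", l)) {
      if (is.na(cur)) .format_error(path, i, "is_a before id")
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      child <- c(child, cur); parent <- c(parent, p); type <- c(type, "is_a")
    } else if (grepl("^relationship:", l)) {
      if (is.na(cur)) .format_error(path, i, "relationship before id")
      f <- strsplit(trimws(sub("!.*$", "", sub("^relationship:", "", l))),
                    "[ \t]+")[[1L]]
      if (length(f) != 2L || !f[1L] %in% c("part_of", "develops_from"))
        .format_error(path, i, "unsupported relationship")
      child <- c(child, cur); parent <- c(parent, f[2L])
      type <- c(type, f[1L])
    }
  }
  ontology(data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
           data.frame(child = child, parent = parent, type = type,
                      stringsAsFactors = FALSE))
}

#' @rdname read_obo
#' @param onto an [ontology()].
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$id[i]
    ee <- onto$edges[onto$edges$child == id, , drop = FALSE]
    rel <- character()
    if (nrow(ee) > 0)
      rel <- ifelse(ee$type == "is_a", paste("is_a:", ee$parent),
                    paste("relationship:", ee$type, ee$parent))
    out <- c(out, "[Term]", paste("id:", id),
             paste("name:", onto$terms$name[i]), rel, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write entity-term annotations as two-column TSV
#'
#' One `entity_id<TAB>term_id` pair per line.
#'
#' @param path file path.
#' @return [read_annotations()] returns an `annotation_relation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ent <- character(length(lines)); trm <- character(length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "") next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L)
      .format_error(path, i, "expected two tab-separated fields")
    ent[i] <- f[1L]; trm[i] <- f[2L]; keep[i] <- TRUE
  }
  annotation_relation(split(trm[keep], ent[keep]))
}

#' @rdname read_annotations
#' @param relation an `annotation_relation`.
#' @export
write_annotations <- function(relation, path) {
  stopifnot(inherits(relation, "annotation_relation"))
  ent <- rep(names(relation), lengths(relation))
  writeLines(paste(ent, unlist(relation, use.names = FALSE), sep = "\t"),
             path)
  invisible(path)
}

#' Read and write an unrolled dataset in ARFF
#'
#' Binary nominal attributes `{0,1}` in vocabulary order with `class` last.
#' Comment lines record the gene/situation vocabulary split and the per-row
#' back-references so that a round trip reproduces the dataset; foreign ARFF
#' files without these comments are read with all features on the gene side
#' and synthetic back-references.
#'
#' @param path file path.
#' @return [read_arff()] returns an `unrolled_dataset`.
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  attrs <- character(); n_gene_vocab <- NA_integer_
  backref <- NULL
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (grepl("^% gene_vocab_size:", l))
      n_gene_vocab <- as.integer(trimws(sub("^% gene_vocab_size:", "", l)))
    else if (grepl("^% backref:", l)) {
      backref <- c(backref, trimws(sub("^% backref:", "", l)))
    } else if (grepl("^@attribute", l, ignore.case = TRUE)) {
      f <- strsplit(l, "[ \t]+")[[1L]]
      if (length(f) < 3L || gsub(" ", "", f[3L]) != "{0,1}")
        .format_error(path, i, "attributes must be nominal {0,1}")
      attrs <- c(attrs, f[2L])
    } else if (grepl("^@data", l, ignore.case = TRUE)) {
      data_at <- i; break
    }
  }
  if (is.na(data_at)) .format_error(path, length(lines), "missing @data")
  if (length(attrs) < 1L || utils::tail(attrs, 1L) != "class")
    .format_error(path, data_at, "last attribute must be `class`")
  feats <- utils::head(attrs, -1L)
  body <- lines[-seq_len(data_at)]
  body <- body[nzchar(trimws(body)) & !grepl("^%", trimws(body))]
  vals <- base::matrix(0L, length(body), length(attrs))
  for (i in seq_along(body)) {
    f <- suppressWarnings(as.integer(strsplit(trimws(body[i]), ",")[[1L]]))
    if (length(f) != length(attrs) || anyNA(f) || !all(f %in% c(0L, 1L)))
      .format_error(path, data_at + i, "malformed data row")
    vals[i, ] <- f
  }
  if (is.na(n_gene_vocab)) n_gene_vocab <- length(feats)
  if (!is.null(backref)) {
    br <- strsplit(backref, "\t", fixed = TRUE)
    gene <- vapply(br, `[`, character(1), 1L)
    situation <- vapply(br, `[`, character(1), 2L)
  } else {
    gene <- paste0("row", seq_along(body))
    situation <- rep("s1", length(body))
  }
  features <- vals[, seq_along(feats), drop = FALSE] == 1L
  colnames(features) <- feats
  structure(list(features = features,
                 class = vals[, length(attrs)],
                 gene = gene, situation = situation,
                 gene_vocab = feats[seq_len(n_gene_vocab)],
                 situation_vocab = feats[-seq_len(n_gene_vocab)]),
            class = "unrolled_dataset")
}

#' @rdname read_arff
#' @param data an `unrolled_dataset`.
#' @param relation relation name written to the `@relation` header.
#' @export
write_arff <- function(data, path, relation = "unrolled") {
  stopifnot(inherits(data, "unrolled_dataset"))
  header <- c(paste("@relation", relation),
              sprintf("%% gene_vocab_size: %d", length(data$gene_vocab)),
              sprintf("%% backref: %s\t%s", data$gene, data$situation),
              sprintf("@attribute %s {0,1}",
                      c(colnames(data$features), "class")),
              "@data")
  body <- apply(cbind(data$features * 1L, data$class), 1L, paste,
                collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write all artifacts of a simulated dataset to a directory
#'
#' Emits the matrix (TSV and FIMI), both annotation tables, both ontologies
#' (OBO) and the ground truth (JSON: planted term sets, member entities and
#' the induced extension).
#'
#' @param pd a `planted_data` object.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_planted <- function(pd, dir) {
  stopifnot(inherits(pd, "planted_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(pd$matrix, file.path(dir, "matrix.tsv"))
  write_fimi(pd$matrix, file.path(dir, "matrix.fimi"))
  write_annotations(pd$r_gene, file.path(dir, "gene_annotations.tsv"))
  write_annotations(pd$r_situation, file.path(dir, "situation_annotations.tsv"))
  write_obo(pd$gene_ontology, file.path(dir, "gene_ontology.obo"))
  write_obo(pd$situation_ontology, file.path(dir, "situation_ontology.obo"))
  truth <- list(
    seed = pd$config$seed,
    biclusters = lapply(seq_along(pd$truth$system), function(k) list(
      gene_terms = pd$truth$gene_terms[[k]],
      situation_terms = pd$truth$situation_terms[[k]],
      member_genes = pd$truth$member_genes[[k]],
      member_situations = pd$truth$member_situations[[k]])),
    extension = pd$truth$extension)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
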