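#' Search configuration for the greedy bicluster miner
#'
#' @param rho positive noise-vs-description trade-off: the cost of one false
#'   prediction (a covered 0 or an uncovered 1) relative to one row/column in
#'   a bicluster description.
#' @param max_biclusters upper bound on the number of extracted biclusters.
#' @param min_rows,min_cols minimal accepted bicluster dimensions.
#' @param seed integer seed (the search is deterministic; the seed is kept in
#'   the configuration so that runs are fully reproducible end to end).
#' @return A list of class `search_config`.
#' @export
search_config <- function(rho = 1, max_biclusters = 50L,
                          min_rows = 2L, min_cols = 2L, seed = 1L) {
  if (rho <= 0) stop("`rho` must be > 0")
  if (max_biclusters < 1L || min_rows < 1L || min_cols < 1L)
    stop("all search bounds must be positive")
  structure(list(rho = rho, max_biclusters = as.integer(max_biclusters),
                 min_rows = as.integer(min_rows),
                 min_cols = as.integer(min_cols), seed = as.integer(seed)),
            class = "search_config")
}

#' Description/noise cost of a bicluster system
#'
#' The total cost balances the size of the description against its quality:
#' each bicluster contributes its number of rows plus columns
#' (`description_cost`), each covered 0-cell is a false positive, each
#' uncovered 1-cell a false negative, and
#' `total = description_cost + rho * (fp + fn)`.
#'
#' @inheritParams bicluster_extension
#' @param rho positive false-prediction cost.
#' @return A list of class `cost_report` with fields `description_cost`,
#'   `false_positives`, `false_negatives`, `total`.
#' @export
bicluster_cost <- function(system, matrix, rho = 1) {
  if (rho <= 0) stop("`rho` must be > 0")
  ind <- extension_indicator(system, matrix)
  desc <- sum(vapply(system, function(b)
    length(b$genes) + length(b$situations), numeric(1)))
  fp <- sum(ind & matrix$values == 0L)
  fn <- sum(!ind & matrix$values == 1L)
  structure(list(description_cost = desc, false_positives = fp,
                 false_negatives = fn, total = desc + rho * (fp + fn)),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("cost: total %.1f (description %d, fp %d, fn %d)\n",
              x$total, x$description_cost, x$false_positives,
              x$false_negatives))
  invisible(x)
}

# cost delta of adding column `col` to candidate rows `rows`
# (only cells not covered by previously accepted biclusters count as noise)
.col_delta <- function(A, covered, rows, col, rho) {
  cells <- A[rows, col]
  free <- !covered[rows, col]
  1 + rho * (sum(free & cells == 0L) - sum(free & cells == 1L))
}

.row_delta <- function(A, covered, row, cols, rho) {
  cells <- A[row, cols]
  free <- !covered[row, cols]
  1 + rho * (sum(free & cells == 0L) - sum(free & cells == 1L))
}

# grow one candidate bicluster from a given seed column:
# a noise-free core first, then cost-based noise-tolerant extension
.grow_candidate <- function(A, covered, rho, seed_col) {
  residual <- A == 1L & !covered
  rows <- which(residual[, seed_col])
  # order rows by residual density (denser rows join the core first)
  rows <- rows[order(-rowSums(residual[rows, , drop = FALSE]), rows)]
  cols <- seed_col
  nr <- nrow(A); nc <- ncol(A)

  # core phase: frequency-first growth of a pure all-1 block -- add the
  # best-supported remaining column (the one keeping the most core rows)
  # while the block's description-minus-coverage value does not increase
  phi <- function(rr, cc) length(rr) + length(cc) -
    rho * sum(residual[rr, cc, drop = FALSE])
  cur <- phi(rows, cols)
  repeat {
    cand <- setdiff(seq_len(nc), cols)
    if (length(cand) == 0L) break
    support <- colSums(A[rows, cand, drop = FALSE] == 1L)
    best <- which.max(support)                # ties: column order
    if (support[best] == 0L) break
    rr <- rows[A[rows, cand[best]] == 1L]
    val <- phi(rr, c(cols, cand[best]))
    if (val > cur) break
    cur <- val
    rows <- rr
    cols <- c(cols, cand[best])
  }

  extend <- function() {
    repeat {
      changed <- FALSE
      for (cc in setdiff(seq_len(nc), cols))
        if (.col_delta(A, covered, rows, cc, rho) <= 0) {
          cols <<- c(cols, cc); changed <- TRUE
        }
      for (rr in setdiff(seq_len(nr), rows))
        if (.row_delta(A, covered, rr, cols, rho) <= 0) {
          rows <<- c(rows, rr); changed <- TRUE
        }
      if (!changed) break
    }
  }
  trim <- function() {
    repeat {
      changed <- FALSE
      for (rr in rows)
        if (length(rows) > 1L &&
            .row_delta(A, covered, rr, cols, rho) > 0) {
          rows <<- setdiff(rows, rr); changed <- TRUE
        }
      for (cc in cols)
        if (length(cols) > 1L &&
            .col_delta(A, covered, rows, cc, rho) > 0) {
          cols <<- setdiff(cols, cc); changed <- TRUE
        }
      if (!changed) break
    }
  }
  extend(); trim(); extend()
  list(rows = sort(rows), cols = sort(cols))
}

#' Greedy noise-tolerant bicluster search
#'
#' Iteratively extracts biclusters that reduce the total description/noise
#' cost of the system, in the spirit of greedy boolean matrix decomposition
#' miners.  Each iteration seeds a candidate with the column holding the most
#' still-uncovered 1s, takes its residual rows, then alternately extends
#' columns and rows while each extension does not increase the total cost
#' (this is where noise, i.e. covered 0-cells, is tolerated), and finally
#' trims rows/columns whose removal lowers the cost.  A candidate is accepted
#' only if it strictly decreases the system's total cost and respects the
#' minimal dimensions, so the search always terminates.
#'
#' @param matrix an `expression_matrix`.
#' @param config a [search_config()].
#' @return A `bicluster_system` (possibly empty).
#' @export
greedy_bicluster <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(config, "search_config"))
  if (any(dim(matrix) == 0L)) stop("matrix must be non-empty")
  A <- matrix$values
  covered <- A == 2L                      # all-FALSE
  rho <- config$rho
  system <- list()
  total <- rho * sum(A == 1L)             # cost of the empty system
  cand_delta <- function(cand) {
    new_cells <- !covered[cand$rows, cand$cols, drop = FALSE]
    blk <- A[cand$rows, cand$cols, drop = FALSE]
    length(cand$rows) + length(cand$cols) +
      rho * (sum(new_cells & blk == 0L) - sum(new_cells & blk == 1L))
  }
  beam <- 16L                             # seed columns examined per round
  while (length(system) < config$max_biclusters) {
    colfreq <- colSums(A == 1L & !covered)
    seeds <- order(-colfreq)[seq_len(min(beam, sum(colfreq > 0L)))]
    if (length(seeds) == 0L) break
    best <- NULL; best_delta <- 0
    for (sc in seeds) {
      cand <- .grow_candidate(A, covered, rho, sc)
      if (length(cand$rows) < config$min_rows ||
          length(cand$cols) < config$min_cols) next
      delta <- cand_delta(cand)
      if (delta < best_delta) { best <- cand; best_delta <- delta }
    }
    if (is.null(best)) break              # no strictly cost-decreasing candidate
    covered[best$rows, best$cols] <- TRUE
    total <- total + best_delta
    system <- c(system, list(bicluster(rownames(A)[best$rows],
                                       colnames(A)[best$cols])))
  }
  bicluster_system(system)
}

#' Unsupervised choice of the noise parameter
#'
#' Runs the greedy search for every candidate `rho` and returns the one whose
#' resulting system minimizes the total cost evaluated at the reference scale
#' `rho = 1`; ties go to the smallest candidate.  This mirrors picking the
#' noise setting that minimizes the total cost of biclusters on the training
#' set, which requires no labeled supervision.
#'
#' @param matrix an `expression_matrix`.
#' @param candidate_rhos numeric vector of candidate noise parameters.
#' @param config base [search_config()]; its `rho` is overridden.
#' @return The selected `rho` (a single number).
#' @export
select_rho <- function(matrix, candidate_rhos, config = search_config()) {
  if (length(candidate_rhos) == 0L) stop("at least one candidate rho needed")
  candidate_rhos <- sort(as.numeric(candidate_rhos))
  costs <- vapply(candidate_rhos, function(r) {
    cfg <- config; cfg$rho <- r
    bicluster_cost(greedy_bicluster(matrix, cfg), matrix, rho = 1)$total
  }, numeric(1))
  candidate_rhos[which.min(costs)]        # ties: smallest rho (sorted)
}
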