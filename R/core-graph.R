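# Core graph containers shared by every stage of the pipeline.
#
# Orientation convention used throughout the package: W[i, j] != 0 (or an
# adjacency entry amat[i, j] = 1 with amat[j, i] = 0) means gene i causes
# gene j -- "row causes column", matching the linear structural equation
# model X = X W + E.

#' Construct an expression matrix
#'
#' Wraps an `n x d` numeric matrix of observational expression values
#' (samples in rows, genes in columns) and validates the invariants the
#' downstream causal-discovery stages rely on: no missing values, at least
#' two genes, at least four samples (the minimum for a Fisher-z test with an
#' empty conditioning set), and unique gene identifiers.
#'
#' @param values Numeric matrix, `n` samples by `d` genes.
#' @param sample_ids Optional character vector of `n` sample labels; defaults
#'   to existing rownames or `sample1..samplen`.
#' @param gene_ids Optional character vector of `d` unique gene labels;
#'   defaults to existing colnames or `gene1..gened`.
#' @return A numeric matrix of class `expression_matrix` with dimnames set.
#' @examples
#' x <- expression_matrix(matrix(rnorm(40), 10, 4))
#' dim(x)
#' @export
expression_matrix <- function(values, sample_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  n <- nrow(values)
  d <- ncol(values)
  if (d < 2L) stop("need at least 2 genes, got ", d)
  if (n < 4L) stop("need at least 4 samples, got ", n)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != d) stop("gene_ids length does not match column count")
  if (length(sample_ids) != n) stop("sample_ids length does not match row count")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, gene_ids)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x), " samples x ", ncol(x), " genes\n",
      sep = "")
  invisible(x)
}

gene_ids_of <- function(x) {
  if (inherits(x, "cpdag") || inherits(x, "weighted_graph") ||
      inherits(x, "ground_truth_graph") || inherits(x, "constraint_mask"))
    return(x$gene_ids)
  colnames(x)
}

#' Construct a CPDAG
#'
#' A completed partially directed acyclic graph over `d` genes, encoded as a
#' `d x d` binary matrix `amat`: a directed edge `i -> j` is
#' `amat[i, j] = 1, amat[j, i] = 0`; an undirected edge `i - j` is
#' `amat[i, j] = amat[j, i] = 1`; non-adjacent pairs are 0 in both entries.
#'
#' @param amat Square 0/1 integer matrix with zero diagonal.
#' @param gene_ids Character vector of gene labels (defaults to `amat`
#'   dimnames or `gene1..`).
#' @return An object of class `cpdag` with elements `amat` and `gene_ids`.
#' @export
cpdag <- function(amat, gene_ids = NULL) {
  amat <- as.matrix(amat)
  d <- nrow(amat)
  if (ncol(amat) != d) stop("amat must be square")
  if (!all(amat %in% c(0, 1))) stop("amat entries must be 0 or 1")
  if (any(diag(amat) != 0)) stop("amat must have a zero diagonal")
  if (is.null(gene_ids)) gene_ids <- colnames(amat)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != d || anyDuplicated(gene_ids))
    stop("gene_ids must be ", d, " unique labels")
  storage.mode(amat) <- "integer"
  dimnames(amat) <- list(gene_ids, gene_ids)
  structure(list(amat = amat, gene_ids = gene_ids), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  a <- x$amat
  dir <- sum(a == 1L & t(a) == 0L)
  und <- sum(a == 1L & t(a) == 1L) / 2L
  cat("cpdag: ", length(x$gene_ids), " genes, ", dir, " directed, ",
      und, " undirected edges\n", sep = "")
  invisible(x)
}

#' Construct a weighted causal graph
#'
#' A `d x d` real matrix `W` of signed linear effects, `W[i, j]` being the
#' direct effect of gene `i` on gene `j`.
#'
#' @param W Square numeric matrix with zero diagonal.
#' @param gene_ids Character vector of gene labels.
#' @return An object of class `weighted_graph` with elements `W` and
#'   `gene_ids`.
#' @export
weighted_graph <- function(W, gene_ids = NULL) {
  W <- as.matrix(W)
  d <- nrow(W)
  if (ncol(W) != d) stop("W must be square")
  if (!is.numeric(W) || anyNA(W)) stop("W must be numeric with no NAs")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (is.null(gene_ids)) gene_ids <- colnames(W)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != d || anyDuplicated(gene_ids))
    stop("gene_ids must be ", d, " unique labels")
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(list(W = W, gene_ids = gene_ids), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph: ", length(x$gene_ids), " genes, ",
      sum(x$W != 0), " edges\n", sep = "")
  invisible(x)
}

#' Construct an edge-constraint mask
#'
#' Boolean `d x d` matrix: `allowed[i, j]` is `TRUE` iff the edge `i -> j`
#' may carry nonzero weight in the constrained optimization. The diagonal is
#' always forbidden.
#'
#' @param allowed Square logical matrix.
#' @param gene_ids Character vector of gene labels.
#' @return An object of class `constraint_mask`.
#' @export
constraint_mask <- function(allowed, gene_ids = NULL) {
  allowed <- as.matrix(allowed)
  d <- nrow(allowed)
  if (ncol(allowed) != d) stop("allowed must be square")
  storage.mode(allowed) <- "logical"
  if (anyNA(allowed)) stop("allowed must not contain NA")
  if (any(diag(allowed))) stop("diagonal of the mask must be FALSE")
  if (is.null(gene_ids)) gene_ids <- colnames(allowed)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != d || anyDuplicated(gene_ids))
    stop("gene_ids must be ", d, " unique labels")
  dimnames(allowed) <- list(gene_ids, gene_ids)
  structure(list(allowed = allowed, gene_ids = gene_ids),
            class = "constraint_mask")
}

#' Construct a ground-truth causal graph
#'
#' Weighted reference DAG plus the binary regulator designation used by the
#' evaluation metrics. A regulator is a gene with at least one outgoing edge;
#' if `regulator_labels` is omitted it is inferred from the out-degree.
#'
#' @param W_true Square numeric matrix of true signed effects; its support
#'   must be acyclic.
#' @param regulator_labels Optional logical vector; every gene with positive
#'   out-degree must be labelled `TRUE`.
#' @param gene_ids Character vector of gene labels.
#' @return An object of class `ground_truth_graph` with elements `W_true`,
#'   `regulator_labels` and `gene_ids`.
#' @export
ground_truth_graph <- function(W_true, regulator_labels = NULL,
                               gene_ids = NULL) {
  g <- weighted_graph(W_true, gene_ids)
  if (!is_acyclic(g)) stop("ground-truth support must be acyclic")
  out_deg <- rowSums(g$W != 0)
  if (is.null(regulator_labels)) {
    regulator_labels <- out_deg > 0
  } else {
    regulator_labels <- as.logical(regulator_labels)
    if (length(regulator_labels) != length(g$gene_ids))
      stop("regulator_labels length must match gene count")
    if (any(out_deg > 0 & !regulator_labels))
      stop("every gene with outgoing edges must be labelled a regulator")
  }
  names(regulator_labels) <- g$gene_ids
  structure(list(W_true = g$W, regulator_labels = regulator_labels,
                 gene_ids = g$gene_ids),
            class = "ground_truth_graph")
}

#' @export
print.ground_truth_graph <- function(x, ...) {
  cat("ground_truth_graph: ", length(x$gene_ids), " genes (",
      sum(x$regulator_labels), " regulators), ", sum(x$W_true != 0),
      " edges\n", sep = "")
  invisible(x)
}

as_weight_matrix <- function(g) {
  if (inherits(g, "weighted_graph")) return(g$W)
  if (inherits(g, "ground_truth_graph")) return(g$W_true)
  g <- as.matrix(g)
  if (nrow(g) != ncol(g)) stop("expected a square weight matrix")
  g
}

#' Zero out edges below a magnitude threshold
#'
#' Standard post-processing of a continuous structure-learning solution:
#' entries with `|W[i, j]| < w_threshold` are set to zero, all others kept.
#'
#' @param g A `weighted_graph` (or square numeric matrix).
#' @param w_threshold Non-negative magnitude cutoff.
#' @return A `weighted_graph` with the thresholded weights.
#' @export
threshold_graph <- function(g, w_threshold) {
  if (!is.numeric(w_threshold) || length(w_threshold) != 1L ||
      is.na(w_threshold) || w_threshold < 0)
    stop("w_threshold must be a single non-negative number")
  W <- as_weight_matrix(g)
  W[abs(W) < w_threshold] <- 0
  weighted_graph(W, gene_ids_of(g))
}

#' Keep the k edges of largest absolute weight
#'
#' Ranks nonzero entries by `|W[i, j]|` and keeps the top `k`, zeroing the
#' rest; the total-edge standardization step used before graph comparison.
#' Ties at the k-th rank are broken deterministically by (row, column)
#' lexicographic order. If fewer than `k` edges are nonzero, all are kept.
#'
#' @param g A `weighted_graph` (or square numeric matrix).
#' @param k Number of edges to retain (non-negative integer).
#' @return A `weighted_graph` with at most `k` nonzero entries.
#' @export
select_top_k_edges <- function(g, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single non-negative integer")
  k <- as.integer(k)
  W <- as_weight_matrix(g)
  nz <- which(W != 0, arr.ind = TRUE)
  if (nrow(nz) > k) {
    ord <- order(-abs(W[nz]), nz[, 1L], nz[, 2L])
    drop_idx <- nz[ord[seq.int(k + 1L, nrow(nz))], , drop = FALSE]
    W[drop_idx] <- 0
  }
  weighted_graph(W, gene_ids_of(g))
}

#' Test whether the support of a weighted graph is acyclic
#'
#' Kahn topological sort on the directed graph whose edges are the nonzero
#' entries of `W` (row causes column).
#'
#' @param g A `weighted_graph`, `ground_truth_graph`, or square matrix.
#' @return `TRUE` iff the support has no directed cycle.
#' @export
is_acyclic <- function(g) {
  A <- as_weight_matrix(g) != 0
  d <- nrow(A)
  in_deg <- colSums(A)
  queue <- which(in_deg == 0L)
  n_removed <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    n_removed <- n_removed + 1L
    children <- which(A[v, ])
    if (length(children)) {
      A[v, children] <- FALSE
      in_deg[children] <- in_deg[children] - 1L
      queue <- c(queue, children[in_deg[children] == 0L])
    }
  }
  n_removed == d
}
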