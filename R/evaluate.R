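# Graph evaluation metrics and the ground-truth subsampling protocol.

support_of <- function(g) as_weight_matrix(g) != 0

check_same_genes <- function(pred, truth) {
  gp <- gene_ids_of(pred)
  gt <- gene_ids_of(truth)
  if (length(gp) != length(gt) || !all(gp == gt))
    stop("predicted and truth graphs must share the same gene set, in order")
}

# status of an unordered pair in a directed support matrix:
# 0 none, 1 i->j, 2 j->i, 3 both  (i < j)
pair_status <- function(A, i, j) {
  fw <- A[i, j]; bw <- A[j, i]
  if (fw && bw) 3L else if (fw) 1L else if (bw) 2L else 0L
}

#' Structural Hamming distance
#'
#' Minimal number of edge additions, deletions and reversals transforming
#' the predicted support into the truth support; a reversed edge costs 1,
#' not 2.
#'
#' @param pred Predicted graph (`weighted_graph` or matrix).
#' @param truth Reference graph (`ground_truth_graph`, `weighted_graph` or
#'   matrix) over the same genes.
#' @return Non-negative integer.
#' @export
shd <- function(pred, truth) {
  check_same_genes(pred, truth)
  A <- support_of(pred)
  B <- support_of(truth)
  d <- nrow(A)
  # per-pair minimal edit cost between statuses {none, ij, ji, both}:
  # differ by presence -> 1 per added/deleted arc, ij vs ji -> 1 (reversal)
  cost <- matrix(c(0, 1, 1, 2,
                   1, 0, 1, 1,
                   1, 1, 0, 1,
                   2, 1, 1, 0), 4, 4, byrow = TRUE)
  total <- 0L
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      total <- total + cost[pair_status(A, i, j) + 1L,
                            pair_status(B, i, j) + 1L]
    }
  }
  as.integer(total)
}

#' Oriented precision, recall and F1
#'
#' True positives are directed edges `i -> j` present in both graphs (the
#' orientation must match). `precision = TP / #pred edges`,
#' `recall = TP / #truth edges`, `f1 = 2PR/(P+R)`; empty denominators give
#' 0.
#'
#' @inheritParams shd
#' @return A list with `precision`, `recall`, `f1`.
#' @export
f1_oriented <- function(pred, truth) {
  check_same_genes(pred, truth)
  A <- support_of(pred)
  B <- support_of(truth)
  tp <- sum(A & B)
  n_pred <- sum(A)
  n_truth <- sum(B)
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_truth > 0) tp / n_truth else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Orientation accuracy
#'
#' Over unordered gene pairs adjacent in both the predicted and the truth
#' graph, the fraction whose predicted direction matches the truth. A pair
#' predicted in both directions counts as incorrect. Returns `NA` when no
#' adjacency is shared (the undefined case, excluded from aggregation). By
#' construction the metric is unaffected by false-positive edges on pairs
#' absent from the truth.
#'
#' @inheritParams shd
#' @return Real in `[0, 1]`, or `NA` if no shared adjacencies.
#' @export
orientation_accuracy <- function(pred, truth) {
  check_same_genes(pred, truth)
  A <- support_of(pred)
  B <- support_of(truth)
  d <- nrow(A)
  shared <- 0L
  correct <- 0L
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      sa <- pair_status(A, i, j)
      sb <- pair_status(B, i, j)
      if (sa == 0L || sb == 0L) next
      shared <- shared + 1L
      if (sa == sb && sa != 3L) correct <- correct + 1L
    }
  }
  if (shared == 0L) return(NA_real_)
  correct / shared
}

#' Per-gene regulator prediction scores
#'
#' The regulatory prediction score of gene `i` is the total absolute weight
#' of its outgoing edges, `sum_j |W[i, j]|`.
#'
#' @param pred A `weighted_graph` (or matrix).
#' @return Named numeric vector of scores.
#' @export
regulator_scores <- function(pred) {
  W <- as_weight_matrix(pred)
  s <- rowSums(abs(W))
  names(s) <- gene_ids_of(pred)
  s
}

# Mann-Whitney rank AUROC with ties counted 1/2.
rank_auroc <- function(scores, labels) {
  pos <- labels
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision (step-wise, not interpolated); ties broken by original
# index for determinism.
average_precision <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp_cum <- cumsum(lab)
  prec <- tp_cum / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Regulator prediction AUROC and AUPRC
#'
#' Compares per-gene regulator scores against the binary regulator
#' designation of the ground truth. AUROC is the normalized Mann-Whitney U
#' (ties counted 1/2); AUPRC is step-wise average precision.
#'
#' @param scores Numeric vector, e.g. from [regulator_scores()].
#' @param labels Logical vector of the same length: `TRUE` = regulator.
#' @return A list with `auroc` and `auprc`; both `NA` (with a warning) if
#'   the labels are single-class.
#' @export
regulator_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (all(labels) || !any(labels)) {
    warning("labels contain a single class; AUROC/AUPRC undefined")
    return(list(auroc = NA_real_, auprc = NA_real_))
  }
  list(auroc = rank_auroc(scores, labels),
       auprc = average_precision(scores, labels))
}

#' Pearson correlation of predicted and true effects on true-positive edges
#'
#' Restricted to edges present with the same orientation in both graphs.
#' Returns `NA` when fewer than 3 true positives exist or either weight
#' vector is constant.
#'
#' @inheritParams shd
#' @return Real in `[-1, 1]`, or `NA` when undefined.
#' @export
coefficient_correlation <- function(pred, truth) {
  check_same_genes(pred, truth)
  Wp <- as_weight_matrix(pred)
  Wt <- as_weight_matrix(truth)
  tp <- which(Wp != 0 & Wt != 0)
  if (length(tp) < 3L) return(NA_real_)
  p <- Wp[tp]; t <- Wt[tp]
  if (stats::sd(p) == 0 || stats::sd(t) == 0) return(NA_real_)
  stats::cor(p, t)
}

#' Sample induced subgraphs of a ground truth
#'
#' Each repeat samples, uniformly without replacement, `n_regulators`
#' regulator genes and `n_targets` target genes and takes the induced
#' subgraph on those genes; connectivity is not required. Repeats are
#' independently seeded (`seed + repeat`) and reproducible.
#'
#' @param truth A [ground_truth_graph()].
#' @param n_regulators,n_targets Sizes of the sampled blocks (default
#'   5 + 25).
#' @param n_repeats Number of subgraphs (default 20).
#' @param seed Integer seed.
#' @return A list of `n_repeats` [ground_truth_graph()] objects.
#' @export
subsample_ground_truth <- function(truth, n_regulators = 5, n_targets = 25,
                                   n_repeats = 20, seed = 1) {
  stopifnot(inherits(truth, "ground_truth_graph"))
  regs <- which(truth$regulator_labels)
  tgts <- which(!truth$regulator_labels)
  if (length(regs) < n_regulators)
    stop("truth has ", length(regs), " regulators, need ", n_regulators)
  if (length(tgts) < n_targets)
    stop("truth has ", length(tgts), " targets, need ", n_targets)
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    keep <- c(sample(regs, n_regulators), sample(tgts, n_targets))
    keep <- sort(keep)
    out[[r]] <- ground_truth_graph(
      truth$W_true[keep, keep, drop = FALSE],
      regulator_labels = truth$regulator_labels[keep],
      gene_ids = truth$gene_ids[keep])
  }
  out
}

#' Evaluate a predicted graph against a ground truth
#'
#' Bundles every metric: SHD, oriented precision/recall/F1, orientation
#' accuracy, regulator AUROC/AUPRC (scores = total absolute outgoing
#' weight), coefficient correlation on true positives, and the
#' true-positive edge count.
#'
#' @param pred A `weighted_graph`.
#' @param truth A [ground_truth_graph()] over the same genes.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_graph <- function(pred, truth) {
  stopifnot(inherits(truth, "ground_truth_graph"))
  check_same_genes(pred, truth)
  f1 <- f1_oriented(pred, truth)
  auc <- suppressWarnings(
    regulator_auc(regulator_scores(pred), truth$regulator_labels))
  structure(list(
    shd = shd(pred, truth),
    precision = f1$precision,
    recall = f1$recall,
    f1 = f1$f1,
    orientation_accuracy = orientation_accuracy(pred, truth),
    regulator_auroc = auc$auroc,
    regulator_auprc = auc$auprc,
    coefficient_correlation = coefficient_correlation(pred, truth),
    n_true_positive_edges = sum(support_of(pred) & support_of(truth))
  ), class = c("evaluation_report", "list"))
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", format(nm, width = 24), " ",
        if (is.na(v)) "NA" else format(v, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
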