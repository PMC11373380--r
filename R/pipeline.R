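# Orchestration of the hybrid method: PC -> constraint mask -> masked
# continuous optimization, plus the bootstrap aggregation protocol.

#' Configuration for the hybrid pipeline
#'
#' @param alpha Significance level of the PC conditional-independence tests.
#' @param max_cond_size Largest PC conditioning-set size.
#' @param notears A [notears_config()].
#' @param n_bootstrap Number of bootstrap replicates for
#'   [bootstrap_aggregate()] (default 10).
#' @param top_k Optional edge count retained after aggregation (`NULL`
#'   keeps all).
#' @param mask_orientations How the CPDAG is encoded as a constraint mask,
#'   `"free"` (default) or `"enforce"`; see [build_constraint_mask()].
#' @param seed Integer master seed; per-replicate seeds are derived from it
#'   by a fixed offset.
#' @return A list of class `pcnt_config`.
#' @export
pcnt_config <- function(alpha = 0.05, max_cond_size = 3,
                        notears = notears_config(), n_bootstrap = 10,
                        top_k = NULL,
                        mask_orientations = c("free", "enforce"),
                        seed = 1) {
  mask_orientations <- match.arg(mask_orientations)
  stopifnot(alpha > 0, alpha < 1, n_bootstrap >= 1,
            inherits(notears, "notears_config"),
            is.null(top_k) || top_k >= 0)
  structure(list(alpha = alpha, max_cond_size = as.integer(max_cond_size),
                 notears = notears, n_bootstrap = as.integer(n_bootstrap),
                 top_k = if (!is.null(top_k)) as.integer(top_k),
                 mask_orientations = mask_orientations,
                 seed = as.integer(seed)),
            class = "pcnt_config")
}

#' Run the hybrid PC-constrained continuous fit (single pass)
#'
#' Runs the PC algorithm to estimate the CPDAG, converts it to a hard
#' edge-constraint mask ([build_constraint_mask()]), and solves the masked
#' continuous acyclicity-constrained program ([notears_fit()]).
#' Non-adjacent pairs are held at exactly zero; with the default `"free"`
#' mask encoding both directions of every adjacent pair stay open and the
#' continuous score resolves them, while `"enforce"` additionally pins PC's
#' directed edges. Deterministic given data and configuration; no
#' bootstrap.
#'
#' @param x An [expression_matrix()].
#' @param config A [pcnt_config()].
#' @return A [weighted_graph()] of signed effects, with attribute `cpdag`
#'   holding the PC output.
#' @examples
#' truth <- generate_star_dag(sim_config(n_regulators = 2, n_targets = 3,
#'                                       n_samples = 800, seed = 4))
#' x <- simulate_linear_sem(truth, n_samples = 800, seed = 4)
#' run_pcnt(x, pcnt_config())
#' @export
run_pcnt <- function(x, config = pcnt_config()) {
  stopifnot(inherits(config, "pcnt_config"))
  cp <- run_pc(x, alpha = config$alpha, max_cond_size = config$max_cond_size)
  if (all(cp$amat == 0L)) {
    warning("PC returned an empty CPDAG; the hybrid fit is the zero graph")
    out <- weighted_graph(matrix(0, length(cp$gene_ids),
                                 length(cp$gene_ids)), cp$gene_ids)
    attr(out, "converged") <- TRUE
    attr(out, "cpdag") <- cp
    return(out)
  }
  mask <- build_constraint_mask(cp, orientations = config$mask_orientations)
  out <- notears_fit(x, mask = mask, config = config$notears)
  attr(out, "cpdag") <- cp
  out
}

run_single_algorithm <- function(x, algorithm, config) {
  switch(algorithm,
    pc = {
      cp <- run_pc(x, alpha = config$alpha,
                   max_cond_size = config$max_cond_size)
      # binary edge-mark indicator; undirected edges contribute both marks
      weighted_graph(matrix(as.numeric(cp$amat), nrow(cp$amat)),
                     cp$gene_ids)
    },
    notears = notears_fit(x, mask = NULL, config = config$notears),
    pcnt = run_pcnt(x, config),
    stop("unknown algorithm: ", algorithm))
}

#' Bootstrap-aggregate an algorithm's edge estimates
#'
#' Reruns an algorithm `n_bootstrap` times on data resampled with
#' replacement (rows/samples only, never genes) and aggregates the outputs
#' into one weighted graph. For the binary-output algorithm (`pc`) the
#' aggregated weight of an edge is the frequency of its appearance across
#' replicates, in `[0, 1]`. For the weighted-output algorithms (`notears`,
#' `pcnt`) it is the mean of the signed weights, a replicate in which the
#' edge is absent contributing 0. Failed replicates are dropped with a
#' warning and the denominator adjusted; if every replicate fails an error
#' is raised. Finally, if `config$top_k` is set, only the `top_k` edges of
#' largest aggregated absolute weight are kept.
#'
#' For the hybrid method the CPDAG constraint is estimated once, on the
#' original (un-resampled) data, and only the constrained continuous fit is
#' bootstrapped. Conditional-independence tests are not valid on
#' with-replacement resamples (duplicated observations make the tests
#' anti-conservative, yielding spurious v-structures whose wrong
#' orientations would be enforced as hard constraints), and a single
#' constraint-search step is also what keeps the hybrid's cost close to one
#' PC run plus cheap masked fits. The plain `pc` algorithm, whose binary
#' output has no other route to a continuous edge weight, is rerun on every
#' replicate.
#'
#' @param x An [expression_matrix()].
#' @param algorithm One of `"pc"`, `"notears"`, `"pcnt"`, or a function
#'   `f(x, config)` returning a [weighted_graph()] (treated as a
#'   weighted-output algorithm).
#' @param config A [pcnt_config()]; `config$seed` makes the resampling
#'   reproducible (replicate `b` uses `seed + b`).
#' @return A [weighted_graph()] of aggregated edge weights.
#' @export
bootstrap_aggregate <- function(x, algorithm = c("pcnt", "pc", "notears"),
                                config = pcnt_config()) {
  if (!is.function(algorithm)) algorithm <- match.arg(algorithm)
  stopifnot(inherits(config, "pcnt_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  ids <- colnames(x) %||% paste0("gene", seq_len(d))
  colnames(x) <- ids
  acc <- matrix(0, d, d)
  n_ok <- 0L
  failures <- character(0)
  pcnt_mask <- NULL
  if (!is.function(algorithm) && algorithm == "pcnt") {
    cp <- run_pc(expression_matrix(x), alpha = config$alpha,
                 max_cond_size = config$max_cond_size)
    if (all(cp$amat == 0L))
      warning("PC returned an empty CPDAG; all bootstrap fits are zero")
    pcnt_mask <- build_constraint_mask(cp,
                                       orientations = config$mask_orientations)
  }
  for (b in seq_len(config$n_bootstrap)) {
    set.seed(config$seed + b)
    rows <- sample.int(n, n, replace = TRUE)
    xb <- expression_matrix(x[rows, , drop = FALSE],
                            sample_ids = paste0("bs", seq_len(n)),
                            gene_ids = ids)
    res <- tryCatch(
      if (is.function(algorithm)) algorithm(xb, config)
      else if (!is.null(pcnt_mask))
        notears_fit(xb, mask = pcnt_mask, config = config$notears)
      else run_single_algorithm(xb, algorithm, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    W <- res$W
    binary <- !is.function(algorithm) && algorithm == "pc"
    acc <- acc + if (binary) as.numeric(W != 0) else W
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L)
    stop("all ", config$n_bootstrap, " bootstrap replicates failed; first ",
         "error: ", failures[[1L]])
  if (length(failures))
    warning(length(failures), " bootstrap replicate(s) failed and were ",
            "dropped")
  out <- weighted_graph(acc / n_ok, ids)
  if (!is.null(config$top_k)) out <- select_top_k_edges(out, config$top_k)
  out
}
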