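# Synthetic ground truth and linear-SEM expression data emulating the
# sparse, star-like regulator/target structure of biological causal graphs:
# a few regulators (transcription factors, signalling proteins) with many
# downstream targets that themselves regulate nothing.

#' Configuration for the synthetic regulator-target benchmark
#'
#' Defaults describe a sparse star-like graph: each regulator-target pair is
#' connected with probability 0.2, regulator-regulator edges (drawn acyclic
#' on a fixed order) with probability 0.1, edge weights uniform in
#' magnitude 0.5-1.5 with random sign, and unit-variance additive noise.
#'
#' @param n_regulators Number of regulator genes.
#' @param n_targets Number of target genes (zero out-degree).
#' @param p_edge_reg_to_target Probability of each regulator-to-target edge.
#' @param p_edge_reg_to_reg Probability of each (ordered) regulator-to-
#'   regulator edge.
#' @param weight_range Length-2 numeric, magnitude range of edge weights;
#'   bounded away from zero so finite-sample recovery is feasible.
#' @param sign_flip_prob Probability that a weight is negative.
#' @param noise_sd Standard deviation of the structural noise.
#' @param noise_dist `"gaussian"` or `"gumbel"` (centered, scaled to
#'   `noise_sd`).
#' @param n_samples Number of observational samples to simulate.
#' @param seed Integer seed making graph and data generation reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regulators = 5, n_targets = 25,
                       p_edge_reg_to_target = 0.2, p_edge_reg_to_reg = 0.1,
                       weight_range = c(0.5, 1.5), sign_flip_prob = 0.5,
                       noise_sd = 1.0, noise_dist = c("gaussian", "gumbel"),
                       n_samples = 1000, seed = 1) {
  noise_dist <- match.arg(noise_dist)
  stopifnot(n_regulators >= 1, n_targets >= 0,
            p_edge_reg_to_target >= 0, p_edge_reg_to_target <= 1,
            p_edge_reg_to_reg >= 0, p_edge_reg_to_reg <= 1,
            length(weight_range) == 2L, weight_range[1] <= weight_range[2],
            weight_range[1] >= 0, sign_flip_prob >= 0, sign_flip_prob <= 1,
            noise_sd >= 0, n_samples >= 1)
  structure(list(n_regulators = as.integer(n_regulators),
                 n_targets = as.integer(n_targets),
                 p_edge_reg_to_target = p_edge_reg_to_target,
                 p_edge_reg_to_reg = p_edge_reg_to_reg,
                 weight_range = as.numeric(weight_range),
                 sign_flip_prob = sign_flip_prob,
                 noise_sd = noise_sd, noise_dist = noise_dist,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a star-like ground-truth DAG
#'
#' Regulator-to-regulator edges are drawn on an upper-triangular order
#' (hence acyclic) with probability `p_edge_reg_to_reg`; regulator-to-target
#' edges with probability `p_edge_reg_to_target`; targets never have
#' outgoing edges. Weights are uniform in `+/- weight_range`. Regulator
#' labels mark the regulator block regardless of realized degree.
#'
#' @param cfg A [sim_config()].
#' @return A [ground_truth_graph()] with genes `R1..` (regulators) and
#'   `T1..` (targets).
#' @export
generate_star_dag <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  R <- cfg$n_regulators
  Tn <- cfg$n_targets
  d <- R + Tn
  ids <- c(paste0("R", seq_len(R)),
           if (Tn > 0) paste0("T", seq_len(Tn)))
  W <- matrix(0, d, d)
  draw_weight <- function(k) {
    mag <- stats::runif(k, cfg$weight_range[1], cfg$weight_range[2])
    sgn <- ifelse(stats::runif(k) < cfg$sign_flip_prob, -1, 1)
    mag * sgn
  }
  if (R >= 2) {
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        if (stats::runif(1) < cfg$p_edge_reg_to_reg)
          W[i, j] <- draw_weight(1L)
      }
    }
  }
  if (Tn > 0) {
    for (i in seq_len(R)) {
      for (j in seq_len(Tn)) {
        if (stats::runif(1) < cfg$p_edge_reg_to_target)
          W[i, R + j] <- draw_weight(1L)
      }
    }
  }
  ground_truth_graph(W, regulator_labels = c(rep(TRUE, R), rep(FALSE, Tn)),
                     gene_ids = ids)
}

topological_order <- function(A) {
  d <- nrow(A)
  in_deg <- colSums(A != 0)
  queue <- which(in_deg == 0L)
  ord <- integer(0)
  A <- A != 0
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, v)
    ch <- which(A[v, ])
    if (length(ch)) {
      A[v, ch] <- FALSE
      in_deg[ch] <- in_deg[ch] - 1L
      queue <- c(queue, ch[in_deg[ch] == 0L])
    }
  }
  if (length(ord) != d) stop("graph is cyclic; no topological order exists")
  ord
}

#' Simulate observational data from a linear structural equation model
#'
#' In topological order, `X[, j] = sum_i W[i, j] X[, i] + eps_j` with i.i.d.
#' additive noise of standard deviation `noise_sd`, either Gaussian or
#' (centered, rescaled) Gumbel.
#'
#' @param truth A [ground_truth_graph()] (or `weighted_graph`); its support
#'   must be acyclic.
#' @param n_samples Number of samples (rows); defaults from `cfg`.
#' @param noise_sd,noise_dist Noise scale and family; default from `cfg`.
#' @param seed Integer seed; default from `cfg`.
#' @param cfg Optional [sim_config()] supplying defaults.
#' @return An [expression_matrix()] of dimension `n_samples x d`.
#' @export
simulate_linear_sem <- function(truth, n_samples = NULL, noise_sd = NULL,
                                noise_dist = NULL, seed = NULL, cfg = NULL) {
  W <- as_weight_matrix(truth)
  ids <- gene_ids_of(truth) %||% paste0("gene", seq_len(nrow(W)))
  if (!is_acyclic(W)) stop("truth graph must be acyclic")
  n_samples <- n_samples %||% cfg$n_samples %||% 1000L
  noise_sd <- noise_sd %||% cfg$noise_sd %||% 1.0
  noise_dist <- noise_dist %||% cfg$noise_dist %||% "gaussian"
  seed <- seed %||% cfg$seed %||% 1L
  d <- nrow(W)
  set.seed(seed)
  draw_noise <- function(n) {
    if (noise_dist == "gaussian") {
      stats::rnorm(n, sd = noise_sd)
    } else {  # gumbel, centered and scaled to sd = noise_sd
      beta <- noise_sd * sqrt(6) / pi
      u <- stats::runif(n)
      g <- -beta * log(-log(u))
      g - beta * 0.5772156649015329  # subtract the mean (Euler-Mascheroni)
    }
  }
  X <- matrix(0, n_samples, d)
  for (j in topological_order(W)) {
    parents <- which(W[, j] != 0)
    mu <- if (length(parents))
      X[, parents, drop = FALSE] %*% W[parents, j] else 0
    X[, j] <- mu + draw_noise(n_samples)
  }
  expression_matrix(X, gene_ids = ids)
}

#' Run the full synthetic benchmark protocol
#'
#' Generates a ground-truth graph, samples induced subgraphs (regulators +
#' targets), simulates observational data from each subgraph, runs the
#' requested algorithms with bootstrap aggregation, standardizes the edge
#' count by top-k selection, and evaluates each output against the subgraph
#' truth.
#'
#' When the generated graph has exactly `n_regulators_sub` regulators and
#' `n_targets_sub` targets every repeat uses the full graph (with freshly
#' simulated data).
#'
#' @param cfg A [sim_config()] describing the ground truth and the data.
#' @param methods Character subset of `c("pc", "notears", "pcnt")`.
#' @param pcnt_cfg A [pcnt_config()] holding algorithm settings (its `top_k`
#'   is applied after aggregation).
#' @param n_regulators_sub,n_targets_sub,n_repeats Subsampling protocol
#'   (defaults 5 regulators + 25 targets, 20 repeats).
#' @return A `data.frame` with one row per (repeat, method) holding every
#'   evaluation metric.
#' @export
run_benchmark <- function(cfg, methods = c("pc", "notears", "pcnt"),
                          pcnt_cfg = pcnt_config(),
                          n_regulators_sub = 5, n_targets_sub = 25,
                          n_repeats = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- generate_star_dag(cfg)
  subs <- subsample_ground_truth(truth, n_regulators = n_regulators_sub,
                                 n_targets = n_targets_sub,
                                 n_repeats = n_repeats, seed = cfg$seed)
  rows <- list()
  for (r in seq_along(subs)) {
    sub_truth <- subs[[r]]
    x <- simulate_linear_sem(sub_truth, n_samples = cfg$n_samples,
                             noise_sd = cfg$noise_sd,
                             noise_dist = cfg$noise_dist,
                             seed = cfg$seed + 7919L * r)
    for (m in methods) {
      run_cfg <- pcnt_cfg
      run_cfg$seed <- pcnt_cfg$seed + 104729L * r
      res <- tryCatch({
        g <- bootstrap_aggregate(x, algorithm = m, config = run_cfg)
        rep_eval <- evaluate_graph(g, sub_truth)
        cbind(data.frame(repeat_id = r, method = m,
                         stringsAsFactors = FALSE),
              as.data.frame(rep_eval))
      }, error = function(e) {
        data.frame(repeat_id = r, method = m, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
    df[cols]
  })
  do.call(rbind, rows)
}
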