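# PC-stable causal discovery: Gaussian conditional-independence skeleton
# search, v-structure orientation, and Meek rules, producing a CPDAG.

pair_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

partial_cor_from_corr <- function(C, i, j, S) {
  if (length(S) == 0L) return(C[i, j])
  idx <- c(i, j, S)
  P <- tryCatch(solve(C[idx, idx, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(P)) return(1)  # singular submatrix: treat as full dependence
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' Fisher-z conditional-independence test
#'
#' Tests independence of genes `i` and `j` given the conditioning set `S`
#' under the Gaussian model. The partial correlation `r` is computed from the
#' inverse of the relevant submatrix of the correlation matrix; the Fisher
#' transform `z = atanh(r)` is compared against a standard normal after
#' scaling by `sqrt(n - |S| - 3)`.
#'
#' If `|r|` is numerically 1 (e.g. duplicated columns) it is clamped just
#' below 1 and dependence is flagged. If `n <= |S| + 3` the test is
#' uninformative: it is skipped with a warning and treated as dependence
#' (the edge is kept).
#'
#' @param x An [expression_matrix()] (or plain numeric matrix).
#' @param i,j Column indices of the two genes (1-based), `i != j`.
#' @param S Integer vector of conditioning-gene indices, disjoint from
#'   `c(i, j)`. Default empty.
#' @param alpha Significance level; independence is declared when
#'   `p_value > alpha`.
#' @return A list with `partial_corr`, `statistic`, `p_value`, `independent`.
#' @examples
#' x <- expression_matrix(matrix(rnorm(200), 100, 2))
#' fisher_z_test(x, 1, 2)
#' @export
fisher_z_test <- function(x, i, j, S = integer(0), alpha = 0.05) {
  x <- as.matrix(x)
  S <- as.integer(S)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("i and j must differ")
  if (i %in% S || j %in% S) stop("S must not contain i or j")
  n <- nrow(x)
  if (n <= length(S) + 3L) {
    warning("n = ", n, " too small for |S| = ", length(S),
            "; test skipped, edge kept")
    return(list(partial_corr = NA_real_, statistic = NA_real_,
                p_value = 0, independent = FALSE))
  }
  C <- stats::cor(x)
  fisher_z_from_corr(C, n, i, j, S, alpha)
}

# Internal work-horse sharing one precomputed correlation matrix.
fisher_z_from_corr <- function(C, n, i, j, S, alpha) {
  r <- partial_cor_from_corr(C, i, j, S)
  clamped <- FALSE
  if (!is.finite(r) || abs(r) >= 1) {
    r <- sign(ifelse(is.finite(r) && r != 0, r, 1)) * (1 - .Machine$double.eps)
    clamped <- TRUE
  }
  z <- atanh(r)
  stat <- sqrt(n - length(S) - 3) * abs(z)
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  list(partial_corr = r, statistic = stat, p_value = p,
       independent = !clamped && p > alpha)
}

#' Learn the undirected skeleton with the stable PC adjacency search
#'
#' Starts from the complete undirected graph and, for conditioning-set sizes
#' `l = 0, 1, ..., max_cond_size`, tests each ordered adjacent pair `(i, j)`
#' against every size-`l` subset of the neighbours of `i` (excluding `j`),
#' with the neighbour sets frozen at the start of each level (the
#' order-independent "stable" variant). The first conditioning set that
#' renders a pair independent removes the edge and is recorded as the pair's
#' separation set.
#'
#' @inheritParams fisher_z_test
#' @param alpha Significance level of the Fisher-z tests, in (0, 1).
#' @param max_cond_size Largest conditioning-set size to try.
#' @return A list with `adjacency` (symmetric logical matrix) and `sepsets`
#'   (environment keyed by `"i-j"`, `i < j`, holding the separating set).
#' @export
learn_skeleton <- function(x, alpha = 0.05, max_cond_size = 3) {
  x <- as.matrix(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  n <- nrow(x)
  d <- ncol(x)
  C <- stats::cor(x)
  adj <- matrix(TRUE, d, d)
  diag(adj) <- FALSE
  sepsets <- new.env(parent = emptyenv())
  small_n_warned <- FALSE

  for (l in 0:max_cond_size) {
    if (n <= l + 3L) {
      if (!small_n_warned) {
        warning("n = ", n, " too small for conditioning sets of size ", l,
                "; tests at this level skipped, edges kept")
        small_n_warned <- TRUE
      }
      break
    }
    adj_frozen <- adj
    any_testable <- FALSE
    for (i in seq_len(d)) {
      nbrs_i <- which(adj_frozen[i, ])
      for (j in nbrs_i) {
        if (!adj[i, j]) next  # removed earlier at this level
        cand <- setdiff(nbrs_i, j)
        if (length(cand) < l) next
        any_testable <- TRUE
        subsets <- if (l == 0L) list(integer(0)) else
          utils::combn(cand, l, simplify = FALSE)
        for (S in subsets) {
          res <- fisher_z_from_corr(C, n, i, j, S, alpha)
          if (res$independent) {
            adj[i, j] <- adj[j, i] <- FALSE
            assign(pair_key(i, j), as.integer(S), envir = sepsets)
            break
          }
        }
      }
    }
    if (!any_testable) break
  }
  dimnames(adj) <- list(colnames(x), colnames(x))
  list(adjacency = adj, sepsets = sepsets)
}

#' Orient v-structures in a skeleton
#'
#' For every unshielded triple `i - k - j` (with `i`, `j` non-adjacent),
#' orients `i -> k <- j` iff `k` is not in the separating set recorded for
#' `{i, j}`. If two triples assert opposite directions for the same edge the
#' edge is left undirected (the conservative resolution: an unsupported
#' direction is never asserted).
#'
#' @param skeleton Result of [learn_skeleton()].
#' @return A partially directed graph as a `cpdag`-encoded adjacency matrix
#'   (not yet Meek-closed).
#' @export
orient_v_structures <- function(skeleton) {
  adj <- skeleton$adjacency
  sepsets <- skeleton$sepsets
  d <- nrow(adj)
  amat <- matrix(0L, d, d, dimnames = dimnames(adj))
  amat[adj] <- 1L

  # collect arrow assertions parent -> child across all unshielded triples
  arrows <- matrix(FALSE, d, d)
  for (k in seq_len(d)) {
    nbrs <- which(adj[k, ])
    if (length(nbrs) < 2L) next
    for (a in seq_len(length(nbrs) - 1L)) {
      for (b in (a + 1L):length(nbrs)) {
        i <- nbrs[a]; j <- nbrs[b]
        if (adj[i, j]) next  # shielded
        key <- pair_key(i, j)
        if (!exists(key, envir = sepsets, inherits = FALSE))
          stop("internal inconsistency: no separation set for non-adjacent ",
               "pair (", i, ", ", j, ")")
        S <- get(key, envir = sepsets)
        if (!(k %in% S)) {
          arrows[i, k] <- TRUE
          arrows[j, k] <- TRUE
        }
      }
    }
  }
  one_way <- arrows & !t(arrows)  # conflicting pairs stay undirected
  amat[t(one_way) & amat == 1L] <- 0L
  amat
}

# Does the pdag have a directed edge a -> b? (encoding: amat[a,b]=1, amat[b,a]=0)
.directed <- function(amat, a, b) amat[a, b] == 1L & amat[b, a] == 0L
.undirected <- function(amat, a, b) amat[a, b] == 1L & amat[b, a] == 1L
.adjacent <- function(amat, a, b) amat[a, b] == 1L | amat[b, a] == 1L

#' Apply the Meek orientation rules
#'
#' Propagates edge orientations in a partially directed graph to its maximal
#' closure without creating directed cycles or new v-structures, using the
#' four standard rules: (R1) `a -> b`, `b - c`, `a`,`c` non-adjacent gives
#' `b -> c`; (R2) `a -> b -> c`, `a - c` gives `a -> c`; (R3) `a - b`,
#' `a - c`, `a - d`, `c -> b`, `d -> b`, `c`,`d` non-adjacent gives
#' `a -> b`; (R4) `a - b`, `a - c`, `c -> d`, `d -> b`, `c`,`b` non-adjacent
#' gives `a -> b`.
#'
#' @param pdag Partially directed adjacency matrix from
#'   [orient_v_structures()].
#' @param gene_ids Optional gene labels for the returned object.
#' @return A [cpdag()] that is maximally oriented.
#' @export
apply_meek_rules <- function(pdag, gene_ids = NULL) {
  amat <- pdag
  d <- nrow(amat)
  repeat {
    changed <- FALSE
    und <- which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)
    # iterate over ordered undirected pairs (x, y); try to orient x -> y
    for (r in seq_len(nrow(und))) {
      x <- und[r, 1L]; y <- und[r, 2L]
      if (!.undirected(amat, x, y)) next
      orient <- FALSE
      # R1: z -> x, z and y non-adjacent
      for (z in seq_len(d)) {
        if (z != y && .directed(amat, z, x) && !.adjacent(amat, z, y)) {
          orient <- TRUE; break
        }
      }
      # R2: x -> z -> y
      if (!orient) {
        for (z in seq_len(d)) {
          if (.directed(amat, x, z) && .directed(amat, z, y)) {
            orient <- TRUE; break
          }
        }
      }
      # R3: x - z, x - w, z -> y, w -> y, z and w non-adjacent
      if (!orient) {
        zs <- which(vapply(seq_len(d), function(z)
          z != y && .undirected(amat, x, z) && .directed(amat, z, y), TRUE))
        if (length(zs) >= 2L) {
          for (a in seq_len(length(zs) - 1L)) {
            for (b in (a + 1L):length(zs)) {
              if (!.adjacent(amat, zs[a], zs[b])) { orient <- TRUE; break }
            }
            if (orient) break
          }
        }
      }
      # R4: x - z, z -> w, w -> y, z and y non-adjacent
      if (!orient) {
        for (z in seq_len(d)) {
          if (z == y || !.undirected(amat, x, z) || .adjacent(amat, z, y))
            next
          for (w in seq_len(d)) {
            if (w != x && .directed(amat, z, w) && .directed(amat, w, y)) {
              orient <- TRUE; break
            }
          }
          if (orient) break
        }
      }
      if (orient) {
        amat[y, x] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cpdag(amat, gene_ids %||% colnames(amat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full PC algorithm
#'
#' Composition of [learn_skeleton()], [orient_v_structures()] and
#' [apply_meek_rules()]: the constraint-based search that estimates the
#' Markov equivalence class (CPDAG) of the causal DAG from observational
#' data. Deterministic given the data and parameters.
#'
#' @inheritParams learn_skeleton
#' @return A [cpdag()].
#' @examples
#' truth <- generate_star_dag(sim_config(n_regulators = 2, n_targets = 3,
#'                                       n_samples = 500, seed = 1))
#' x <- simulate_linear_sem(truth, n_samples = 500, seed = 1)
#' run_pc(x, alpha = 0.01)
#' @export
run_pc <- function(x, alpha = 0.05, max_cond_size = 3) {
  skel <- learn_skeleton(x, alpha = alpha, max_cond_size = max_cond_size)
  pdag <- orient_v_structures(skel)
  apply_meek_rules(pdag, gene_ids = colnames(skel$adjacency))
}
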