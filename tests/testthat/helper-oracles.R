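# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the implementation it checks.

# All 3-node directed support patterns (64), as 3x3 0/1 matrices.
all_3node_digraphs <- function() {
  arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  lapply(0:63, function(code) {
    A <- matrix(0, 3, 3)
    for (b in 1:6) if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0)
      A[arcs[b, 1L], arcs[b, 2L]] <- 1
    A
  })
}

# Exhaustive cycle check: a digraph has a cycle iff some power of the
# adjacency matrix has a nonzero diagonal entry.
has_cycle_bruteforce <- function(A) {
  A <- (A != 0) * 1
  P <- A
  for (k in seq_len(nrow(A))) {
    if (any(diag(P) != 0)) return(TRUE)
    P <- P %*% A
  }
  FALSE
}

# Truncated power series for the matrix exponential (independent of
# arma::expmat).
expm_series <- function(M, terms = 60) {
  d <- nrow(M)
  out <- diag(d)
  term <- diag(d)
  for (k in seq_len(terms)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# Brute-force minimal-edit SHD: breadth-first search in the space of
# digraph supports, moves = add arc, delete arc, reverse existing arc.
shd_bruteforce <- function(A, B) {
  enc <- function(M) paste(as.integer(M != 0), collapse = "")
  d <- nrow(A)
  target <- enc(B)
  frontier <- list(A != 0)
  seen <- enc(A)
  dist <- 0L
  if (seen == target) return(0L)
  seen <- c(seen)
  repeat {
    dist <- dist + 1L
    nxt <- list()
    for (M in frontier) {
      for (i in seq_len(d)) for (j in seq_len(d)) {
        if (i == j) next
        moves <- list()
        M1 <- M; M1[i, j] <- !M1[i, j]          # add or delete
        moves[[1]] <- M1
        if (M[i, j] && !M[j, i]) {               # reverse
          M2 <- M; M2[i, j] <- FALSE; M2[j, i] <- TRUE
          moves[[2]] <- M2
        }
        for (Mn in moves) {
          key <- enc(Mn)
          if (key == target) return(dist)
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            nxt[[length(nxt) + 1L]] <- Mn
          }
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) stop("BFS exhausted without reaching target")
  }
}

# Trapezoidal AUROC: integrate the ROC curve over all distinct thresholds.
auroc_trapezoid <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  tpr <- c(0, vapply(ths, function(t) sum(scores >= t & labels) / n_pos, 0))
  fpr <- c(0, vapply(ths, function(t) sum(scores >= t & !labels) / n_neg, 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Simulate a named linear SEM directly (independent of simulate_linear_sem)
# for hand-built structures; columns are filled parents-first.
sem_data_manual <- function(W, n, seed, ids = NULL) {
  set.seed(seed)
  d <- nrow(W)
  X <- matrix(0, n, d)
  done <- rep(FALSE, d)
  while (!all(done)) {
    progressed <- FALSE
    for (j in seq_len(d)) {
      if (done[j]) next
      parents <- which(W[, j] != 0)
      if (all(done[parents])) {
        X[, j] <- X %*% W[, j] + stats::rnorm(n)
        done[j] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cyclic W in sem_data_manual")
  }
  colnames(X) <- ids %||% paste0("g", seq_len(d))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DAG on d nodes: random permutation order, edge prob p, weights
# uniform +/-[0.5, 2]
random_dag <- function(d, p, seed) {
  set.seed(seed)
  ord <- sample(d)
  W <- matrix(0, d, d)
  for (a in seq_len(d - 1L)) for (b in (a + 1L):d) {
    if (stats::runif(1) < p) {
      w <- stats::runif(1, 0.5, 2) * sample(c(-1, 1), 1)
      W[ord[a], ord[b]] <- w
    }
  }
  W
}

collider_truth <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  W["X", "Y"] <- 1
  W["Z", "Y"] <- 1
  ground_truth_graph(W)
}

chain_truth <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  W["X", "Y"] <- 1
  W["Y", "Z"] <- 1
  ground_truth_graph(W)
}
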