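test_that("fisher_z_test matches the closed-form transform and normal tail", {
  # build data whose sample correlation is exactly known: r = 0.5, n = 100
  # via two columns with controlled empirical correlation
  set.seed(1)
  n <- 100
  u <- scale(stats::rnorm(n))[, 1]
  v <- scale(stats::resid(stats::lm(stats::rnorm(n) ~ u)))[, 1]
  r_target <- 0.5
  y <- r_target * u + sqrt(1 - r_target^2) * v
  x <- expression_matrix(cbind(a = u, b = y, c = stats::rnorm(n)))
  res <- fisher_z_test(x, 1, 2, integer(0), alpha = 0.05)
  expect_equal(res$partial_corr, 0.5, tolerance = 1e-10)
  # z = atanh(0.5) = 0.549306, statistic = z * sqrt(97)
  expect_equal(res$statistic, 0.5493061 * sqrt(97), tolerance = 1e-6)
  expect_equal(res$p_value, 2 * (1 - stats::pnorm(atanh(0.5) * sqrt(97))),
               tolerance = 1e-9)
  expect_false(res$independent)

  # r exactly 0: z = 0, statistic = 0, p = 1
  y0 <- v  # orthogonal to u by construction
  x0 <- expression_matrix(cbind(a = u, b = y0, c = stats::rnorm(n)))
  res0 <- fisher_z_test(x0, 1, 2)
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-10)
  expect_true(res0$independent)

  # duplicated column: clamped r, dependence flagged
  xd <- expression_matrix(cbind(a = u, b = u, c = stats::rnorm(n)))
  resd <- fisher_z_test(xd, 1, 2)
  expect_false(resd$independent)
  expect_lt(abs(resd$partial_corr), 1)

  # n too small for the conditioning set: warned, treated as dependent
  xs <- expression_matrix(matrix(stats::rnorm(5 * 6), 5, 6))
  expect_warning(ress <- fisher_z_test(xs, 1, 2, S = 3:5), "skipped")
  expect_false(ress$independent)

  expect_error(fisher_z_test(x, 1, 1), "differ")
  expect_error(fisher_z_test(x, 1, 2, S = 1), "must not contain")
})

test_that("skeleton search separates chains and colliders correctly", {
  # chain X -> Y -> Z: skeleton X-Y-Z, X and Z separated by {Y}
  x <- sem_data_manual(chain_truth()$W_true, 5000, seed = 11,
                       ids = c("X", "Y", "Z"))
  sk <- learn_skeleton(expression_matrix(x), alpha = 0.01)
  expect_identical(unname(sk$adjacency),
                   matrix(c(FALSE, TRUE, FALSE,
                            TRUE, FALSE, TRUE,
                            FALSE, TRUE, FALSE), 3, 3))
  expect_identical(get("1-3", envir = sk$sepsets), 2L)

  # collider X -> Y <- Z: same skeleton, X and Z marginally independent
  xc <- sem_data_manual(collider_truth()$W_true, 5000, seed = 12,
                        ids = c("X", "Y", "Z"))
  skc <- learn_skeleton(expression_matrix(xc), alpha = 0.01)
  expect_identical(unname(skc$adjacency),
                   matrix(c(FALSE, TRUE, FALSE,
                            TRUE, FALSE, TRUE,
                            FALSE, TRUE, FALSE), 3, 3))
  expect_identical(get("1-3", envir = skc$sepsets), integer(0))

  # mutually independent columns: empty skeleton at large n
  set.seed(13)
  xi <- expression_matrix(matrix(stats::rnorm(2000 * 3), 2000, 3))
  ski <- learn_skeleton(xi, alpha = 0.01)
  expect_true(all(!ski$adjacency))
})

test_that("v-structure orientation uses separation sets, conservatively", {
  xc <- sem_data_manual(collider_truth()$W_true, 5000, seed = 14,
                        ids = c("X", "Y", "Z"))
  skc <- learn_skeleton(expression_matrix(xc), alpha = 0.01)
  pdag <- orient_v_structures(skc)
  # X -> Y <- Z: edge marks at Y from X and from Z, none backwards
  expect_identical(unname(pdag),
                   matrix(c(0L, 1L, 0L,
                            0L, 0L, 0L,
                            0L, 1L, 0L), 3, 3, byrow = TRUE))

  # chain: Y is in the separating set, edges stay undirected
  x <- sem_data_manual(chain_truth()$W_true, 5000, seed = 15,
                       ids = c("X", "Y", "Z"))
  sk <- learn_skeleton(expression_matrix(x), alpha = 0.01)
  pd <- orient_v_structures(sk)
  expect_identical(pd, t(pd))

  # no unshielded triple: a single edge is untouched
  adj <- matrix(FALSE, 2, 2); adj[1, 2] <- adj[2, 1] <- TRUE
  sk1 <- list(adjacency = adj, sepsets = new.env())
  expect_identical(unname(orient_v_structures(sk1)),
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # conflicting orientations leave the edge undirected: two triples
  # disagreeing about edge b-c is simulated directly through sepsets
  adj2 <- matrix(FALSE, 4, 4)
  # a - c, b - c, b - d with a-b, a-d, c-d missing
  adj2[1, 3] <- adj2[3, 1] <- TRUE
  adj2[2, 3] <- adj2[3, 2] <- TRUE
  adj2[2, 4] <- adj2[4, 2] <- TRUE
  sep <- new.env()
  assign("1-2", integer(0), envir = sep)   # a _|_ b not given c => a->c<-b
  assign("3-4", integer(0), envir = sep)   # c _|_ d not given b => c->b<-d
  assign("1-4", integer(0), envir = sep)
  pd2 <- orient_v_structures(list(adjacency = adj2, sepsets = sep))
  # edge b-c is claimed b->c (first triple) and c->b (second): stays
  # undirected
  expect_identical(pd2[2, 3], 1L)
  expect_identical(pd2[3, 2], 1L)
  # a->c survives (no conflict)
  expect_identical(pd2[1, 3], 1L)
  expect_identical(pd2[3, 1], 0L)

  # missing separation set for a non-adjacent pair is an internal error
  sep_bad <- new.env()
  expect_error(orient_v_structures(list(adjacency = adj2,
                                        sepsets = sep_bad)),
               "separation set")
})

test_that("Meek rules orient the textbook configurations", {
  # R1: a -> b, b - c, a and c non-adjacent => b -> c
  am <- matrix(0L, 3, 3)
  am[1, 2] <- 1L
  am[2, 3] <- am[3, 2] <- 1L
  out <- apply_meek_rules(am)$amat
  expect_identical(unname(out[2, 3]), 1L)
  expect_identical(unname(out[3, 2]), 0L)

  # R2: a -> b -> c with a - c => a -> c
  am2 <- matrix(0L, 3, 3)
  am2[1, 2] <- 1L; am2[2, 3] <- 1L
  am2[1, 3] <- am2[3, 1] <- 1L
  out2 <- apply_meek_rules(am2)$amat
  expect_identical(unname(out2[1, 3]), 1L)
  expect_identical(unname(out2[3, 1]), 0L)

  # fully undirected triangle: no rule fires
  am3 <- matrix(1L, 3, 3); diag(am3) <- 0L
  expect_identical(apply_meek_rules(am3)$amat, cpdag(am3)$amat)

  # R3: a-b, a-c, a-d, c->b, d->b, c/d non-adjacent => a->b
  am4 <- matrix(0L, 4, 4)  # nodes a=1,b=2,c=3,d=4
  am4[1, 2] <- am4[2, 1] <- 1L
  am4[1, 3] <- am4[3, 1] <- 1L
  am4[1, 4] <- am4[4, 1] <- 1L
  am4[3, 2] <- 1L
  am4[4, 2] <- 1L
  out4 <- apply_meek_rules(am4)$amat
  expect_identical(unname(out4[1, 2]), 1L)
  expect_identical(unname(out4[2, 1]), 0L)
})

test_that("run_pc recovers the collider exactly and the chain up to equivalence", {
  hits <- 0L
  for (s in 1:20) {
    x <- sem_data_manual(collider_truth()$W_true, 10000, seed = 100 + s,
                         ids = c("X", "Y", "Z"))
    cp <- run_pc(expression_matrix(x), alpha = 0.01)
    want <- matrix(0L, 3, 3, dimnames = dimnames(cp$amat))
    want["X", "Y"] <- 1L; want["Z", "Y"] <- 1L
    if (identical(cp$amat, want)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  # chain data: undirected X - Y - Z (Markov equivalence class)
  x <- sem_data_manual(chain_truth()$W_true, 5000, seed = 21,
                       ids = c("X", "Y", "Z"))
  cp <- run_pc(expression_matrix(x), alpha = 0.01)
  want <- matrix(0L, 3, 3, dimnames = dimnames(cp$amat))
  want["X", "Y"] <- want["Y", "X"] <- 1L
  want["Y", "Z"] <- want["Z", "Y"] <- 1L
  expect_identical(cp$amat, want)

  # two independent columns: empty CPDAG
  set.seed(30)
  xi <- expression_matrix(matrix(stats::rnorm(4000), 2000, 2))
  expect_true(all(run_pc(xi, alpha = 0.01)$amat == 0L))
})

test_that("PC output is order invariant (stable variant)", {
  cfg <- sim_config(n_regulators = 3, n_targets = 6, n_samples = 800,
                    seed = 5)
  truth <- generate_star_dag(cfg)
  x <- simulate_linear_sem(truth, cfg = cfg)
  cp <- run_pc(x, alpha = 0.05)
  set.seed(99)
  perm <- sample(ncol(x))
  xp <- expression_matrix(unclass(x)[, perm], gene_ids = colnames(x)[perm])
  cpp <- run_pc(xp, alpha = 0.05)
  # un-permute and compare
  inv <- order(perm)
  expect_identical(unname(cpp$amat[inv, inv]), unname(cp$amat))
})

test_that("PC on a single-hub star recovers the undirected equivalence class", {
  # one regulator with 5 targets: every target pair is an unshielded
  # triple whose separating set contains the regulator, so no v-structure;
  # but target-target marginal dependence separates only given the hub.
  W <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  W[1, 2:6] <- 1
  x <- sem_data_manual(W, 5000, seed = 77, ids = paste0("g", 1:6))
  cp <- run_pc(expression_matrix(x), alpha = 0.01)
  # all five adjacencies recovered
  adj <- (cp$amat | t(cp$amat))
  expect_identical(unname(adj[1, 2:6]), rep(TRUE, 5))
  # the hub-target edges belong to a Markov equivalence class with no
  # v-structure, so they stay undirected
  expect_identical(cp$amat, t(cp$amat))
})

test_that("skeleton error rate on random 5-node DAGs is consistent with alpha", {
  # regression-style check: with strong edges and n = 5000 the recovered
  # skeleton equals the true skeleton in the vast majority of seeded runs
  n_exact <- 0L
  n_runs <- 25L
  for (s in seq_len(n_runs)) {
    W <- random_dag(5, 0.4, seed = 300 + s)
    truth <- ground_truth_graph(W)
    x <- simulate_linear_sem(truth, n_samples = 5000, seed = 400 + s)
    sk <- learn_skeleton(x, alpha = 0.01)
    if (identical(unname(sk$adjacency), unname(W != 0 | t(W) != 0)))
      n_exact <- n_exact + 1L
  }
  expect_gte(n_exact, 20L)
})
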