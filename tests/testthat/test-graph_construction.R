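test_that("affinity formulas match their closed forms", {
  # collinear vectors have cosine 1
  X <- rbind(c(1, 1), c(2, 2))
  expect_equal(compute_affinity(X, "cosine")$values[1, 2], 1.0)
  # perfect anticorrelation
  X <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(compute_affinity(X, "pearson")$values[1, 2], -1.0)
  # rbf at squared distance 2*sigma^2 is exp(-1)
  sigma <- 1.3
  X <- rbind(c(0, 0), c(sqrt(2) * sigma, 0))
  expect_equal(compute_affinity(X, "rbf", sigma = sigma)$values[1, 2],
               exp(-1), tolerance = 1e-12)
})

test_that("affinity matrices are symmetric with bounded entries", {
  set.seed(3)
  X <- matrix(rnorm(8 * 10), 8, 10)
  for (m in c("cosine", "pearson")) {
    S <- compute_affinity(X, m)$values
    expect_equal(S, t(S))
    expect_true(all(S >= -1 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, 8))
  }
  S <- compute_affinity(X, "rbf", sigma = 2)$values
  expect_true(all(S > 0 & S <= 1))
  expect_equal(S, t(S))
})

test_that("degenerate features get zero affinity, with a warning", {
  X <- rbind(c(0, 0, 0), c(1, 2, 3))
  expect_warning(a <- compute_affinity(X, "cosine"), "zero-norm")
  expect_equal(a$values[1, 2], 0)
  X2 <- rbind(c(5, 5, 5), c(1, 2, 3))
  expect_warning(a2 <- compute_affinity(X2, "pearson"), "zero-variance")
  expect_equal(a2$values[1, 2], 0)
  expect_error(compute_affinity(X, "rbf", sigma = -1), "sigma")
})

test_that("thresholding keeps only strong off-diagonal affinities", {
  set.seed(4)
  X <- matrix(rnorm(6 * 12), 6, 12)
  aff <- compute_affinity(X, "cosine")
  # threshold above the max cosine empties the graph
  expect_equal(sum(threshold_graph(aff, 1.1)$adjacency), 0)
  # direct comparison on a hand-built matrix
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.8; S[1, 3] <- S[3, 1] <- 0.2
  g <- threshold_graph(S, 0.5)
  expect_equal(unname(g$adjacency),
               rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  # symmetry is preserved and the diagonal stays zero
  g2 <- threshold_graph(aff, 0.1)
  expect_equal(g2$adjacency, t(g2$adjacency))
  expect_true(all(diag(g2$adjacency) == 0))
})

test_that("raising the threshold never adds an edge", {
  set.seed(5)
  X <- matrix(rnorm(10 * 8), 10, 8)
  aff <- compute_affinity(X, "pearson")
  eps_grid <- seq(-0.5, 0.9, by = 0.2)
  prev <- threshold_graph(aff, eps_grid[1])$adjacency
  for (e in eps_grid[-1]) {
    cur <- threshold_graph(aff, e)$adjacency
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("automatic threshold lands in the target degree band", {
  set.seed(6)
  X <- matrix(rnorm(40 * 30), 40, 30)
  aff <- compute_affinity(X, "cosine")
  eps <- choose_epsilon(aff, target_degree = 10)
  A <- threshold_graph(aff, eps)$adjacency
  expect_gte(median(rowSums(A)), 3)
  expect_lte(median(rowSums(A)), 30)
})

test_that("symmetric renormalization matches hand calculations", {
  # isolated node: self-loop only
  expect_equal(normalize_sym(matrix(0, 1, 1))$values,
               matrix(1, 1, 1), ignore_attr = TRUE)
  # one edge: row sums of A + I are 2
  Ahat <- normalize_sym(rbind(c(0, 1), c(1, 0)))$values
  expect_equal(unname(Ahat), matrix(0.5, 2, 2))
  expect_error(normalize_sym(rbind(c(0, 1), c(0, 0))), "symmetric")
})

test_that("normalized graphs are symmetric with spectral radius <= 1", {
  set.seed(7)
  for (i in 1:20) {
    d <- sample(1:12, 1)
    Ahat <- normalize_sym(random_adjacency(d))$values
    expect_equal(Ahat, t(Ahat))
    ev <- eigen(Ahat, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-8)
    expect_true(all(is.finite(Ahat)))
  }
})

test_that("normalization is equivariant under feature permutation", {
  set.seed(8)
  A <- random_adjacency(9)
  perm <- sample(9)
  direct <- normalize_sym(A[perm, perm])$values
  permuted <- normalize_sym(A)$values[perm, perm]
  expect_equal(direct, permuted, ignore_attr = TRUE)
})

test_that("bipartite normalization extracts transpose-consistent blocks", {
  # single edge between two singleton sets: joint degrees are 2
  nb <- assemble_and_normalize_bipartite(matrix(1, 1, 1))
  expect_equal(unname(nb$hat_Bu), matrix(0.5, 1, 1))
  expect_equal(unname(nb$hat_Bv), matrix(0.5, 1, 1))
  # empty incidence: zero blocks
  nb0 <- assemble_and_normalize_bipartite(matrix(0, 3, 2))
  expect_true(all(nb0$hat_Bu == 0) && all(nb0$hat_Bv == 0))
  # transpose property and joint-normalization agreement on random graphs
  set.seed(9)
  for (i in 1:10) {
    p <- sample(1:8, 1); q <- sample(1:8, 1)
    B <- random_incidence(p, q)
    nb <- assemble_and_normalize_bipartite(B)
    expect_lt(max(abs(nb$hat_Bv - t(nb$hat_Bu))), 1e-12)
    expect_true(all(nb$hat_Bu >= 0))
    # independent route: normalize the explicit joint matrix and cut blocks
    Bj <- rbind(cbind(matrix(0, p, p), B), cbind(t(B), matrix(0, q, q)))
    Bt <- Bj + diag(p + q)
    dd <- 1 / sqrt(rowSums(Bt))
    Bhat <- diag(dd) %*% Bt %*% diag(dd)
    expect_equal(unname(nb$hat_Bu), Bhat[1:p, (p + 1):(p + q), drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("prior edge lists map onto the identifier universes", {
  edges <- data.frame(a = "u1", b = "v1")
  bg <- build_bipartite_from_prior(edges, c("u1", "u2"), "v1")
  expect_equal(unname(bg$incidence), rbind(1, 0))
  # duplicates collapse to a single edge
  bg2 <- build_bipartite_from_prior(rbind(edges, edges), c("u1", "u2"), "v1")
  expect_equal(sum(bg2$incidence), 1)
  # unknown identifiers are skipped and counted
  e3 <- data.frame(a = c("u1", "u2", "uX"), b = c("v1", "v1", "v1"))
  expect_message(bg3 <- build_bipartite_from_prior(e3, c("u1", "u2"), "v1"),
                 "1 edge")
  expect_equal(sum(bg3$incidence), 2)
  # empty result warns but does not error
  expect_warning(
    expect_message(build_bipartite_from_prior(
      data.frame(a = "zz", b = "v1"), c("u1"), c("v1")), "skipped"),
    "empty")
})

test_that("score cutoffs filter edges in the configured direction", {
  e <- data.frame(u = c("u1", "u1"), v = c("v1", "v2"), s = c(-0.4, -0.1))
  # repression-style scores: keep more-negative-than-cutoff edges
  bg <- build_bipartite_from_prior(e, "u1", c("v1", "v2"),
                                   score_cutoff = -0.2, score_direction = "le")
  expect_equal(unname(bg$incidence), cbind(1, 0))
  bg2 <- build_bipartite_from_prior(e, "u1", c("v1", "v2"),
                                    score_cutoff = -0.2, score_direction = "ge")
  expect_equal(unname(bg2$incidence), cbind(0, 1))
})

test_that("data-driven bipartite graphs match a brute-force pair scan", {
  # self-similar and orthogonal singletons
  x <- matrix(c(1, 2, 3), 1)
  expect_equal(sum(build_data_driven_bipartite(x, x, "cosine", 0.99)$incidence), 1)
  xu <- matrix(c(1, 0), 1); xv <- matrix(c(0, 1), 1)
  expect_equal(sum(build_data_driven_bipartite(xu, xv, "cosine", 0.1)$incidence), 0)
  # random instance vs explicit double loop
  set.seed(10)
  Xu <- matrix(rnorm(4 * 10), 4, 10); Xv <- matrix(rnorm(3 * 10), 3, 10)
  eps <- 0.2
  got <- build_data_driven_bipartite(Xu, Xv, "cosine", eps)$incidence
  for (i in 1:4) for (j in 1:3) {
    a <- sum(Xu[i, ] * Xv[j, ]) / (sqrt(sum(Xu[i, ]^2)) * sqrt(sum(Xv[j, ]^2)))
    expect_equal(unname(got[i, j]), as.numeric(a >= eps))
  }
  expect_error(build_data_driven_bipartite(Xu, matrix(rnorm(3 * 9), 3, 9),
                                           "cosine", 0.2), "sample axis")
})

test_that("hybrid graphs interpolate between prior and data affinities", {
  prior <- bipartite_graph(rbind(c(1, 0), c(0, 1)))
  A <- rbind(c(0.2, 0.9), c(0.1, 0.3))
  expect_equal(hybrid_bipartite(prior, A, 1, 0.5)$incidence,
               prior$incidence, ignore_attr = TRUE)
  expect_equal(unname(hybrid_bipartite(prior, A, 0, 0.5)$incidence),
               (A >= 0.5) * 1)
  # 0.5 * 1 + 0.5 * 0.2 = 0.6 >= 0.55 keeps the edge
  h <- hybrid_bipartite(bipartite_graph(matrix(1, 1, 1)),
                        matrix(0.2, 1, 1), 0.5, 0.55)
  expect_equal(sum(h$incidence), 1)
  expect_error(hybrid_bipartite(prior, A, 1.2, 0.5), "lam")
})

test_that("rewiring preserves edge counts and is seed-reproducible", {
  set.seed(11)
  bg <- bipartite_graph(random_incidence(10, 8, 0.2))
  expect_identical(rewire_bipartite(bg, 0, seed = 1)$incidence, bg$incidence)
  for (f in c(0.1, 0.5, 1)) {
    rw <- rewire_bipartite(bg, f, seed = 5)
    expect_equal(sum(rw$incidence), sum(bg$incidence))
  }
  expect_identical(rewire_bipartite(bg, 0.5, seed = 5)$incidence,
                   rewire_bipartite(bg, 0.5, seed = 5)$incidence)
  expect_false(identical(rewire_bipartite(bg, 0.5, seed = 5)$incidence,
                         rewire_bipartite(bg, 0.5, seed = 6)$incidence))
})

test_that("graphs round-trip through edge lists", {
  set.seed(12)
  A <- random_adjacency(6, 0.4)
  rownames(A) <- colnames(A) <- paste0("f", 1:6)
  g <- threshold_graph(A, 0.5)  # A is binary; eps 0.5 keeps the 1s
  edges <- graph_to_edges(g)
  expect_equal(nrow(edges), sum(A) / 2)
  bg <- bipartite_graph(random_incidence(4, 3, 0.5))
  be <- graph_to_edges(bg)
  rebuilt <- build_bipartite_from_prior(be, bg$row_feature_ids,
                                        bg$col_feature_ids,
                                        orientation = "v_u")
  expect_equal(rebuilt$incidence, bg$incidence)
})
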