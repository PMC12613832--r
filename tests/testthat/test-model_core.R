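test_that("intra-omics convolution matches hand arithmetic", {
  # identity graph and weights propagate non-negative inputs unchanged
  H <- matrix(c(1, 2, 0.5, 3), 2, 2)
  expect_equal(intra_layer(H, diag(2), diag(2)), H)
  # hand multiply: W = 2I, A-hat all 0.5, H = (1, 3)
  out <- intra_layer(matrix(c(1, 3), 2, 1), matrix(0.5, 2, 2), 2 * diag(2))
  expect_equal(out, matrix(c(4, 4), 2, 1))
  # negative pre-activation picks up the leaky slope
  out2 <- intra_layer(matrix(1, 1, 1), matrix(1, 1, 1),
                      matrix(-1, 1, 1), slope = 0.01)
  expect_equal(out2, matrix(-0.01, 1, 1))
  expect_error(intra_layer(matrix(1, 2, 1), diag(3), diag(2)), "shape")
})

test_that("bipartite convolution equals brute-force neighbour aggregation", {
  # no cross edges: all-zero output
  expect_equal(inter_layer(matrix(rnorm(3), 3, 1), matrix(0, 2, 3), diag(2)),
               matrix(0, 2, 1))
  # scalar case
  expect_equal(inter_layer(matrix(2, 1, 1), matrix(0.5, 1, 1), diag(1)),
               matrix(1, 1, 1))
  set.seed(20)
  for (i in 1:10) {
    p <- sample(2:6, 1); q <- sample(2:6, 1); n <- sample(2:5, 1)
    Bh <- assemble_and_normalize_bipartite(random_incidence(p, q))$hat_Bu
    H <- matrix(rnorm(q * n), q, n)
    W <- matrix(rnorm(p * p), p, p)
    expect_equal(inter_layer(H, Bh, W, 0.01),
                 brute_leaky(W %*% brute_aggregate(Bh, H), 0.01),
                 tolerance = 1e-12)
  }
})

test_that("weighted fusion obeys its limits and midpoint", {
  Zi <- matrix(2, 1, 1); Ze <- matrix(0, 1, 1)
  expect_identical(fuse_weighted(Zi, Ze, 1), Zi)
  expect_equal(fuse_weighted(Zi, Ze, 0), Ze)
  expect_equal(fuse_weighted(Zi, Ze, 0.5), matrix(1, 1, 1))
  expect_error(fuse_weighted(Zi, Ze, 1.5), "k must")
})

test_that("prediction head applies sigmoid/softmax correctly", {
  h <- predict_head(list(matrix(1, 1, 1), matrix(1, 1, 1)),
                    matrix(1, 2, 1), task = "binary")
  expect_equal(h$logits[1, 1], 2)
  expect_equal(h$scores[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  # zero weights: scores 0.5
  h0 <- predict_head(matrix(rnorm(6), 3, 2), matrix(0, 3, 1), "binary")
  expect_equal(unname(h0$scores), matrix(0.5, 2, 1))
  # softmax rows sum to one
  hm <- predict_head(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3),
                     "multiclass")
  expect_equal(unname(rowSums(hm$scores)), rep(1, 3), tolerance = 1e-6)
})

test_that("fusion limits reproduce the ablation modes bitwise", {
  s <- tiny_setup(p = 4, q = 3, n = 5, L = 2, k = 1)
  both1 <- gcn_forward(s$model, s$graphs, s$X)
  m_intra <- s$model; m_intra$mode <- "intra_only"
  expect_identical(both1$scores, gcn_forward(m_intra, s$graphs, s$X)$scores)

  m0 <- s$model; m0$k <- 0
  both0 <- gcn_forward(m0, s$graphs, s$X)
  m_inter <- s$model; m_inter$mode <- "inter_only"
  expect_identical(both0$scores, gcn_forward(m_inter, s$graphs, s$X)$scores)
})

test_that("the layered forward pass equals composition of the primitives", {
  s <- tiny_setup(p = 3, q = 2, n = 4, L = 2, k = 0.3)
  md <- s$model; g <- s$graphs
  Hu <- t(s$X[[1]]); Hv <- t(s$X[[2]])
  for (l in 1:2) {
    Zu <- intra_layer(Hu, g$intra[[1]], md$weights[[w_intra_name(l, 1)]], md$leaky_slope)
    Zv <- intra_layer(Hv, g$intra[[2]], md$weights[[w_intra_name(l, 2)]], md$leaky_slope)
    Zvu <- inter_layer(Hv, g$inter[[1]][[2]], md$weights[[w_inter_name(l, 1, 2)]], md$leaky_slope)
    Zuv <- inter_layer(Hu, g$inter[[2]][[1]], md$weights[[w_inter_name(l, 2, 1)]], md$leaky_slope)
    Hu <- fuse_weighted(Zu, Zvu, md$k)
    Hv <- fuse_weighted(Zv, Zuv, md$k)
  }
  manual <- predict_head(list(Hu, Hv), md$weights[["head"]], "binary")
  fw <- gcn_forward(md, g, s$X)
  expect_identical(unname(fw$scores), unname(manual$scores))
})

test_that("single linear layer reduces to the closed-form product", {
  # slope 1 makes the activation the identity; identity weights leave the
  # propagated signal untouched: H1_u = A_hat_u %*% t(X_u) at k = 1
  s <- tiny_setup(p = 4, q = 3, n = 5, L = 1, k = 1, slope = 1)
  md <- s$model
  md$weights[[w_intra_name(1, 1)]] <- diag(4)
  md$weights[[w_intra_name(1, 2)]] <- diag(3)
  fw <- gcn_forward(md, s$graphs, s$X)
  expect_equal(fw$state$H[[2]][[1]], s$graphs$intra[[1]] %*% t(s$X[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("three-block models aggregate pairwise messages symmetrically", {
  set.seed(21)
  dims <- c(4, 3, 2); n <- 5
  A <- lapply(dims, function(d) normalize_sym(random_adjacency(d)))
  mk_nb <- function(p, q, empty = FALSE) {
    B <- if (empty) matrix(0, p, q) else random_incidence(p, q, 0.5)
    assemble_and_normalize_bipartite(B)
  }
  X <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  md <- gcn_model(dims, n_layers = 1, k = 0.4, init_seed = 2)

  # all-zero bipartite graphs into block 1: its fused state is k * Z_intra
  g0 <- gcn_graphs(A, list("1_2" = mk_nb(4, 3, TRUE), "1_3" = mk_nb(4, 2, TRUE),
                           "2_3" = mk_nb(3, 2)))
  fw0 <- gcn_forward(md, g0, X)
  intra1 <- intra_layer(t(X[[1]]), g0$intra[[1]],
                        md$weights[[w_intra_name(1, 1)]], md$leaky_slope)
  expect_equal(fw0$state$H[[2]][[1]], 0.4 * intra1, tolerance = 1e-12)

  # swapping blocks 2 and 3 (with all graphs/weights) leaves block 1 alone
  nb12 <- mk_nb(4, 3); nb13 <- mk_nb(4, 2); nb23 <- mk_nb(3, 2)
  g <- gcn_graphs(A, list("1_2" = nb12, "1_3" = nb13, "2_3" = nb23))
  fw <- gcn_forward(md, g, X)
  As <- list(A[[1]], A[[3]], A[[2]])
  nb32 <- assemble_and_normalize_bipartite(bipartite_graph(t(nb23$hat_Bu > 0) * 1))
  nb32 <- list(hat_Bu = nb23$hat_Bv, hat_Bv = nb23$hat_Bu,
               row_feature_ids = nb23$col_feature_ids,
               col_feature_ids = nb23$row_feature_ids)
  class(nb32) <- "normalized_bipartite"
  gs <- gcn_graphs(As, list("1_2" = nb13, "1_3" = nb12, "2_3" = nb32))
  ms <- gcn_model(c(4, 2, 3), n_layers = 1, k = 0.4, init_seed = 99)
  ms$weights[[w_intra_name(1, 1)]] <- md$weights[[w_intra_name(1, 1)]]
  ms$weights[[w_intra_name(1, 2)]] <- md$weights[[w_intra_name(1, 3)]]
  ms$weights[[w_intra_name(1, 3)]] <- md$weights[[w_intra_name(1, 2)]]
  ms$weights[[w_inter_name(1, 1, 2)]] <- md$weights[[w_inter_name(1, 1, 3)]]
  ms$weights[[w_inter_name(1, 1, 3)]] <- md$weights[[w_inter_name(1, 1, 2)]]
  ms$weights[[w_inter_name(1, 2, 1)]] <- md$weights[[w_inter_name(1, 3, 1)]]
  ms$weights[[w_inter_name(1, 2, 3)]] <- md$weights[[w_inter_name(1, 3, 2)]]
  ms$weights[[w_inter_name(1, 3, 1)]] <- md$weights[[w_inter_name(1, 2, 1)]]
  ms$weights[[w_inter_name(1, 3, 2)]] <- md$weights[[w_inter_name(1, 2, 3)]]
  fws <- gcn_forward(ms, gs, list(X[[1]], X[[3]], X[[2]]))
  expect_equal(fws$state$H[[2]][[1]], fw$state$H[[2]][[1]], tolerance = 1e-12)
})

test_that("sample permutation permutes predictions identically", {
  s <- tiny_setup(p = 5, q = 4, n = 6, seed = 22)
  fw <- gcn_forward(s$model, s$graphs, s$X)
  perm <- sample(6)
  fwp <- gcn_forward(s$model, s$graphs, lapply(s$X, function(x) x[perm, ]))
  expect_equal(fwp$scores, fw$scores[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("embeddings are the head inputs, in block order", {
  s <- tiny_setup(p = 2, q = 1, n = 3)
  fw <- gcn_forward(s$model, s$graphs, s$X)
  E <- extract_embeddings(fw)
  expect_equal(dim(E), c(3, 3))
  # reconstructing the logits from the embeddings proves shared state
  expect_equal(unname(E %*% s$model$weights[["head"]]), unname(fw$logits),
               tolerance = 1e-12)
})
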