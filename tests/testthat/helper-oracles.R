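# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's vectorized code paths: aggregation is a
# per-node loop over neighbours, AUROC is explicit pair counting, the Youden
# scan enumerates thresholds.

# internal helpers, used to address specific weight matrices / subsets
w_intra_name <- crossgcn:::w_intra
w_inter_name <- crossgcn:::w_inter
standardize_matrix <- crossgcn:::standardize_matrix

# random binary symmetric adjacency with zero diagonal
random_adjacency <- function(d, p_edge = 0.3) {
  A <- matrix(0, d, d)
  if (d > 1) {
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p_edge)
    A <- A + t(A)
  }
  A
}

random_incidence <- function(p, q, p_edge = 0.3) {
  matrix(rbinom(p * q, 1, p_edge), p, q)
}

# per-node neighbour aggregation: row i of out = sum_j G[i,j] * H[j, ]
brute_aggregate <- function(G, H) {
  out <- matrix(0, nrow(G), ncol(H))
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      out[i, ] <- out[i, ] + G[i, j] * H[j, ]
    }
  }
  out
}

brute_leaky <- function(x, slope) ifelse(x < 0, slope * x, x)

# AUROC as the concordant-pair fraction (ties 0.5)
brute_auroc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over distinct scores, smallest optimum wins
brute_youden <- function(y, s) {
  cand <- sort(unique(s))
  js <- sapply(cand, function(t) {
    pred <- s >= t
    sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0) - 1
  })
  cand[which(js >= max(js) - 1e-12)[1L]]
}

# a tiny two-block model + matching graphs + inputs, for gradient and
# identity checks
tiny_setup <- function(p = 3, q = 2, n = 4, L = 2, k = 0.5, seed = 7,
                       mode = "both", task = "binary", nc = 2,
                       slope = 0.01) {
  set.seed(seed)
  Au <- normalize_sym(random_adjacency(p))
  Av <- normalize_sym(random_adjacency(q))
  nb <- assemble_and_normalize_bipartite(random_incidence(p, q, 0.5))
  graphs <- gcn_graphs(list(Au, Av), nb)
  model <- gcn_model(c(p, q), nc = nc, n_layers = L, k = k, mode = mode,
                     task = task, leaky_slope = slope, init_seed = seed)
  Xu <- matrix(rnorm(n * p), n, p)
  Xv <- matrix(rnorm(n * q), n, q)
  y <- rep_len(if (task == "binary") 0:1 else 0:(nc - 1), n)
  list(model = model, graphs = graphs, X = list(Xu, Xv), y = y)
}

# finite-difference gradient of f at weights[[nm]][idx]
fd_grad <- function(f, model, nm, idx, h = 1e-5) {
  mp <- model; mp$weights[[nm]][idx] <- mp$weights[[nm]][idx] + h
  mm <- model; mm$weights[[nm]][idx] <- mm$weights[[nm]][idx] - h
  (f(mp) - f(mm)) / (2 * h)
}

# fabricate a minimal gcn_forward-like object for loss-identity tests
fake_forward <- function(z_intra_u, z_inter_u, z_intra_v, z_inter_v) {
  structure(list(
    state = list(
      z_intra = list(list(z_intra_u, z_intra_v)),
      z_inter = list(list(list(NULL, z_inter_u), list(z_inter_v, NULL)))),
    model = list(M = 2L)),
    class = "gcn_forward")
}
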