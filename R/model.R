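#' Feature-level multi-omics GCN model
#'
#' Constructs the parameter set for a feature-space graph convolutional
#' network over `M >= 2` omics blocks. Per layer `l` and omics block `m`, the
#' model holds a square intra-omics weight matrix (d_m x d_m) and, for every
#' other block `m2`, a square inter-omics weight matrix for messages arriving
#' from `m2`. Square weights keep the hidden representation of each block at
#' its native feature dimension across layers, so the final representations
#' stay interpretable as per-feature values. A fully connected head maps the
#' concatenated final representations to class scores.
#'
#' Weights are initialized from a scaled uniform distribution
#' (limit `sqrt(6 / (fan_in + fan_out))`) under `init_seed`, so two models
#' built with the same arguments are identical.
#'
#' @param dims integer vector of feature counts per omics block (length M >= 2);
#'   names are used as block labels (default `omics1..omicsM`).
#' @param nc number of classes; for `task = "binary"` the head has a single
#'   sigmoid output and `nc` is stored as 2 for bookkeeping.
#' @param n_layers number of graph convolution layers (default 2).
#' @param k fusion weight in \[0, 1\]: the intra-omics representation enters
#'   with weight `k`, the (averaged) inter-omics representations with `1 - k`.
#' @param leaky_slope negative slope of the Leaky ReLU activation.
#' @param task `"binary"` or `"multiclass"`.
#' @param mode `"both"` runs intra and inter branches with weighted fusion;
#'   `"intra_only"` / `"inter_only"` are the ablation modes that train a
#'   single branch and skip fusion.
#' @param head_bias add a bias to the prediction head (default FALSE; the
#'   graph layers never carry biases).
#' @param init_seed integer seed for weight initialization.
#' @return object of class `gcn_model`.
#' @export
gcn_model <- function(dims, nc = 2L, n_layers = 2L, k = 0.5,
                      leaky_slope = 0.01,
                      task = c("binary", "multiclass"),
                      mode = c("both", "intra_only", "inter_only"),
                      head_bias = FALSE, init_seed = 1L) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  M <- length(dims)
  if (M < 2L) stop("need at least two omics blocks")
  if (any(dims < 1L)) stop("every omics block needs at least one feature")
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (!is.numeric(k) || k < 0 || k > 1) stop("k must lie in [0, 1]")
  if (leaky_slope <= 0) stop("leaky_slope must be positive")
  nc <- as.integer(nc)
  if (task == "binary") {
    n_out <- 1L
    nc <- 2L
  } else {
    if (nc < 2L) stop("multiclass task needs nc >= 2")
    n_out <- nc
  }
  blocks <- names(dims) %||% paste0("omics", seq_len(M))
  names(dims) <- blocks

  old_rng <- local_seed(init_seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  glorot <- function(nr, nc_) {
    lim <- sqrt(6 / (nr + nc_))
    matrix(stats::runif(nr * nc_, -lim, lim), nr, nc_)
  }
  weights <- list()
  for (l in seq_len(n_layers)) {
    for (m in seq_len(M)) {
      weights[[w_intra(l, m)]] <- glorot(dims[m], dims[m])
      for (m2 in setdiff(seq_len(M), m)) {
        weights[[w_inter(l, m, m2)]] <- glorot(dims[m], dims[m])
      }
    }
  }
  weights[["head"]] <- glorot(sum(dims), n_out)
  if (head_bias) weights[["head_b"]] <- rep(0, n_out)

  structure(
    list(dims = dims, blocks = blocks, M = M, nc = nc, n_out = n_out,
         n_layers = as.integer(n_layers), k = k, leaky_slope = leaky_slope,
         task = task, mode = mode, head_bias = head_bias,
         init_seed = as.integer(init_seed), weights = weights),
    class = "gcn_model"
  )
}

w_intra <- function(l, m) sprintf("intra.l%d.m%d", l, m)
w_inter <- function(l, m, from) sprintf("inter.l%d.m%d.from%d", l, m, from)

#' Bundle normalized graphs for the model
#'
#' @param intra list of M [normalize_sym()] results (or plain normalized
#'   matrices), one per omics block, in model block order.
#' @param bipartite for M = 2, a single [assemble_and_normalize_bipartite()]
#'   result; for M > 2, a list named `"<i>_<j>"` (i < j, block indices) with
#'   one normalized bipartite per block pair. Every pair must be present.
#' @return object of class `gcn_graphs` holding, for each ordered pair
#'   (m, m2), the normalized block matrix carrying messages from m2 into m.
#' @export
gcn_graphs <- function(intra, bipartite) {
  A <- lapply(intra, function(g) if (inherits(g, "normalized_graph")) g$values else as.matrix(g))
  M <- length(A)
  if (M < 2L) stop("need at least two intra-omics graphs")
  if (inherits(bipartite, "normalized_bipartite")) bipartite <- list("1_2" = bipartite)
  if (M == 2L && is.null(names(bipartite)) && length(bipartite) == 1L) {
    names(bipartite) <- "1_2"
  }
  B <- vector("list", M)
  for (m in seq_len(M)) B[[m]] <- vector("list", M)
  for (i in seq_len(M - 1L)) {
    for (j in seq((i + 1L), M)) {
      key <- paste0(i, "_", j)
      nb <- bipartite[[key]]
      if (is.null(nb)) stop("missing bipartite graph for omics pair (", i, ", ", j, ")")
      if (!inherits(nb, "normalized_bipartite")) stop("bipartite entries must be normalized_bipartite objects")
      if (nrow(nb$hat_Bu) != nrow(A[[i]]) || ncol(nb$hat_Bu) != nrow(A[[j]])) {
        stop("bipartite graph for pair (", i, ", ", j, ") does not match the intra graph dimensions")
      }
      B[[i]][[j]] <- nb$hat_Bu   # messages j -> i
      B[[j]][[i]] <- nb$hat_Bv   # messages i -> j
    }
  }
  ids <- lapply(seq_len(M), function(m) {
    rn <- rownames(A[[m]])
    if (is.null(rn)) paste0("b", m, "_f", seq_len(nrow(A[[m]]))) else rn
  })
  structure(list(intra = A, inter = B, M = M, feature_ids = ids),
            class = "gcn_graphs")
}

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

leaky_relu_grad <- function(pre, slope) {
  g <- array(1, dim = dim(pre))
  g[pre < 0] <- slope
  g
}

#' Single intra-omics graph convolution
#'
#' Computes `LeakyReLU(W %*% A_hat %*% H)`: each feature aggregates its graph
#' neighbours (self-loop included via the renormalization), the result is
#' mixed by the square weight matrix, and the activation is applied.
#'
#' @param H d x n hidden matrix (features x samples).
#' @param A_hat normalized intra-omics graph ([normalize_sym()] result or
#'   d x d matrix).
#' @param W d x d weight matrix.
#' @param slope Leaky ReLU negative slope.
#' @return d x n matrix.
#' @export
intra_layer <- function(H, A_hat, W, slope = 0.01) {
  A <- if (inherits(A_hat, "normalized_graph")) A_hat$values else as.matrix(A_hat)
  H <- as.matrix(H); W <- as.matrix(W)
  if (ncol(A) != nrow(H) || ncol(W) != nrow(A)) stop("intra_layer: shape mismatch")
  leaky_relu(W %*% (A %*% H), slope)
}

#' Single inter-omics (bipartite) graph convolution
#'
#' Computes `LeakyReLU(W %*% B_hat %*% H_other)`: features of the receiving
#' block aggregate the hidden state of the other omics block across the
#' normalized bipartite incidence.
#'
#' @param H_other d_other x n hidden matrix of the sending block.
#' @param B_hat d_self x d_other normalized incidence block (oriented
#'   self <- other).
#' @param W d_self x d_self weight matrix.
#' @param slope Leaky ReLU negative slope.
#' @return d_self x n matrix.
#' @export
inter_layer <- function(H_other, B_hat, W, slope = 0.01) {
  B <- as.matrix(B_hat); H_other <- as.matrix(H_other); W <- as.matrix(W)
  if (ncol(B) != nrow(H_other) || ncol(W) != nrow(B)) stop("inter_layer: shape mismatch")
  leaky_relu(W %*% (B %*% H_other), slope)
}

#' Weighted fusion of intra- and inter-omics representations
#'
#' @param Z_intra,Z_inter equal-shape matrices.
#' @param k fusion weight in \[0, 1\]; `k = 1` returns `Z_intra` exactly and
#'   `k = 0` returns `Z_inter` exactly (the ablation limits).
#' @return `k * Z_intra + (1 - k) * Z_inter`.
#' @export
fuse_weighted <- function(Z_intra, Z_inter, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1) {
    stop("k must be a single number in [0, 1]")
  }
  if (!all(dim(as.matrix(Z_intra)) == dim(as.matrix(Z_inter)))) {
    stop("fuse_weighted: shape mismatch")
  }
  k * Z_intra + (1 - k) * Z_inter
}

#' Prediction head over concatenated representations
#'
#' Row-concatenates the per-block final hidden matrices, transposes to
#' sample-major and applies the fully connected layer:
#' sigmoid for the binary task (one output column), row-wise softmax for the
#' multiclass task.
#'
#' @param H_blocks list of d_m x n matrices (or a single matrix).
#' @param W (sum d_m) x n_out weight matrix.
#' @param task `"binary"` or `"multiclass"`.
#' @param bias optional length-n_out bias.
#' @return list with `scores` (n x n_out probabilities) and `logits`.
#' @export
predict_head <- function(H_blocks, W, task = c("binary", "multiclass"),
                         bias = NULL) {
  task <- match.arg(task)
  if (is.matrix(H_blocks)) H_blocks <- list(H_blocks)
  C <- do.call(rbind, H_blocks)
  W <- as.matrix(W)
  if (ncol(W) < 1L) stop("head needs at least one output column")
  if (nrow(W) != nrow(C)) stop("predict_head: shape mismatch")
  logits <- crossprod(C, W)                  # n x n_out
  if (!is.null(bias)) logits <- sweep(logits, 2L, bias, "+")
  if (task == "binary") {
    scores <- 1 / (1 + exp(-logits))
  } else {
    mx <- apply(logits, 1L, max)
    e <- exp(logits - mx)
    scores <- e / rowSums(e)
  }
  list(scores = scores, logits = logits)
}

#' Forward pass of the multi-omics GCN
#'
#' Runs `n_layers` rounds of parallel intra-omics and inter-omics convolution
#' with weighted fusion (per the model `mode`), starting from the transposed
#' input matrices, then applies the prediction head. With M blocks, each block
#' receives one intra-omics representation and `M - 1` inter-omics
#' representations per layer; under `mode = "both"` they combine as
#' `k * Z_intra + (1 - k) * mean(Z_inter)`.
#'
#' @param model a [gcn_model()].
#' @param graphs a [gcn_graphs()] matching the model dimensions.
#' @param X list of n x d_m matrices (samples x features), in block order.
#' @return object of class `gcn_forward`: list with `scores`, `logits` and
#'   `state` (all cached per-layer quantities, used for losses, gradients and
#'   embedding extraction).
#' @export
gcn_forward <- function(model, graphs, X) {
  if (!inherits(model, "gcn_model")) stop("model must be a gcn_model")
  if (!inherits(graphs, "gcn_graphs")) stop("graphs must be a gcn_graphs")
  if (is.matrix(X)) X <- list(X)
  M <- model$M
  if (graphs$M != M || length(X) != M) stop("model, graphs and X disagree on the number of omics blocks")
  for (m in seq_len(M)) {
    if (ncol(X[[m]]) != model$dims[m]) {
      stop("X block ", m, " has ", ncol(X[[m]]), " features; model expects ", model$dims[m])
    }
  }
  n <- nrow(X[[1L]])
  if (any(vapply(X, nrow, 1L) != n)) stop("all omics blocks must share the sample axis")

  L <- model$n_layers
  k <- model$k
  slope <- model$leaky_slope
  mode <- model$mode
  wts <- model$weights

  H <- vector("list", L + 1L)
  H[[1L]] <- lapply(X, t)                    # H^(0) = X^T, features x samples
  agg_intra <- pre_intra <- z_intra <- vector("list", L)
  agg_inter <- pre_inter <- z_inter <- vector("list", L)

  for (l in seq_len(L)) {
    agg_intra[[l]] <- pre_intra[[l]] <- z_intra[[l]] <- vector("list", M)
    agg_inter[[l]] <- pre_inter[[l]] <- z_inter[[l]] <-
      lapply(seq_len(M), function(m) vector("list", M))
    Hl <- vector("list", M)
    for (m in seq_len(M)) {
      zi <- NULL
      if (mode != "inter_only") {
        a <- graphs$intra[[m]] %*% H[[l]][[m]]
        pre <- wts[[w_intra(l, m)]] %*% a
        zi <- leaky_relu(pre, slope)
        agg_intra[[l]][[m]] <- a
        pre_intra[[l]][[m]] <- pre
        z_intra[[l]][[m]] <- zi
      }
      zes <- NULL
      if (mode != "intra_only") {
        others <- setdiff(seq_len(M), m)
        zes <- vector("list", length(others))
        for (ii in seq_along(others)) {
          m2 <- others[ii]
          a <- graphs$inter[[m]][[m2]] %*% H[[l]][[m2]]
          pre <- wts[[w_inter(l, m, m2)]] %*% a
          z <- leaky_relu(pre, slope)
          agg_inter[[l]][[m]][[m2]] <- a
          pre_inter[[l]][[m]][[m2]] <- pre
          z_inter[[l]][[m]][[m2]] <- z
          zes[[ii]] <- z
        }
      }
      Hl[[m]] <- switch(mode,
        both = fuse_weighted(zi, Reduce(`+`, zes) / length(zes), k),
        intra_only = zi,
        inter_only = Reduce(`+`, zes) / length(zes))
    }
    H[[l + 1L]] <- Hl
  }

  head <- predict_head(H[[L + 1L]], wts[["head"]], model$task,
                       bias = wts[["head_b"]])
  sample_ids <- rownames(X[[1L]])
  if (!is.null(sample_ids)) rownames(head$scores) <- rownames(head$logits) <- sample_ids

  structure(
    list(scores = head$scores, logits = head$logits,
         state = list(H = H, agg_intra = agg_intra, pre_intra = pre_intra,
                      z_intra = z_intra, agg_inter = agg_inter,
                      pre_inter = pre_inter, z_inter = z_inter,
                      sample_ids = sample_ids, n = n),
         model = model, graphs = graphs),
    class = "gcn_forward"
  )
}

#' Extract sample embeddings from a forward pass
#'
#' Returns the representations fed to the prediction head: the final-layer
#' hidden blocks, concatenated in block order and transposed to sample-major.
#' These are the values exported for downstream analyses (e.g. survival
#' modelling) outside this package.
#'
#' @param fw a [gcn_forward()] result.
#' @return n x (sum d_m) matrix; columns named by feature identifier, rows by
#'   sample identifier when available.
#' @export
extract_embeddings <- function(fw) {
  if (!inherits(fw, "gcn_forward")) stop("fw must be a gcn_forward result")
  Hfin <- fw$state$H[[length(fw$state$H)]]
  E <- t(do.call(rbind, Hfin))
  colnames(E) <- unlist(fw$graphs$feature_ids)
  if (!is.null(fw$state$sample_ids)) rownames(E) <- fw$state$sample_ids
  E
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf(
    "<gcn_model> %d omics blocks (%s), %d layer(s), mode = %s, k = %.2f, task = %s\n",
    x$M, paste(x$dims, collapse = " + "), x$n_layers, x$mode, x$k, x$task))
  invisible(x)
}
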