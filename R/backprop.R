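# Analytic gradients for the multi-omics GCN.
#
# All layers are linear maps plus Leaky ReLU, so backpropagation is plain
# matrix calculus. The generic backward walk accepts gradients injected at
# the fused hidden state of the top layer (supervised training) and/or at the
# pre-fusion Z representations of any layer (dual-alignment pretraining), and
# accumulates gradients for every weight matrix. Correctness is pinned by
# finite-difference tests.

# Backward walk. fw: gcn_forward result; dH_top: list per block, gradient
# w.r.t. the final fused hidden state (or NULL); dz_inj: optional list indexed
# [[layer]] with members $intra[[m]] and $inter[[m]][[m2]] (any may be NULL).
# Returns a named list of gradients matching model$weights (head excluded).
backward_graph_weights <- function(fw, dH_top = NULL, dz_inj = NULL) {
  model <- fw$model
  graphs <- fw$graphs
  st <- fw$state
  M <- model$M
  L <- model$n_layers
  k <- model$k
  slope <- model$leaky_slope
  mode <- model$mode
  wts <- model$weights
  n <- st$n

  grads <- list()
  zero_like <- function(m) matrix(0, model$dims[m], n)
  dH <- if (is.null(dH_top)) lapply(seq_len(M), zero_like) else dH_top

  for (l in rev(seq_len(L))) {
    dH_prev <- lapply(seq_len(M), zero_like)
    inj <- if (!is.null(dz_inj) && length(dz_inj) >= l) dz_inj[[l]] else NULL
    for (m in seq_len(M)) {
      others <- setdiff(seq_len(M), m)
      # split the fused-state gradient between the two branches
      if (mode == "both") {
        dzi <- k * dH[[m]]
        w_int <- (1 - k) / length(others)
      } else if (mode == "intra_only") {
        dzi <- dH[[m]]
        w_int <- 0
      } else {
        dzi <- NULL
        w_int <- 1 / length(others)
      }
      if (mode != "inter_only") {
        if (!is.null(inj) && !is.null(inj$intra[[m]])) dzi <- dzi + inj$intra[[m]]
        pre <- st$pre_intra[[l]][[m]]
        dpre <- dzi * leaky_relu_grad(pre, slope)
        nm <- w_intra(l, m)
        g <- tcrossprod(dpre, st$agg_intra[[l]][[m]])
        grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
        dH_prev[[m]] <- dH_prev[[m]] +
          crossprod(graphs$intra[[m]], crossprod(wts[[nm]], dpre))
      }
      if (mode != "intra_only") {
        for (m2 in others) {
          dze <- w_int * dH[[m]]
          if (!is.null(inj) && !is.null(inj$inter[[m]][[m2]])) {
            dze <- dze + inj$inter[[m]][[m2]]
          }
          pre <- st$pre_inter[[l]][[m]][[m2]]
          dpre <- dze * leaky_relu_grad(pre, slope)
          nm <- w_inter(l, m, m2)
          g <- tcrossprod(dpre, st$agg_inter[[l]][[m]][[m2]])
          grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
          dH_prev[[m2]] <- dH_prev[[m2]] +
            crossprod(graphs$inter[[m]][[m2]], crossprod(wts[[nm]], dpre))
        }
      }
    }
    dH <- dH_prev
  }
  grads
}

# Supervised loss and gradients w.r.t. every weight (graph layers + head).
supervised_grads <- function(model, graphs, X, y) {
  fw <- gcn_forward(model, graphs, X)
  n <- fw$state$n
  if (model$task == "binary") {
    yv <- matrix(as.numeric(y), ncol = 1L)
    dlogits <- (fw$scores - yv) / n
  } else {
    Y1 <- matrix(0, n, model$n_out)
    Y1[cbind(seq_len(n), as.integer(y) + 1L)] <- 1
    dlogits <- (fw$scores - Y1) / n
  }
  Hfin <- fw$state$H[[model$n_layers + 1L]]
  C <- do.call(rbind, Hfin)
  grads <- list(head = C %*% dlogits)
  if (model$head_bias) grads[["head_b"]] <- colSums(dlogits)
  dC <- tcrossprod(model$weights[["head"]], dlogits)  # D x n
  offsets <- c(0L, cumsum(model$dims))
  dH_top <- lapply(seq_len(model$M), function(m) {
    dC[(offsets[m] + 1L):offsets[m + 1L], , drop = FALSE]
  })
  grads <- c(grads, backward_graph_weights(fw, dH_top = dH_top))
  list(loss = classification_loss(y, fw$scores, model$task),
       grads = grads, forward = fw)
}

# Dual-alignment pretraining loss alpha*L_A + (1-alpha)*L_R and gradients
# w.r.t. the graph-layer weights (the head is untouched). `layers` is
# "final" (default) or "all".
pretrain_grads <- function(model, graphs, X, alpha, layers = "final") {
  if (model$mode != "both") stop("dual-alignment pretraining requires mode 'both'")
  fw <- gcn_forward(model, graphs, X)
  st <- fw$state
  M <- model$M
  L <- model$n_layers
  lay_set <- if (identical(layers, "all")) seq_len(L) else L

  dz_inj <- vector("list", L)
  LA <- 0; LR <- 0
  for (l in lay_set) {
    inj <- list(intra = vector("list", M),
                inter = lapply(seq_len(M), function(m) vector("list", M)))
    for (m in seq_len(M)) {
      zi <- st$z_intra[[l]][[m]]
      N <- length(zi)
      di <- matrix(0, nrow(zi), ncol(zi))
      for (m2 in setdiff(seq_len(M), m)) {
        ze <- st$z_inter[[l]][[m]][[m2]]
        diff <- zi - ze
        LA <- LA + mean(diff^2) / (M - 1L)
        gA <- (2 / N) * diff / (M - 1L)
        di <- di + alpha * gA
        inj$inter[[m]][[m2]] <- -alpha * gA
      }
      diffR <- zi - t(X[[m]])
      LR <- LR + mean(diffR^2)
      di <- di + (1 - alpha) * (2 / N) * diffR
      inj$intra[[m]] <- di
    }
    dz_inj[[l]] <- inj
  }
  grads <- backward_graph_weights(fw, dH_top = NULL, dz_inj = dz_inj)
  list(loss = alpha * LA + (1 - alpha) * LR,
       alignment = LA, reconstruction = LR, grads = grads, forward = fw)
}
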