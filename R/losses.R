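#' Classification loss
#'
#' Mean binary cross-entropy over samples for the binary task, mean
#' categorical cross-entropy for the multiclass task. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param y binary labels in `{0, 1}` or multiclass labels in `{0..nc-1}`.
#' @param scores n x 1 probabilities (binary) or n x nc row-stochastic matrix
#'   (multiclass); a [gcn_forward()] result is also accepted.
#' @param task `"binary"` or `"multiclass"`.
#' @return non-negative scalar.
#' @export
classification_loss <- function(y, scores, task = c("binary", "multiclass")) {
  task <- match.arg(task)
  if (inherits(scores, "gcn_forward")) scores <- scores$scores
  p <- pmin(pmax(as.matrix(scores), 1e-7), 1 - 1e-7)
  y <- as.numeric(y)
  if (task == "binary") {
    if (any(!y %in% c(0, 1))) stop("binary labels must lie in {0, 1}")
    if (length(y) != nrow(p)) stop("labels and scores disagree in length")
    -mean(y * log(p[, 1L]) + (1 - y) * log(1 - p[, 1L]))
  } else {
    nc <- ncol(p)
    if (any(y < 0 | y > nc - 1 | y != floor(y))) {
      stop("multiclass labels must lie in {0..", nc - 1, "}")
    }
    -mean(log(p[cbind(seq_len(nrow(p)), y + 1L)]))
  }
}

#' Alignment loss between intra- and inter-omics representations
#'
#' For each omics block, the mean squared difference between the block's
#' intra-omics representation and the representation of the same block
#' aggregated from the other omics (averaged over the M - 1 sending blocks),
#' summed over blocks. With two blocks this is
#' `MSE(Z_u, Z_v2u) + MSE(Z_v, Z_u2v)`. Used as the consistency term of
#' dual-alignment pretraining.
#'
#' @param fw a [gcn_forward()] result (must have been run with
#'   `mode = "both"`).
#' @param layer layer index; default the final layer.
#' @return non-negative scalar.
#' @export
alignment_loss <- function(fw, layer = NULL) {
  st <- fw$state
  L <- length(st$z_intra)
  if (is.null(layer)) layer <- L
  M <- fw$model$M
  loss <- 0
  for (m in seq_len(M)) {
    zi <- st$z_intra[[layer]][[m]]
    if (is.null(zi)) stop("alignment loss needs the intra branch (mode 'both')")
    for (m2 in setdiff(seq_len(M), m)) {
      ze <- st$z_inter[[layer]][[m]][[m2]]
      if (is.null(ze)) stop("alignment loss needs the inter branch (mode 'both')")
      loss <- loss + mean((zi - ze)^2) / (M - 1L)
    }
  }
  loss
}

#' Reconstruction loss against the original inputs
#'
#' Mean squared difference between each block's intra-omics representation at
#' the given layer and the transposed input matrix, summed over blocks
#' (`MSE(Z_u, X_u^T) + MSE(Z_v, X_v^T)` for two blocks). Square per-layer
#' weights guarantee the shapes agree. Keeps pretrained representations close
#' to the measured values.
#'
#' @param fw a [gcn_forward()] result.
#' @param X list of input matrices (samples x features) as passed to
#'   [gcn_forward()].
#' @param layer layer index; default the final layer.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(fw, X, layer = NULL) {
  st <- fw$state
  if (is.matrix(X)) X <- list(X)
  L <- length(st$z_intra)
  if (is.null(layer)) layer <- L
  loss <- 0
  for (m in seq_len(fw$model$M)) {
    zi <- st$z_intra[[layer]][[m]]
    if (is.null(zi)) stop("reconstruction loss needs the intra branch")
    Xt <- t(X[[m]])
    if (!all(dim(zi) == dim(Xt))) stop("representation/input shape mismatch")
    loss <- loss + mean((zi - Xt)^2)
  }
  loss
}
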