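#' Pairwise feature affinities
#'
#' Computes the full pairwise affinity matrix between molecular features,
#' where each feature is represented by its vector of values across samples.
#' Three affinity functions are supported: cosine similarity, Pearson
#' correlation, and the Gaussian (RBF) kernel
#' \eqn{s(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}.
#'
#' Degenerate features (zero norm under cosine, zero variance under Pearson)
#' cannot carry a meaningful affinity; every pair involving such a feature is
#' assigned affinity 0 with a warning, so constant features never gain edges.
#'
#' @param feature_vectors numeric matrix, one row per feature, one column per
#'   sample (features x samples). Row names are taken as feature identifiers.
#' @param method one of `"cosine"`, `"pearson"`, `"rbf"`.
#' @param sigma positive bandwidth, required for `method = "rbf"` only.
#'   Defaults to the median pairwise Euclidean distance when `NULL`.
#' @return an object of class `affinity_matrix`: a list with `values`
#'   (symmetric d x d matrix), `feature_ids`, `method` and `sigma`.
#' @examples
#' X <- matrix(rnorm(40), nrow = 4)
#' a <- compute_affinity(X, method = "cosine")
#' range(a$values)
#' @export
compute_affinity <- function(feature_vectors,
                             method = c("cosine", "pearson", "rbf"),
                             sigma = NULL) {
  method <- match.arg(method)
  X <- as.matrix(feature_vectors)
  if (!is.numeric(X)) stop("feature_vectors must be numeric")
  if (anyNA(X)) stop("feature_vectors must not contain missing values")
  d <- nrow(X)
  n <- ncol(X)
  if (d < 1L) stop("need at least one feature")
  if (n < 2L) stop("need at least two samples per feature vector")
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(d))

  if (method == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    degenerate <- nrm == 0
    nrm[degenerate] <- 1
    S <- tcrossprod(X / nrm)
    S <- pmin(pmax(S, -1), 1)
    if (any(degenerate)) {
      warning(sum(degenerate), " zero-norm feature(s); their affinities set to 0")
      S[degenerate, ] <- 0
      S[, degenerate] <- 0
    }
    diag(S)[!degenerate] <- 1
  } else if (method == "pearson") {
    sds <- apply(X, 1L, stats::sd)
    degenerate <- sds == 0
    S <- suppressWarnings(stats::cor(t(X)))
    S[!is.finite(S)] <- 0
    if (any(degenerate)) {
      warning(sum(degenerate), " zero-variance feature(s); their affinities set to 0")
      S[degenerate, ] <- 0
      S[, degenerate] <- 0
    }
    S <- pmin(pmax(S, -1), 1)
    diag(S)[!degenerate] <- 1
    S <- (S + t(S)) / 2
  } else {
    D2 <- as.matrix(stats::dist(X))^2
    if (is.null(sigma)) {
      off <- as.numeric(stats::dist(X))
      sigma <- stats::median(off)
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
      stop("sigma must be a single positive number for the rbf affinity")
    }
    S <- exp(-D2 / (2 * sigma^2))
  }
  dimnames(S) <- list(ids, ids)
  structure(
    list(values = S, feature_ids = ids, method = method,
         sigma = if (method == "rbf") sigma else NULL),
    class = "affinity_matrix"
  )
}

#' Threshold an affinity matrix into a binary feature graph
#'
#' Off-diagonal entries with affinity at or above `eps` become edges; the
#' diagonal is forced to zero (self-loops are added separately during
#' normalization, see [normalize_sym()]).
#'
#' @param affinity an [compute_affinity()] result, or a symmetric numeric
#'   matrix.
#' @param eps edge-inclusion threshold. When `NULL`, chosen automatically so
#'   that the median node degree falls in a sparse-but-connected band (see
#'   [choose_epsilon()]).
#' @param omics_id optional label stored on the graph.
#' @return object of class `feature_graph` with fields `adjacency` (binary,
#'   symmetric, zero diagonal), `feature_ids`, `omics_id`, `threshold`.
#' @export
threshold_graph <- function(affinity, eps = NULL, omics_id = "omics") {
  S <- affinity_values(affinity)
  ids <- affinity_ids(affinity, nrow(S))
  if (max(abs(S - t(S))) > 1e-8) stop("affinity matrix must be symmetric")
  if (is.null(eps)) eps <- choose_epsilon(affinity)
  A <- (S >= eps) * 1
  A <- A * (A == t(A))   # guard exact symmetry under fp-equal comparisons
  diag(A) <- 0
  dimnames(A) <- list(ids, ids)
  structure(
    list(adjacency = A, feature_ids = ids, omics_id = omics_id,
         threshold = eps),
    class = "feature_graph"
  )
}

#' Choose an affinity threshold by target degree
#'
#' Picks the threshold as the off-diagonal affinity quantile at which the
#' expected node degree equals `target_degree`, then verifies the resulting
#' median degree lies within `degree_band` (re-targeting to the nearest band
#' edge when it does not). This keeps constructed graphs sparse enough to be
#' informative but dense enough to propagate signal.
#'
#' @param affinity affinity matrix (object or plain matrix).
#' @param target_degree desired median node degree (default 10).
#' @param degree_band acceptable median-degree interval, default `c(3, 30)`.
#' @return a single numeric threshold.
#' @export
choose_epsilon <- function(affinity, target_degree = 10, degree_band = c(3, 30)) {
  S <- affinity_values(affinity)
  d <- nrow(S)
  if (d < 2L) return(Inf)
  off <- S[upper.tri(S)]
  eps_for <- function(k) {
    k <- min(max(k, 1), d - 1L)
    stats::quantile(off, probs = max(0, 1 - k / (d - 1L)), names = FALSE,
                    type = 1L)
  }
  med_deg <- function(eps) {
    A <- (S >= eps) * 1; diag(A) <- 0
    stats::median(rowSums(A))
  }
  eps <- eps_for(target_degree)
  md <- med_deg(eps)
  if (md < degree_band[1]) eps <- eps_for(degree_band[1] + 1)
  if (md > degree_band[2]) eps <- eps_for(degree_band[2] - 1)
  eps
}

# ---- internal accessors -----------------------------------------------------

affinity_values <- function(x) {
  if (inherits(x, "affinity_matrix")) x$values else as.matrix(x)
}

affinity_ids <- function(x, d) {
  if (inherits(x, "affinity_matrix")) return(x$feature_ids)
  ids <- rownames(as.matrix(x))
  if (is.null(ids)) ids <- paste0("f", seq_len(d))
  ids
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d features, method = %s\n",
              length(x$feature_ids), x$method))
  invisible(x)
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph> '%s': %d nodes, %d edges (eps = %.4g)\n",
              x$omics_id, length(x$feature_ids), sum(x$adjacency) / 2,
              x$threshold))
  invisible(x)
}
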