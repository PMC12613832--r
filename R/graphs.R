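#' Symmetric renormalization of a feature graph
#'
#' Computes \eqn{\hat A = D^{-1/2} (A + I) D^{-1/2}} where `D` holds the row
#' sums of \eqn{A + I}. Adding the identity gives every node a self-connection
#' before normalization, so every degree is at least 1 and isolated features
#' remain well defined; the result is symmetric with spectral radius at most 1.
#'
#' @param graph a [threshold_graph()] result, or a binary symmetric adjacency
#'   matrix with zero diagonal.
#' @return object of class `normalized_graph` with `values` and `feature_ids`.
#' @export
normalize_sym <- function(graph) {
  A <- graph_adjacency(graph)
  d <- nrow(A)
  ids <- graph_ids(graph, d)
  if (!isTRUE(all.equal(A, t(A), tolerance = 0, check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  if (any(A != 0 & A != 1)) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  At <- A
  diag(At) <- 1
  dinv <- 1 / sqrt(rowSums(At))
  Ahat <- At * tcrossprod(dinv)   # D^{-1/2} At D^{-1/2}
  Ahat <- (Ahat + t(Ahat)) / 2
  dimnames(Ahat) <- list(ids, ids)
  structure(list(values = Ahat, feature_ids = ids), class = "normalized_graph")
}

#' Construct a bipartite graph object
#'
#' @param incidence binary p x q matrix; rows index omics1 features, columns
#'   omics2 features. An entry of 1 marks a cross-omics edge.
#' @param row_ids,col_ids feature identifiers (defaults taken from dimnames).
#' @return object of class `bipartite_graph`.
#' @export
bipartite_graph <- function(incidence, row_ids = NULL, col_ids = NULL) {
  B <- as.matrix(incidence)
  if (any(B != 0 & B != 1)) stop("incidence must be binary")
  if (is.null(row_ids)) row_ids <- rownames(B)
  if (is.null(col_ids)) col_ids <- colnames(B)
  if (is.null(row_ids)) row_ids <- paste0("u", seq_len(nrow(B)))
  if (is.null(col_ids)) col_ids <- paste0("v", seq_len(ncol(B)))
  dimnames(B) <- list(row_ids, col_ids)
  structure(list(incidence = B, row_feature_ids = row_ids,
                 col_feature_ids = col_ids),
            class = "bipartite_graph")
}

#' Normalize a bipartite graph through its joint adjacency
#'
#' Embeds the p x q incidence into the joint (p+q) x (p+q) adjacency with zero
#' diagonal blocks, applies the same symmetric renormalization as
#' [normalize_sym()] (self-loops added via the identity), and extracts the
#' off-diagonal blocks: `hat_Bu` (p x q, messages omics2 -> omics1) and
#' `hat_Bv` (q x p, its transpose). Features without cross edges get all-zero
#' block rows.
#'
#' @param bip a [bipartite_graph()] (or binary incidence matrix).
#' @return object of class `normalized_bipartite` with `hat_Bu`, `hat_Bv`,
#'   `row_feature_ids`, `col_feature_ids`.
#' @export
assemble_and_normalize_bipartite <- function(bip) {
  if (!inherits(bip, "bipartite_graph")) bip <- bipartite_graph(bip)
  B <- bip$incidence
  p <- nrow(B); q <- ncol(B)
  # joint degrees: self-loop plus cross edges
  deg_u <- 1 + rowSums(B)
  deg_v <- 1 + colSums(B)
  su <- 1 / sqrt(deg_u)
  sv <- 1 / sqrt(deg_v)
  hat_Bu <- B * outer(su, sv)
  hat_Bv <- t(hat_Bu)
  dimnames(hat_Bu) <- list(bip$row_feature_ids, bip$col_feature_ids)
  dimnames(hat_Bv) <- list(bip$col_feature_ids, bip$row_feature_ids)
  structure(list(hat_Bu = hat_Bu, hat_Bv = hat_Bv,
                 row_feature_ids = bip$row_feature_ids,
                 col_feature_ids = bip$col_feature_ids),
            class = "normalized_bipartite")
}

#' Bipartite graph from a prior interaction edge list
#'
#' Builds a binary incidence over the supplied feature universes from a
#' two/three-column edge list such as a curated regulator-target network.
#' Edges referencing unknown identifiers are skipped with a message reporting
#' the count. When a `score` column is present and `score_cutoff` is given,
#' only edges passing the cutoff are kept; `score_direction = "le"` keeps
#' scores at or below the cutoff (the convention for repression-strength
#' scores, which are more negative for stronger predicted repression) while
#' `"ge"` keeps scores at or above it (generic edge weights).
#'
#' @param edges data.frame; the first two columns hold feature identifiers and
#'   an optional third column a numeric score.
#' @param u_ids,v_ids identifier universes for the two omics; rows of the
#'   incidence are `u_ids`, columns are `v_ids`.
#' @param score_cutoff optional numeric cutoff.
#' @param score_direction `"le"` or `"ge"`, see above.
#' @param orientation `"u_v"` when the first edge column lists omics1 (row
#'   side) features, `"v_u"` when it lists omics2 features first, as in
#'   regulator-target files where the miRNA comes first.
#' @return a [bipartite_graph()] over `u_ids` x `v_ids`. Warns (not errors)
#'   when no edge survives.
#' @export
build_bipartite_from_prior <- function(edges, u_ids, v_ids,
                                       score_cutoff = NULL,
                                       score_direction = c("le", "ge"),
                                       orientation = c("u_v", "v_u")) {
  score_direction <- match.arg(score_direction)
  orientation <- match.arg(orientation)
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge list needs at least two columns")
  src <- as.character(edges[[1L]])
  tgt <- as.character(edges[[2L]])
  if (orientation == "v_u") { tmp <- src; src <- tgt; tgt <- tmp }
  keep <- rep(TRUE, length(src))
  if (!is.null(score_cutoff)) {
    if (ncol(edges) < 3L) stop("score_cutoff given but edge list has no score column")
    sc <- as.numeric(edges[[3L]])
    keep <- if (score_direction == "le") sc <= score_cutoff else sc >= score_cutoff
    keep[is.na(keep)] <- FALSE
  }
  src <- src[keep]; tgt <- tgt[keep]
  # identifiers are case-sensitive exact strings
  i <- match(src, u_ids)
  j <- match(tgt, v_ids)
  known <- !is.na(i) & !is.na(j)
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    message(n_skipped, " edge(s) referenced unknown feature identifiers and were skipped")
  }
  B <- matrix(0, length(u_ids), length(v_ids), dimnames = list(u_ids, v_ids))
  if (any(known)) B[cbind(i[known], j[known])] <- 1
  if (sum(B) == 0) {
    warning("prior bipartite graph is empty; model will rely on intra-omics signal only")
  }
  bipartite_graph(B, u_ids, v_ids)
}

#' Data-driven bipartite graph from cross-omics affinities
#'
#' Applies one of the affinity functions of [compute_affinity()] between every
#' feature of omics1 and every feature of omics2 (both expressed as vectors
#' over the shared samples) and keeps pairs with affinity at or above `eps`.
#'
#' @param Xu_features p x n matrix (omics1 features x samples).
#' @param Xv_features q x n matrix (omics2 features x samples), same sample
#'   order.
#' @param method,sigma as in [compute_affinity()].
#' @param eps inclusion threshold.
#' @return a [bipartite_graph()] with p rows and q columns.
#' @export
build_data_driven_bipartite <- function(Xu_features, Xv_features,
                                        method = c("cosine", "pearson", "rbf"),
                                        eps, sigma = NULL) {
  method <- match.arg(method)
  Xu <- as.matrix(Xu_features); Xv <- as.matrix(Xv_features)
  if (ncol(Xu) != ncol(Xv)) stop("the two omics must share the sample axis")
  A <- cross_affinity(Xu, Xv, method, sigma)
  B <- (A >= eps) * 1
  bipartite_graph(B,
                  row_ids = rownames(Xu) %||% paste0("u", seq_len(nrow(Xu))),
                  col_ids = rownames(Xv) %||% paste0("v", seq_len(nrow(Xv))))
}

# rectangular affinity between two feature sets sharing the sample axis
cross_affinity <- function(Xu, Xv, method = c("cosine", "pearson", "rbf"),
                           sigma = NULL) {
  method <- match.arg(method)
  if (method == "cosine") {
    nu <- sqrt(rowSums(Xu^2)); nv <- sqrt(rowSums(Xv^2))
    nu[nu == 0] <- Inf; nv[nv == 0] <- Inf
    A <- tcrossprod(Xu / nu, Xv / nv)
  } else if (method == "pearson") {
    A <- suppressWarnings(stats::cor(t(Xu), t(Xv)))
    A[!is.finite(A)] <- 0
  } else {
    if (is.null(sigma)) {
      sigma <- stats::median(stats::dist(rbind(Xu, Xv)))
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    if (sigma <= 0) stop("sigma must be positive")
    d2 <- outer(rowSums(Xu^2), rowSums(Xv^2), "+") - 2 * tcrossprod(Xu, Xv)
    d2[d2 < 0] <- 0
    A <- exp(-d2 / (2 * sigma^2))
  }
  A
}

#' Blend a prior bipartite graph with data-driven affinities
#'
#' Keeps the edge (i, j) when
#' \eqn{\lambda \cdot prior_{ij} + (1-\lambda) \cdot a_{ij} \ge \epsilon}.
#' At `lam = 1` this reduces to the prior thresholded at `eps`; at `lam = 0`
#' to the purely data-driven graph.
#'
#' @param prior a [bipartite_graph()].
#' @param data_affinity p x q numeric cross-affinity matrix.
#' @param lam blending weight in \[0, 1\].
#' @param eps inclusion threshold.
#' @return a [bipartite_graph()].
#' @export
hybrid_bipartite <- function(prior, data_affinity, lam, eps) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1) {
    stop("lam must be a single number in [0, 1]")
  }
  P <- prior$incidence
  A <- as.matrix(data_affinity)
  if (!all(dim(P) == dim(A))) stop("prior and data_affinity shapes disagree")
  B <- (lam * P + (1 - lam) * A >= eps) * 1
  bipartite_graph(B, prior$row_feature_ids, prior$col_feature_ids)
}

#' Randomly rewire a fraction of bipartite edges
#'
#' Robustness probe: removes `ceiling(fraction * |E|)` uniformly chosen edges
#' and adds the same number of uniformly chosen absent pairs, preserving the
#' edge count. Used to measure how sensitive classification performance is to
#' corruption of the cross-omics prior.
#'
#' @param bip a [bipartite_graph()].
#' @param fraction fraction of edges to rewire, in \[0, 1\].
#' @param seed integer RNG seed for reproducibility.
#' @return a rewired [bipartite_graph()] with the same edge count (best effort
#'   with a warning if the graph is too dense to place all replacement edges).
#' @export
rewire_bipartite <- function(bip, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]")
  }
  B <- bip$incidence
  edge_idx <- which(B == 1)
  m <- length(edge_idx)
  n_rew <- ceiling(fraction * m)
  if (n_rew == 0L) return(bip)
  old_rng <- local_seed(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  drop <- sample(edge_idx, n_rew)
  B[drop] <- 0
  absent <- which(B == 0)
  if (length(absent) < n_rew) {
    warning("graph too dense to place all replacement edges; adding ", length(absent))
    n_rew <- length(absent)
  }
  add <- if (length(absent) == 1L) absent else sample(absent, n_rew)
  B[add] <- 1
  bipartite_graph(B, bip$row_feature_ids, bip$col_feature_ids)
}

#' Export a graph as an edge list
#'
#' @param graph a `feature_graph` or `bipartite_graph`.
#' @return data.frame with columns `source`, `target` (feature identifiers);
#'   intra-omics edges are listed once (upper triangle).
#' @export
graph_to_edges <- function(graph) {
  if (inherits(graph, "feature_graph")) {
    A <- graph$adjacency
    idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    data.frame(source = graph$feature_ids[idx[, 1L]],
               target = graph$feature_ids[idx[, 2L]],
               stringsAsFactors = FALSE)
  } else if (inherits(graph, "bipartite_graph")) {
    idx <- which(graph$incidence == 1, arr.ind = TRUE)
    data.frame(source = graph$col_feature_ids[idx[, 2L]],
               target = graph$row_feature_ids[idx[, 1L]],
               stringsAsFactors = FALSE)
  } else {
    stop("unsupported graph class")
  }
}

# ---- internal helpers -------------------------------------------------------

graph_adjacency <- function(g) {
  if (inherits(g, "feature_graph")) g$adjacency else as.matrix(g)
}

graph_ids <- function(g, d) {
  if (inherits(g, "feature_graph")) return(g$feature_ids)
  ids <- rownames(as.matrix(g))
  if (is.null(ids)) ids <- paste0("f", seq_len(d))
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed scoping: set the RNG to `seed` and return the previous state so the
# caller can restore it (keeps library calls from perturbing user RNG streams).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d x %d features, %d edges\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' @export
print.normalized_graph <- function(x, ...) {
  cat(sprintf("<normalized_graph> %d features\n", length(x$feature_ids)))
  invisible(x)
}

#' @export
print.normalized_bipartite <- function(x, ...) {
  cat(sprintf("<normalized_bipartite> %d x %d\n",
              nrow(x$hat_Bu), ncol(x$hat_Bu)))
  invisible(x)
}
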