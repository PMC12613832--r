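#' K-nearest-neighbour imputation
#'
#' Replaces each missing entry by the mean of that feature over the K nearest
#' samples, with distances computed as root-mean-square Euclidean distance
#' over mutually observed features. For each missing value the K nearest
#' samples *observing that feature* are used; a feature observed nowhere is
#' dropped with a warning.
#'
#' @param X numeric matrix, samples x features, `NA` marking missing entries.
#' @param K number of neighbours (default 5).
#' @return completed matrix (possibly with all-missing features dropped).
#' @export
knn_impute <- function(X, K = 5L) {
  X <- as.matrix(X)
  if (!anyNA(X)) return(X)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " feature(s) missing in every sample were dropped")
    X <- X[, !all_missing, drop = FALSE]
  }
  O <- !is.na(X)
  Xz <- X
  Xz[!O] <- 0
  Om <- O * 1
  # squared-distance numerator over co-observed features and the co-counts
  SS <- Xz^2
  num <- SS %*% t(Om) + Om %*% t(SS) - 2 * tcrossprod(Xz)
  cnt <- tcrossprod(Om)
  D2 <- num / cnt                       # mean squared difference; NaN when no overlap
  diag(D2) <- Inf
  D2[!is.finite(D2)] <- Inf

  need <- which(rowSums(!O) > 0L)
  for (i in need) {
    ord <- order(D2[i, ])
    miss_feats <- which(!O[i, ])
    for (j in miss_feats) {
      donors <- ord[O[ord, j]]
      donors <- donors[is.finite(D2[i, donors])]
      if (length(donors) == 0L) {
        X[i, j] <- mean(X[, j], na.rm = TRUE)
      } else {
        use <- donors[seq_len(min(K, length(donors)))]
        X[i, j] <- mean(X[use, j])
      }
    }
  }
  X
}

#' Keep the most variable features
#'
#' Retains the `n_keep` features with the largest sample variance
#' (denominator n - 1), ordered by descending variance with ties broken by
#' original column order. Typical settings for expression data are 1000
#' features for mRNA, 200 for miRNA and 1000 for DNA methylation.
#'
#' @param X samples x features matrix.
#' @param n_keep number of features to keep; when it exceeds the feature
#'   count, all features are kept with a warning.
#' @return matrix restricted (and reordered) to the selected features; the
#'   kept identifiers are available as `colnames`.
#' @export
top_variance_select <- function(X, n_keep) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (n_keep > d) {
    warning("n_keep (", n_keep, ") exceeds the feature count (", d, "); keeping all")
    n_keep <- d
  }
  v <- apply(X, 2L, stats::var)
  ord <- order(-v)                      # stable: ties keep original order
  X[, ord[seq_len(n_keep)], drop = FALSE]
}

#' Restrict features to network nodes
#'
#' Keeps only the features present in `node_ids` — intended to be the union
#' of the node sets of the intra- and inter-omics graphs that have at least
#' one edge — preserving the input column order.
#'
#' @param X samples x features matrix with feature identifiers as colnames.
#' @param node_ids character vector of connected node identifiers.
#' @return the restricted matrix.
#' @export
restrict_to_network <- function(X, node_ids) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs feature identifiers as colnames")
  keep <- colnames(X) %in% node_ids
  if (!any(keep)) {
    stop("no feature of X appears in the network node set; ",
         "check that identifiers use the same vocabulary (first network ids: ",
         paste(utils::head(node_ids, 3L), collapse = ", "), ")")
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(n_drop, " feature(s) without network edges dropped")
  }
  X[, keep, drop = FALSE]
}

# z-score each column by the subset's own statistics; constant columns are
# centred but not scaled.
standardize_matrix <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, sd_, "/")
}

# one stratified train/val/test split (indices only)
split_indices <- function(y, seed, test_frac = 0.2, val_frac = 0.2) {
  old_rng <- local_seed(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  y <- as.factor(y)
  if (any(table(y) < 5L)) {
    warning("a class has fewer than 5 samples; stratification is best effort")
  }
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n_test <- round(test_frac * length(idx))
    test <- c(test, idx[seq_len(n_test)])
  }
  rest <- setdiff(seq_along(y), test)
  val <- integer(0)
  yr <- y[rest]
  for (cl in levels(y)) {
    idx <- sample(rest[yr == cl])
    n_val <- round(val_frac * length(idx))
    val <- c(val, idx[seq_len(n_val)])
  }
  train <- setdiff(rest, val)
  list(train = sort(train), val = sort(val), test = sort(test))
}

# labels as integer codes 0..nc-1 (numeric input is assumed already coded)
label_codes <- function(y) {
  if (is.factor(y) || is.character(y)) as.integer(as.factor(y)) - 1L
  else as.integer(y)
}

# materialize one split: per-subset standardized matrices + labels
make_split <- function(X, y, seed, test_frac = 0.2, val_frac = 0.2) {
  if (is.matrix(X)) X <- list(X)
  yc <- label_codes(y)
  idx <- split_indices(y, seed, test_frac, val_frac)
  subset_of <- function(rows) {
    list(X = lapply(X, function(x) standardize_matrix(x[rows, , drop = FALSE])),
         y = yc[rows], idx = rows)
  }
  out <- list(train = subset_of(idx$train), val = subset_of(idx$val),
              test = subset_of(idx$test), seed = seed)
  class(out) <- "omics_split"
  out
}

#' Repeated stratified splits with leakage-free standardization
#'
#' For each repeat: a stratified 80/20 train/test split, then a stratified
#' 80/20 split of the training portion into training and validation. Each of
#' the three subsets is z-scored per feature using only its own mean and
#' standard deviation, so no statistic crosses subset boundaries. Repeat `r`
#' uses seed `seed + r`, making the whole collection reproducible from the
#' base seed.
#'
#' @param X one samples x features matrix or a list of them (shared sample
#'   axis).
#' @param y per-sample labels, coded 0..nc-1 (or coercible).
#' @param n_repeats number of repeated splits (100 for protocol-faithful
#'   runs; use fewer for quick checks).
#' @param seed base seed.
#' @param test_frac,val_frac split fractions (defaults 0.2 and 0.2).
#' @return list of splits; each has `train`, `val`, `test` (each with
#'   standardized `X` list, integer `y`, sample indices `idx`) and `seed`.
#' @export
make_splits <- function(X, y, n_repeats = 100L, seed = 1L,
                        test_frac = 0.2, val_frac = 0.2) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  lapply(seq_len(n_repeats), function(r) {
    make_split(X, y, seed = seed + r, test_frac = test_frac,
               val_frac = val_frac)
  })
}
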