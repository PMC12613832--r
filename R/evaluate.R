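#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive sample receives a higher
#' score than a uniformly chosen negative one, with ties counting one half
#' (the rank/Wilcoxon formulation).
#'
#' @param labels binary labels (0/1, logical, or two-level factor).
#' @param scores numeric scores, higher meaning more positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  y <- label_codes(labels)
  if (length(y) != length(scores)) stop("labels and scores disagree in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index classification threshold
#'
#' Scans the distinct observed scores as candidate thresholds (a sample is
#' predicted positive when its score is at or above the threshold) and
#' returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken by the smallest optimal threshold.
#'
#' @inheritParams auroc
#' @return the optimal threshold (one of the observed score values).
#' @export
youden_threshold <- function(labels, scores) {
  y <- label_codes(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("threshold undefined: both classes must be present")
  cand <- sort(unique(scores))
  best_t <- cand[1L]
  best_j <- -Inf
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / n1
    spec <- sum(!pred & y == 0) / n0
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

#' Matthews correlation coefficient
#'
#' Binary MCC from the confusion matrix, generalized to any number of classes
#' by the multi-category formulation
#' \eqn{(c s - \sum_k p_k t_k) / \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}
#' (c = correct predictions, s = total, p_k/t_k = predicted/true class
#' counts), which reduces exactly to the binary formula for two classes.
#' Defined as 0 when any marginal term is zero (e.g. all-one-class
#' predictions).
#'
#' @param labels true labels.
#' @param predicted predicted labels on the same coding.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  lv <- sort(unique(c(labels, predicted)))
  C <- table(factor(labels, levels = lv), factor(predicted, levels = lv))
  s <- sum(C)
  c_ <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- c_ * s - sum(p_k * t_k)
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Bundle a multi-omics dataset for the evaluation pipeline
#'
#' @param X list of samples x features matrices (shared sample axis), one per
#'   omics block.
#' @param y per-sample labels.
#' @param bipartite optional prior cross-omics network(s): a single
#'   [bipartite_graph()] for two blocks, or a list named `"<i>_<j>"` for more.
#'   When absent, data-driven bipartite graphs are built per repeat from the
#'   training split.
#' @return list of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(X, y, bipartite = NULL) {
  if (is.matrix(X)) X <- list(X)
  n <- nrow(X[[1L]])
  if (any(vapply(X, nrow, 1L) != n)) stop("all omics blocks must share the sample axis")
  if (length(y) != n) stop("labels must cover every sample")
  if (inherits(bipartite, "bipartite_graph")) bipartite <- list("1_2" = bipartite)
  structure(list(X = X, y = y, bipartite = bipartite, n = n),
            class = "multiomics_dataset")
}

#' Pipeline configuration
#'
#' Hyperparameters for the full train/evaluate pipeline. Defaults follow the
#' package protocol: cosine affinity intra-omics graphs thresholded to a
#' median node degree near 10, two GCN layers, fusion weight `k = 0.5`,
#' weighted-message-passing training.
#'
#' @param mode `"both"`, `"intra_only"` or `"inter_only"`.
#' @param k fusion weight.
#' @param n_layers GCN layers.
#' @param leaky_slope Leaky ReLU slope.
#' @param strategy,alpha,pretrain_epochs,learning_rate,max_epochs,patience,min_improve
#'   see [train_config()].
#' @param n_repeats repeated splits (protocol value 100; scale down for quick
#'   runs).
#' @param seed base seed; repeat `r` derives split seed `seed + r` and weight
#'   seed `seed + 10000 + r`.
#' @param graph_method affinity for intra-omics graphs.
#' @param graph_eps intra-omics threshold; `NULL` = automatic by target
#'   degree.
#' @param target_degree target median degree for automatic thresholding.
#' @param bipartite_eps threshold for data-driven bipartite graphs (used only
#'   when the dataset carries no prior network); `NULL` = automatic.
#' @param rewire_fraction fraction of prior bipartite edges randomly rewired
#'   per repeat (robustness probe; 0 disables).
#' @param head_bias bias in the prediction head.
#' @param task `"binary"` or `"multiclass"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "both", k = 0.5, n_layers = 2L,
                            leaky_slope = 0.01,
                            strategy = "wmp", alpha = 0.5,
                            pretrain_epochs = 50L,
                            learning_rate = 1e-3, max_epochs = 500L,
                            patience = 20L, min_improve = 1e-6,
                            n_repeats = 20L, seed = 1L,
                            graph_method = "cosine", graph_eps = NULL,
                            target_degree = 10, bipartite_eps = NULL,
                            rewire_fraction = 0, head_bias = FALSE,
                            task = "binary") {
  structure(as.list(environment()), class = "pipeline_config")
}

# build the normalized graphs for one repeat from the training split
build_repeat_graphs <- function(data, split, config, repeat_seed) {
  M <- length(split$train$X)
  intra <- vector("list", M)
  for (m in seq_len(M)) {
    feats <- t(split$train$X[[m]])            # features x training samples
    aff <- compute_affinity(feats, method = config$graph_method)
    eps_m <- config$graph_eps %||% choose_epsilon(aff, config$target_degree)
    intra[[m]] <- normalize_sym(threshold_graph(aff, eps_m,
                                                omics_id = paste0("omics", m)))
  }
  bip <- list()
  for (i in seq_len(M - 1L)) {
    for (j in seq((i + 1L), M)) {
      key <- paste0(i, "_", j)
      bg <- if (!is.null(data$bipartite)) {
        data$bipartite[[key]]
      } else {
        A <- cross_affinity(t(split$train$X[[i]]), t(split$train$X[[j]]),
                            config$graph_method)
        eps_b <- config$bipartite_eps %||%
          stats::quantile(A, probs = max(0, 1 - config$target_degree / ncol(A)),
                          names = FALSE)
        bipartite_graph((A >= eps_b) * 1,
                        colnames(split$train$X[[i]]),
                        colnames(split$train$X[[j]]))
      }
      if (is.null(bg)) stop("no bipartite graph available for pair ", key)
      if (config$rewire_fraction > 0) {
        bg <- rewire_bipartite(bg, config$rewire_fraction, seed = repeat_seed)
      }
      bip[[key]] <- assemble_and_normalize_bipartite(bg)
    }
  }
  gcn_graphs(intra, bip)
}

#' Evaluate a trained model on a held-out split
#'
#' Binary task: AUROC from the predicted probabilities, then the Youden
#' threshold computed on the evaluation set's own ROC converts scores to
#' labels for the MCC. Multiclass: macro one-vs-rest AUROC and argmax labels
#' for the multi-category MCC.
#'
#' @param model trained [gcn_model()].
#' @param graphs [gcn_graphs()].
#' @param X list of matrices for the evaluation subset.
#' @param y labels for the evaluation subset.
#' @return list with `auroc`, `mcc`, `threshold` (NA for multiclass).
#' @export
evaluate_split <- function(model, graphs, X, y) {
  fw <- gcn_forward(model, graphs, X)
  y <- label_codes(y)
  if (model$task == "binary") {
    s <- fw$scores[, 1L]
    a <- auroc(y, s)
    thr <- youden_threshold(y, s)
    pred <- as.integer(s >= thr)
    list(auroc = a, mcc = mcc(y, pred), threshold = thr)
  } else {
    classes <- seq_len(model$n_out) - 1L
    present <- classes[classes %in% y & vapply(classes, function(cl) any(y != cl), TRUE)]
    aucs <- vapply(present, function(cl) auroc(as.integer(y == cl),
                                               fw$scores[, cl + 1L]), 1)
    pred <- max.col(fw$scores) - 1L
    list(auroc = mean(aucs), mcc = mcc(y, pred), threshold = NA_real_)
  }
}

#' Repeated train/evaluate protocol
#'
#' For each repeat: draw a stratified split ([make_splits()]), build the
#' intra-omics graphs from the standardized training matrix (and the
#' bipartite graphs from the dataset prior, or from training-data affinities
#' when no prior exists), initialize a fresh model, train with early stopping
#' and evaluate on the held-out test set. Per-repeat metrics and their
#' mean/sd aggregates are returned.
#'
#' @param data a [multiomics_dataset()].
#' @param config a [pipeline_config()].
#' @return object of class `eval_report`: list with `per_repeat` (data.frame
#'   repeat/auroc/mcc/threshold/best_epoch/stopped_epoch), `summary`
#'   (mean/sd per metric), `n_repeats`, `config`.
#' @export
repeated_eval <- function(data, config = pipeline_config()) {
  if (!inherits(data, "multiomics_dataset")) stop("data must be a multiomics_dataset")
  tc <- train_config(strategy = config$strategy, alpha = config$alpha,
                     max_epochs = config$max_epochs, patience = config$patience,
                     pretrain_epochs = config$pretrain_epochs,
                     learning_rate = config$learning_rate,
                     min_improve = config$min_improve, seed = config$seed)
  nc <- length(unique(label_codes(data$y)))
  rows <- vector("list", config$n_repeats)
  failures <- character(0)
  for (r in seq_len(config$n_repeats)) {
    res <- tryCatch({
      split <- make_split(data$X, data$y, seed = config$seed + r)
      graphs <- build_repeat_graphs(data, split, config,
                                    repeat_seed = config$seed + r)
      model <- gcn_model(dims = vapply(data$X, ncol, 1L), nc = nc,
                         n_layers = config$n_layers, k = config$k,
                         leaky_slope = config$leaky_slope, task = config$task,
                         mode = config$mode, head_bias = config$head_bias,
                         init_seed = config$seed + 10000L + r)
      fit <- train_gcn(model, graphs, split$train$X, split$train$y,
                       split$val$X, split$val$y, tc)
      ev <- evaluate_split(fit$model, graphs, split$test$X, split$test$y)
      data.frame(rep = r, auroc = ev$auroc, mcc = ev$mcc,
                 threshold = ev$threshold, best_epoch = fit$best_epoch,
                 stopped_epoch = fit$stopped_epoch)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("repeat %d: %s", r, conditionMessage(res)))
    } else {
      rows[[r]] <- res
    }
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per) || nrow(per) == 0L) {
    stop("every repeat failed; first error: ", failures[1L])
  }
  if (length(failures) > 0L) {
    warning("partial report: ", length(failures), " repeat(s) failed")
  }
  summary <- data.frame(
    metric = c("auroc", "mcc"),
    mean = c(mean(per$auroc), mean(per$mcc)),
    sd = c(stats::sd(per$auroc), stats::sd(per$mcc))
  )
  structure(list(per_repeat = per, summary = summary,
                 n_repeats = config$n_repeats, failures = failures,
                 config = unclass(config)),
            class = "eval_report")
}

#' Ablation runner: both branches vs single-branch models
#'
#' Runs [repeated_eval()] in the three modes with identical base seed, so all
#' three reports share the same splits and weight initializations and any
#' metric difference is attributable to the mode.
#'
#' @param data a [multiomics_dataset()].
#' @param config a [pipeline_config()]; its `mode` is overridden.
#' @return named list of three `eval_report`s: `both`, `intra_only`,
#'   `inter_only`.
#' @export
run_ablation <- function(data, config = pipeline_config()) {
  modes <- c("both", "intra_only", "inter_only")
  out <- lapply(modes, function(md) {
    cfg <- config
    cfg$mode <- md
    repeated_eval(data, cfg)
  })
  names(out) <- modes
  out
}

#' Fusion-weight sweep
#'
#' Runs [repeated_eval()] at each fusion weight with shared splits (same base
#' seed) and returns the mean metric curve over `k`.
#'
#' @param data a [multiomics_dataset()].
#' @param config a [pipeline_config()]; its `k` is overridden.
#' @param k_values fusion weights to evaluate (default 0.1 .. 0.9).
#' @return data.frame with `k`, `mean_auroc`, `sd_auroc`, `mean_mcc`,
#'   `sd_mcc`.
#' @export
run_k_sweep <- function(data, config = pipeline_config(),
                        k_values = seq(0.1, 0.9, by = 0.1)) {
  if (any(k_values < 0 | k_values > 1)) stop("k_values must lie in [0, 1]")
  rows <- lapply(k_values, function(kv) {
    cfg <- config
    cfg$k <- kv
    cfg$mode <- "both"
    rep <- repeated_eval(data, cfg)
    data.frame(k = kv,
               mean_auroc = rep$summary$mean[1L], sd_auroc = rep$summary$sd[1L],
               mean_mcc = rep$summary$mean[2L], sd_mcc = rep$summary$sd[2L])
  })
  do.call(rbind, rows)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d/%d repeats: AUROC %.4f +/- %.4f, MCC %.4f +/- %.4f\n",
              nrow(x$per_repeat), x$n_repeats,
              x$summary$mean[1L], x$summary$sd[1L],
              x$summary$mean[2L], x$summary$sd[2L]))
  invisible(x)
}
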