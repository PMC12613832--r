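#' Training configuration
#'
#' Collects every training hyperparameter with the package defaults:
#' full-batch adaptive-moment (Adam) gradient descent, learning rate 1e-3,
#' early stopping once the validation loss has failed to improve (strict
#' decrease by at least `min_improve`) for `patience` consecutive epochs.
#' For `strategy = "da"` the graph layers are first pretrained without labels
#' for `pretrain_epochs` epochs on the objective
#' `alpha * alignment + (1 - alpha) * reconstruction`, then the whole model
#' is fine-tuned end-to-end on the classification loss.
#'
#' @param strategy `"wmp"` (end-to-end weighted message passing) or `"da"`
#'   (dual-alignment pretraining followed by supervised fine-tuning).
#' @param alpha trade-off between alignment and reconstruction losses during
#'   pretraining, in \[0, 1\].
#' @param max_epochs maximum supervised epochs.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param pretrain_epochs unsupervised epochs for `strategy = "da"`.
#' @param learning_rate Adam step size.
#' @param min_improve minimal validation-loss decrease counted as improvement.
#' @param pretrain_layers `"final"` evaluates the pretraining losses at the
#'   last layer only, `"all"` sums them over layers.
#' @param seed integer seed recorded with the run.
#' @return list of class `train_config`.
#' @export
train_config <- function(strategy = c("wmp", "da"), alpha = 0.5,
                         max_epochs = 500L, patience = 20L,
                         pretrain_epochs = 100L, learning_rate = 1e-3,
                         min_improve = 1e-6, pretrain_layers = "final",
                         seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (patience < 1L) stop("patience must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(list(strategy = strategy, alpha = alpha,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 learning_rate = learning_rate, min_improve = min_improve,
                 pretrain_layers = pretrain_layers, seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() {
  list(m = list(), v = list(), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(weights, grads, opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(weights = weights, opt = opt)
}

# ---- pretraining ------------------------------------------------------------

#' Dual-alignment unsupervised pretraining
#'
#' Trains the graph-layer weights (no labels, head untouched) to minimize
#' `alpha * alignment_loss + (1 - alpha) * reconstruction_loss` by full-batch
#' Adam. At `alpha = 1` the objective is pure alignment, at `alpha = 0` pure
#' reconstruction.
#'
#' @param model a [gcn_model()] with `mode = "both"`.
#' @param graphs a [gcn_graphs()].
#' @param X list of n x d_m input matrices.
#' @param config a [train_config()] (uses `alpha`, `pretrain_epochs`,
#'   `learning_rate`, `pretrain_layers`).
#' @return list with the updated `model` and `history` (data.frame of epoch,
#'   loss, alignment, reconstruction).
#' @export
pretrain_dual <- function(model, graphs, X, config = train_config("da")) {
  opt <- adam_state()
  hist <- vector("list", config$pretrain_epochs)
  for (ep in seq_len(config$pretrain_epochs)) {
    pg <- pretrain_grads(model, graphs, X, config$alpha, config$pretrain_layers)
    if (!is.finite(pg$loss)) {
      stop("pretraining diverged at epoch ", ep, " (loss = ", pg$loss,
           "); lower the learning rate")
    }
    upd <- adam_step(model$weights, pg$grads, opt, config$learning_rate)
    model$weights <- upd$weights
    opt <- upd$opt
    hist[[ep]] <- data.frame(epoch = ep, loss = pg$loss,
                             alignment = pg$alignment,
                             reconstruction = pg$reconstruction)
  }
  list(model = model, history = do.call(rbind, hist))
}

# ---- supervised training ----------------------------------------------------

#' Train the multi-omics GCN with early stopping
#'
#' Optimizes the classification loss on the training split by full-batch Adam;
#' after every epoch the validation loss is evaluated, and training stops once
#' it has failed to improve for `patience` consecutive epochs. The returned
#' model carries the weights of the best validation epoch. For
#' `config$strategy = "da"`, [pretrain_dual()] runs first on the training
#' inputs.
#'
#' Training is deterministic: the only randomness is the weight
#' initialization, fixed by the model's `init_seed`.
#'
#' @param model a [gcn_model()].
#' @param graphs a [gcn_graphs()].
#' @param X_train,X_val lists of n x d_m matrices (samples x features).
#' @param y_train,y_val labels (`{0,1}` binary, `{0..nc-1}` multiclass).
#' @param config a [train_config()].
#' @return list with `model` (best-epoch weights), `history` (data.frame
#'   epoch/train_loss/val_loss), `best_epoch`, `stopped_epoch`, and
#'   `pretrain_history` (NULL for `strategy = "wmp"`).
#' @export
train_gcn <- function(model, graphs, X_train, y_train, X_val, y_val,
                      config = train_config()) {
  if (length(unique(as.integer(y_train))) < 2L) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  pre_hist <- NULL
  if (config$strategy == "da") {
    pre <- pretrain_dual(model, graphs, X_train, config)
    model <- pre$model
    pre_hist <- pre$history
  }
  opt <- adam_state()
  best_loss <- Inf
  best_weights <- model$weights
  best_epoch <- 0L
  wait <- 0L
  rows <- vector("list", config$max_epochs)
  stopped <- config$max_epochs
  for (ep in seq_len(config$max_epochs)) {
    sg <- supervised_grads(model, graphs, X_train, y_train)
    if (!is.finite(sg$loss)) {
      stop("training diverged at epoch ", ep, "; lower the learning rate")
    }
    upd <- adam_step(model$weights, sg$grads, opt, config$learning_rate)
    model$weights <- upd$weights
    opt <- upd$opt
    val_fw <- gcn_forward(model, graphs, X_val)
    val_loss <- classification_loss(y_val, val_fw$scores, model$task)
    rows[[ep]] <- data.frame(epoch = ep, train_loss = sg$loss,
                             val_loss = val_loss)
    if (val_loss < best_loss - config$min_improve) {
      best_loss <- val_loss
      best_weights <- model$weights
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- ep
        break
      }
    }
  }
  model$weights <- best_weights
  list(model = model,
       history = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       best_epoch = best_epoch, stopped_epoch = stopped,
       pretrain_history = pre_hist)
}
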