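# Differentiable layer primitives on (D, H, W, C) arrays. Convolutions are
# implemented in compiled code (src/conv3d.cpp); normalization, activation
# and the loss live here. Every *_bw returns analytic gradients; the test
# suite checks them against central finite differences.

LRELU_SLOPE <- 0.01
IN_EPS <- 1e-5

lrelu_fw <- function(x) .lrelu_fw(x)

lrelu_bw <- function(x, gy) .lrelu_bw(x, gy)

# Instance normalization with learnable per-channel scale/shift: statistics
# over the spatial extent of each channel (batch plays no role; patches are
# normalized one by one). The compiled kernel returns per-channel mean and
# inverse std; the backward pass recomputes xhat from the cached input.
# `act = TRUE` fuses the trailing leaky ReLU of a conv-norm-act unit.
in_fw <- function(x, gamma, beta, act = FALSE) {
  r <- .in_fw(x, gamma, beta, IN_EPS, act)
  list(y = r$y,
       cache = list(x = x, mu = r$mu, istd = r$istd, act = act,
                    y = if (act) r$y))
}

in_bw <- function(gy, gamma, cache) {
  r <- .in_bw(cache$x, gy, gamma, cache$mu, cache$istd, isTRUE(cache$act),
              cache$y %||% numeric(0))
  list(gx = r$gx, dgamma = r$dgamma, dbeta = r$dbeta)
}

softmax_channels <- function(x) .softmax4(x)

# Nearest-neighbour downsampling of an integer target by a power-of-two
# factor (used to supervise coarser decoder outputs).
downsample_target <- function(target, factor) {
  if (factor == 1L) return(target)
  d <- dim(target)
  target[seq(1, d[1], by = factor),
         seq(1, d[2], by = factor),
         seq(1, d[3], by = factor), drop = FALSE]
}

#' Deep-supervision loss weights
#'
#' @param dice_weight,ce_weight weights of the soft-Dice and cross-entropy
#'   terms (defaults 1 and 1, summed).
#' @param ds_weights per-supervision-level weights, finest first; normalized
#'   to sum to 1. Default halves per coarser level.
#' @param n_levels number of supervision levels used to build the default
#'   `ds_weights`.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(dice_weight = 1, ce_weight = 1,
                         ds_weights = NULL, n_levels = 1L) {
  if (is.null(ds_weights)) ds_weights <- 0.5^(seq_len(n_levels) - 1)
  if (any(ds_weights < 0) || dice_weight < 0 || ce_weight < 0)
    stopf("loss_weights: weights must be >= 0")
  ds_weights <- ds_weights / sum(ds_weights)
  structure(list(dice_weight = dice_weight, ce_weight = ce_weight,
                 ds_weights = ds_weights), class = "loss_weights")
}

# Pooled ("batch") soft Dice + cross-entropy at one resolution level, over a
# list of per-sample logit arrays. Foreground classes only enter the Dice
# term; intersections and sizes are pooled across the batch.
# Returns loss value and per-sample logit gradients.
level_loss <- function(logits_list, targets_list, dice_weight, ce_weight,
                       eps = 1e-5, want_grad = TRUE) {
  B <- length(logits_list)
  C <- dim(logits_list[[1]])[4]
  fg <- 2:C  # channel c corresponds to label c-1
  stats <- lapply(seq_len(B), function(b) {
    tg <- targets_list[[b]]
    storage.mode(tg) <- "integer"
    .dice_ce_stats(logits_list[[b]], tg)
  })
  num <- den <- numeric(C)
  for (b in seq_len(B)) {
    num <- num + 2 * stats[[b]]$sum_pg
    den <- den + stats[[b]]$sum_p + stats[[b]]$sum_g
  }
  dice_per_class <- num[fg] / (den[fg] + eps)
  dice_loss <- 1 - mean(dice_per_class)
  nvox <- vapply(targets_list, length, 0L)
  ce <- mean(vapply(seq_len(B), function(b) stats[[b]]$ce_sum / nvox[b], 0))
  value <- dice_weight * dice_loss + ce_weight * ce
  if (!want_grad) return(list(value = value, grads = NULL))
  n_fg <- length(fg)
  # dice: dL/dp_c(v) = -(dice_w/n_fg) * (2*g_v*(den+eps) - num) / (den+eps)^2
  coefA <- coefB <- numeric(C)
  for (c in fg) {
    dc <- den[c] + eps
    coefA[c] <- -dice_weight * 2 / dc / n_fg
    coefB[c] <- dice_weight * num[c] / dc^2 / n_fg
  }
  grads <- lapply(seq_len(B), function(b) {
    tg <- targets_list[[b]]
    storage.mode(tg) <- "integer"
    .dice_ce_grad(stats[[b]]$prob, tg, coefA, coefB,
                  ce_weight / (nvox[b] * B))
  })
  list(value = value, grads = grads)
}

#' Composite deep-supervision segmentation loss
#'
#' Per supervision level: `dice_weight * soft-Dice loss + ce_weight *
#' cross-entropy`, where the soft-Dice loss is `1 - mean` over foreground
#' classes of `2*sum(p*g) / (sum(p) + sum(g) + eps)` on softmax
#' probabilities `p` and one-hot targets `g` (intersections and sizes pooled
#' over the batch). Levels are combined with the normalized `ds_weights`;
#' targets are downsampled to coarser levels by nearest neighbour.
#'
#' @param preds list of logit arrays `(D, H, W, n_classes)`, finest first,
#'   one per supervision level — or a list of such lists for a batch.
#' @param target integer label array matching the finest level (or a list of
#'   such arrays for a batch).
#' @param w a [loss_weights()] object; `length(w$ds_weights)` must equal the
#'   number of levels.
#' @return scalar loss (finite).
#' @export
composite_loss <- function(preds, target, w = loss_weights(n_levels = length(preds))) {
  batched <- is.list(preds[[1]])
  preds_b <- if (batched) preds else list(preds)
  targets_b <- if (batched) target else list(target)
  L <- length(preds_b[[1]])
  if (length(w$ds_weights) != L)
    stopf("composite_loss: %d supervision levels but %d ds_weights",
          L, length(w$ds_weights))
  total <- 0
  for (l in seq_len(L)) {
    f <- 2L^(l - 1L)
    ll <- level_loss(lapply(preds_b, `[[`, l),
                     lapply(targets_b, downsample_target, factor = f),
                     w$dice_weight, w$ce_weight, want_grad = FALSE)
    total <- total + w$ds_weights[l] * ll$value
  }
  if (!is.finite(total)) stopf("composite_loss: non-finite loss")
  total
}

# Loss + per-level, per-sample logit gradients for training.
composite_loss_grad <- function(preds_b, targets_b, w) {
  L <- length(preds_b[[1]])
  B <- length(preds_b)
  total <- 0
  grads <- lapply(seq_len(B), function(b) vector("list", L))
  for (l in seq_len(L)) {
    f <- 2L^(l - 1L)
    ll <- level_loss(lapply(preds_b, `[[`, l),
                     lapply(targets_b, downsample_target, factor = f),
                     w$dice_weight, w$ce_weight, want_grad = TRUE)
    total <- total + w$ds_weights[l] * ll$value
    for (b in seq_len(B)) grads[[b]][[l]] <- w$ds_weights[l] * ll$grads[[b]]
  }
  list(value = total, grads = grads)
}

# Foreground soft Dice of a single prediction (used as validation
# pseudo-Dice): mean over foreground classes PRESENT in the target of the
# soft Dice between softmax probabilities and the one-hot target. NA when
# the target holds no foreground at all.
foreground_soft_dice <- function(logits, target, eps = 1e-5) {
  p <- softmax_channels(logits)
  C <- dim(p)[4]
  present <- (2:C)[vapply(2:C, function(c) any(target == c - 1), TRUE)]
  if (length(present) == 0) return(NA_real_)
  vals <- vapply(present, function(c) {
    g <- target == (c - 1)
    (2 * sum(p[, , , c] * g)) / (sum(p[, , , c]) + sum(g) + eps)
  }, 0)
  mean(vals)
}
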