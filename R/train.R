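# Single-stage training and the two-stage pipelines.
#
# Optimizer: SGD with Nesterov momentum and polynomial learning-rate decay
# (lr = lr0 * (1 - step/total)^exponent), the convention of patch-based
# segmentation frameworks. A training stage runs epochs x steps_per_epoch
# optimizer steps; per epoch a validation pseudo-Dice (foreground soft Dice
# on held-out foreground-centred patches) is recorded and both the final
# and the best-validation checkpoints are kept.

#' Polynomial learning-rate schedule
#'
#' @param step current optimizer step, `0 <= step <= total_steps`.
#' @param total_steps total number of steps.
#' @param lr0 initial learning rate (default 0.01).
#' @param exponent polynomial exponent (default 0.9).
#' @return the learning rate `lr0 * (1 - step/total_steps)^exponent`.
#' @export
lr_schedule <- function(step, total_steps, lr0 = 0.01, exponent = 0.9) {
  stopifnot(step >= 0, step <= total_steps, total_steps >= 1)
  lr0 * (1 - step / total_steps)^exponent
}

#' Training-stage configuration
#'
#' Bundles everything defining one training stage. Schedule defaults are
#' desk-scale; the full-scale reference schedule (1000 epochs of 250 steps,
#' batch 2, patch 320 x 256 x 64) is expressible but not a default.
#'
#' @param recipe a [channel_recipe()].
#' @param sampler `"default"` (foreground oversampling) or `"masked"`
#'   (prior-mask-guided).
#' @param fg_fraction foreground-oversampling probability for the default
#'   sampler (default 0.33).
#' @param prior_source `"none"`, `"stage1_output"`, or `"provided_prior"`;
#'   required (non-`"none"`) when `sampler = "masked"`.
#' @param patch_size integer length-3 training patch.
#' @param batch_size patches per optimizer step.
#' @param epochs,steps_per_epoch schedule; total steps = product.
#' @param lr0,poly_exponent,momentum optimizer settings (defaults 0.01,
#'   0.9, 0.99).
#' @param seed stage seed; fixes weight init, sampling, and augmentation.
#' @param augmentations character subset of
#'   `c("flip", "rot90", "intensity_scale", "gaussian_noise")`.
#' @param net a [net_config()]; its `in_channels` is overridden from
#'   `recipe`.
#' @param loss a [loss_weights()]; `ds_weights` length is aligned to
#'   `net$ds_levels`.
#' @param val_patches_per_case foreground-centred patches per validation
#'   case used for the epoch pseudo-Dice.
#' @return a `stage_config` object.
#' @export
stage_config <- function(recipe = channel_recipe(),
                         sampler = c("default", "masked"),
                         fg_fraction = 0.33,
                         prior_source = c("none", "stage1_output", "provided_prior"),
                         patch_size = c(32L, 32L, 32L),
                         batch_size = 2L,
                         epochs = 5L, steps_per_epoch = 20L,
                         lr0 = 0.01, poly_exponent = 0.9, momentum = 0.99,
                         seed = 1L,
                         augmentations = c("flip", "rot90"),
                         net = net_config(),
                         loss = NULL,
                         val_patches_per_case = 2L) {
  sampler <- match.arg(sampler)
  prior_source <- match.arg(prior_source)
  if (sampler == "masked" && prior_source == "none")
    stopf("stage_config: masked sampler requires a prior_source")
  stopifnot(epochs >= 1, steps_per_epoch >= 1, batch_size >= 1)
  bad <- setdiff(augmentations,
                 c("flip", "rot90", "intensity_scale", "gaussian_noise"))
  if (length(bad)) stopf("stage_config: unknown augmentations: %s",
                         paste(bad, collapse = ", "))
  net$in_channels <- recipe$n_channels
  if (is.null(loss)) loss <- loss_weights(n_levels = net$ds_levels)
  if (length(loss$ds_weights) != net$ds_levels)
    loss <- loss_weights(loss$dice_weight, loss$ce_weight,
                         n_levels = net$ds_levels)
  structure(list(recipe = recipe, sampler = sampler,
                 fg_fraction = fg_fraction, prior_source = prior_source,
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 lr0 = lr0, poly_exponent = poly_exponent,
                 momentum = momentum, seed = as.integer(seed),
                 augmentations = augmentations, net = net, loss = loss,
                 val_patches_per_case = as.integer(val_patches_per_case)),
            class = "stage_config")
}

rot90_4d <- function(a, k) {
  k <- k %% 4L
  while (k > 0) {
    a <- aperm(a, c(2, 1, 3, 4))
    a <- a[rev(seq_len(dim(a)[1])), , , , drop = FALSE]
    k <- k - 1L
  }
  a
}

flip_4d <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 4)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, drop = FALSE))
}

# Joint geometric + image-channel intensity augmentation of a patch.
# n_img_channels: leading channels treated as images (intensity ops apply);
# trailing channels (prior mask) only undergo geometry.
augment_patch <- function(input, target, augmentations, n_img_channels) {
  dim(target) <- c(dim(target), 1L)
  if ("flip" %in% augmentations) {
    for (axis in 1:3) if (runif(1) < 0.5) {
      input <- flip_4d(input, axis)
      target <- flip_4d(target, axis)
    }
  }
  if ("rot90" %in% augmentations && dim(input)[1] == dim(input)[2]) {
    k <- sample.int(4L, 1L) - 1L
    input <- rot90_4d(input, k)
    target <- rot90_4d(target, k)
  }
  if ("intensity_scale" %in% augmentations) {
    sc <- runif(1, 0.9, 1.1)
    for (c in seq_len(n_img_channels)) input[, , , c] <- input[, , , c] * sc
  }
  if ("gaussian_noise" %in% augmentations && runif(1) < 0.5) {
    sdv <- runif(1, 0, 0.1)
    for (c in seq_len(n_img_channels))
      input[, , , c] <- input[, , , c] +
        array(rnorm(prod(dim(input)[1:3]), sd = sdv), dim = dim(input)[1:3])
  }
  dim(target) <- dim(target)[1:3]
  storage.mode(target) <- "integer"
  list(input = input, target = target)
}

# Nested SGD-with-Nesterov update; params/grads/velocity share structure.
sgd_update <- function(params, grads, vel, lr, momentum) {
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      r <- sgd_update(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- r$params; vel[[nm]] <- r$vel
    } else {
      v <- momentum * vel[[nm]] + grads[[nm]]
      params[[nm]] <- params[[nm]] - lr * (grads[[nm]] + momentum * v)
      vel[[nm]] <- v
    }
  }
  list(params = params, vel = vel)
}

zero_like <- function(params)
  lapply(params, function(p) if (is.list(p)) zero_like(p) else p * 0)

add_grads <- function(a, b) {
  for (nm in names(a))
    a[[nm]] <- if (is.list(a[[nm]])) add_grads(a[[nm]], b[[nm]]) else a[[nm]] + b[[nm]]
  a
}

resolve_prior <- function(case, prior_source, stage1_masks = NULL) {
  switch(prior_source,
         none = NULL,
         provided_prior = {
           if (is.null(case$prior_mask))
             stopf("case '%s': prior_source = provided_prior but case has no prior_mask",
                   case$case_id)
           case$prior_mask
         },
         stage1_output = {
           pm <- stage1_masks[[case$case_id]]
           if (is.null(pm))
             stopf("case '%s': prior_source = stage1_output but no stage-1 mask supplied",
                   case$case_id)
           pm
         })
}

#' Train one stage
#'
#' Runs `epochs * steps_per_epoch` SGD steps with the configured sampler
#' and augmentations. Per epoch, the mean training loss, the learning rate,
#' and a validation pseudo-Dice (foreground soft Dice on
#' `val_patches_per_case` foreground-centred patches per validation case)
#' are recorded; the parameter set with the best pseudo-Dice is kept
#' alongside the final one.
#'
#' @param cfg a [stage_config()].
#' @param train_cases,val_cases lists of [case_record()]s.
#' @param stage1_masks named list of [labelmap()]s by case id; required when
#'   `prior_source = "stage1_output"`.
#' @param checkpoint_dir optional directory; when given, `final.rds` and
#'   `best.rds` checkpoints are written.
#' @param verbose print per-epoch progress.
#' @return list with `net` (final), `best_net`, `history` (data frame with
#'   epoch, mean_loss, val_dice, lr), `best_epoch`, and `mask_violations`
#'   (count of masked-sampler draws that failed to intersect the prior;
#'   asserted 0).
#' @export
train_stage <- function(cfg, train_cases, val_cases = list(),
                        stage1_masks = NULL, checkpoint_dir = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "stage_config"), length(train_cases) >= 1)
  if (cfg$prior_source == "stage1_output" && is.null(stage1_masks))
    stopf("train_stage: prior_source = stage1_output requires stage1_masks")
  check_patch_divisible(cfg$net, cfg$patch_size)
  with_seed(cfg$seed, {
    net <- build_network(cfg$net)
    vel <- zero_like(net$params)
    train_cases <- lapply(train_cases, precompute_norm, recipe = cfg$recipe)
    val_cases <- lapply(val_cases, precompute_norm, recipe = cfg$recipe)
    priors <- lapply(train_cases, resolve_prior,
                     prior_source = if (cfg$sampler == "masked") cfg$prior_source else "none",
                     stage1_masks = stage1_masks)
    empty_prior_warned <- FALSE
    mask_violations <- 0L
    n_img <- 1L + isTRUE(cfg$recipe$use_prior_image)
    total_steps <- cfg$epochs * cfg$steps_per_epoch
    history <- data.frame(epoch = seq_len(cfg$epochs), mean_loss = NA_real_,
                          val_dice = NA_real_, lr = NA_real_)
    best_dice <- -Inf; best_params <- net$params; best_epoch <- NA_integer_
    gstep <- 0L
    for (ep in seq_len(cfg$epochs)) {
      losses <- numeric(cfg$steps_per_epoch)
      for (st in seq_len(cfg$steps_per_epoch)) {
        lr <- lr_schedule(gstep, total_steps, cfg$lr0, cfg$poly_exponent)
        batch_in <- vector("list", cfg$batch_size)
        batch_tg <- vector("list", cfg$batch_size)
        for (b in seq_len(cfg$batch_size)) {
          ci <- sample.int(length(train_cases), 1L)
          case <- train_cases[[ci]]
          spec <- if (cfg$sampler == "masked") {
            pr <- priors[[ci]]
            if (is.null(pr) || !any(pr$labels > 0L)) {
              if (!empty_prior_warned) {
                warnf("case '%s': empty prior; using default sampling for such cases",
                      case$case_id)
                empty_prior_warned <- TRUE
              }
              sample_default(case, cfg$patch_size, cfg$fg_fraction)
            } else {
              s <- sample_masked(case, pr, cfg$patch_size)
              if (!patch_intersects_mask(s, pr))
                mask_violations <- mask_violations + 1L
              s
            }
          } else {
            sample_default(case, cfg$patch_size, cfg$fg_fraction)
          }
          xt <- extract_patch(case, spec, cfg$recipe)
          if (length(cfg$augmentations))
            xt <- augment_patch(xt$input, xt$target, cfg$augmentations, n_img)
          batch_in[[b]] <- xt$input
          batch_tg[[b]] <- xt$target
        }
        fwd <- lapply(batch_in, function(x) net_forward(net, x, want_cache = TRUE))
        lg <- composite_loss_grad(lapply(fwd, `[[`, "logits"), batch_tg, cfg$loss)
        losses[st] <- lg$value
        grads <- NULL
        for (b in seq_len(cfg$batch_size)) {
          g <- net_backward(net, fwd[[b]]$cache, lg$grads[[b]])
          grads <- if (is.null(grads)) g else add_grads(grads, g)
        }
        upd <- sgd_update(net$params, grads, vel, lr, cfg$momentum)
        net$params <- upd$params; vel <- upd$vel
        gstep <- gstep + 1L
      }
      # epoch-end validation pseudo-Dice on foreground-centred patches
      vdice <- NA_real_
      if (length(val_cases)) {
        vals <- c()
        for (vc in val_cases) {
          for (r in seq_len(cfg$val_patches_per_case)) {
            spec <- sample_default(vc, cfg$patch_size, fg_fraction = 1)
            xt <- extract_patch(vc, spec, cfg$recipe)
            lgt <- net_forward(net, xt$input)$logits[[1]]
            vals <- c(vals, foreground_soft_dice(lgt, xt$target))
          }
        }
        vdice <- mean(vals, na.rm = TRUE)
      }
      history$mean_loss[ep] <- mean(losses)
      history$val_dice[ep] <- vdice
      history$lr[ep] <- lr_schedule(gstep - 1L, total_steps, cfg$lr0,
                                    cfg$poly_exponent)
      if (is.finite(vdice) && vdice > best_dice) {
        best_dice <- vdice; best_params <- net$params; best_epoch <- ep
      }
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f val pseudo-Dice %s", ep,
                        cfg$epochs, mean(losses),
                        if (is.na(vdice)) "-" else sprintf("%.3f", vdice)))
    }
    if (!length(val_cases) || !is.finite(best_dice)) {
      best_params <- net$params; best_epoch <- cfg$epochs
    }
    best_net <- structure(list(cfg = net$cfg, params = best_params),
                          class = "network")
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(net, file.path(checkpoint_dir, "final.rds"), cfg$recipe,
                      extra = list(best_epoch = best_epoch))
      save_checkpoint(best_net, file.path(checkpoint_dir, "best.rds"),
                      cfg$recipe, extra = list(best_epoch = best_epoch))
    }
    list(net = net, best_net = best_net, history = history,
         best_epoch = best_epoch, mask_violations = mask_violations)
  })
}

predict_cases <- function(net, cases, recipe, patch, overlap = 0.5,
                          rois = NULL) {
  out <- list()
  for (case in cases) {
    roi <- if (!is.null(rois)) rois[[case$case_id]]
    out[[case$case_id]] <-
      sliding_window_predict(net, case, recipe, patch = patch,
                             overlap = overlap, roi = roi)
  }
  out
}

#' Pre-treatment two-stage pipeline
#'
#' `baseline` trains a single stage-1 model with default sampling. `c1` and
#' `c2` additionally run stage-1 inference on the training cohort (in-sample),
#' attach the outputs as priors, and train a refinement stage with
#' mask-guided sampling — `c1` with image-only input, `c2` with the stage-1
#' mask as an extra input channel. Final inference is an *unrestricted*
#' sliding window for all variants (which is what lets a `c1`-style model
#' hallucinate island components outside the stage-1 region).
#'
#' @param variant `"baseline"`, `"c1"` or `"c2"`.
#' @param train_cases,val_cases lists of [case_record()]s (a pre-treatment
#'   cohort; priors are not consulted).
#' @param cfg1 stage-1 [stage_config()] (sampler `"default"`).
#' @param cfg2 stage-2 [stage_config()]; must have
#'   `prior_source = "stage1_output"`; its recipe is forced to image-only for
#'   `c1` and image + prior-mask for `c2`.
#' @param infer_overlap sliding-window overlap for all inference.
#' @param checkpoint which checkpoint predicts: `"best"` (highest validation
#'   pseudo-Dice, the default — mirroring validation-based model selection)
#'   or `"final"`.
#' @return list with `stage1`, `stage2` (train_stage results; `stage2` NULL
#'   for baseline), `predictions` (named list over validation cases) and
#'   `variant`.
#' @export
run_pre_rt_pipeline <- function(variant = c("baseline", "c1", "c2"),
                                train_cases, val_cases,
                                cfg1, cfg2 = NULL, infer_overlap = 0.5,
                                checkpoint = c("best", "final")) {
  variant <- match.arg(variant)
  checkpoint <- match.arg(checkpoint)
  pick <- function(st) if (checkpoint == "best") st$best_net else st$net
  s1 <- train_stage(cfg1, train_cases, val_cases)
  if (variant == "baseline") {
    preds <- predict_cases(pick(s1), val_cases, cfg1$recipe, cfg1$patch_size,
                           infer_overlap)
    return(list(stage1 = s1, stage2 = NULL, predictions = preds,
                variant = variant))
  }
  stopifnot(!is.null(cfg2))
  if (cfg2$prior_source != "stage1_output")
    stopf("run_pre_rt_pipeline: cfg2 must have prior_source = 'stage1_output'")
  cfg2$recipe <- channel_recipe(use_prior_image = FALSE,
                                use_prior_mask = (variant == "c2"))
  cfg2$net$in_channels <- cfg2$recipe$n_channels
  # in-sample stage-1 inference provides the training priors
  s1_train_masks <- predict_cases(pick(s1), train_cases, cfg1$recipe,
                                  cfg1$patch_size, infer_overlap)
  train2 <- train_cases
  if (variant == "c2") {
    for (i in seq_along(train2))
      train2[[i]]$prior_mask <- s1_train_masks[[train2[[i]]$case_id]]
  }
  s1_val_masks <- predict_cases(pick(s1), val_cases, cfg1$recipe,
                                cfg1$patch_size, infer_overlap)
  val2 <- val_cases
  if (variant == "c2") {
    for (i in seq_along(val2))
      val2[[i]]$prior_mask <- s1_val_masks[[val2[[i]]$case_id]]
  }
  s2 <- train_stage(cfg2, train2, val2, stage1_masks = s1_train_masks)
  preds <- predict_cases(pick(s2), val2, cfg2$recipe, cfg2$patch_size,
                         infer_overlap)
  list(stage1 = s1, stage2 = s2, predictions = preds, variant = variant)
}

#' Mid-treatment pipeline
#'
#' A single training run per variant (the registered prior substitutes for
#' a first stage): `c1` ignores the priors entirely (image-only input,
#' default sampling, unrestricted inference); `c3` stacks the prior image
#' and prior mask as input channels (default sampling, unrestricted
#' inference); `staged_c3` additionally samples training patches from
#' within the prior mask and restricts sliding-window inference to patches
#' intersecting it.
#'
#' @param variant `"c1"`, `"c3"` or `"staged_c3"`.
#' @param train_cases,val_cases mid-treatment [case_record()]s carrying
#'   `prior_image` and `prior_mask` (not consulted by `c1`).
#' @param cfg a [stage_config()]; recipe/sampler/prior_source are forced to
#'   the variant's definition.
#' @param infer_overlap sliding-window overlap.
#' @param checkpoint which checkpoint predicts: `"best"` (highest validation
#'   pseudo-Dice; default) or `"final"`.
#' @return list with `stage` (train_stage result), `predictions` (named
#'   list over validation cases) and `variant`.
#' @export
run_mid_rt_pipeline <- function(variant = c("c1", "c3", "staged_c3"),
                                train_cases, val_cases, cfg,
                                infer_overlap = 0.5,
                                checkpoint = c("best", "final")) {
  variant <- match.arg(variant)
  checkpoint <- match.arg(checkpoint)
  if (variant == "c1") {
    cfg$recipe <- channel_recipe()
    cfg$sampler <- "default"; cfg$prior_source <- "none"
  } else {
    cfg$recipe <- channel_recipe(use_prior_image = TRUE, use_prior_mask = TRUE)
    for (case in c(train_cases, val_cases))
      if (is.null(case$prior_image) || is.null(case$prior_mask))
        stopf("run_mid_rt_pipeline: case '%s' lacks prior image/mask", case$case_id)
    if (variant == "staged_c3") {
      cfg$sampler <- "masked"; cfg$prior_source <- "provided_prior"
    } else {
      cfg$sampler <- "default"; cfg$prior_source <- "none"
    }
  }
  cfg$net$in_channels <- cfg$recipe$n_channels
  st <- train_stage(cfg, train_cases, val_cases)
  rois <- if (variant == "staged_c3")
    stats::setNames(lapply(val_cases, `[[`, "prior_mask"),
                    vapply(val_cases, `[[`, "", "case_id"))
  use_net <- if (checkpoint == "best") st$best_net else st$net
  preds <- predict_cases(use_net, val_cases, cfg$recipe, cfg$patch_size,
                         infer_overlap, rois = rois)
  list(stage = st, predictions = preds, variant = variant)
}
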