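# Gaussian-weighted sliding-window inference, optionally restricted to
# patches that intersect a prior region of interest.
#
# Per axis, patch starts are spaced by ceil(patch * (1 - overlap)); the
# final start is clipped so the last patch ends at the boundary. Softmax
# probabilities of covering patches are blended with a separable Gaussian
# weight (maximal at the patch centre), and the per-voxel argmax gives the
# label. In masked mode, voxels covered by no retained patch are labelled
# background — "not inferred" is an explicit output contract, not an
# accident.

axis_starts <- function(n, patch, overlap) {
  step <- max(1L, as.integer(ceiling(patch * (1 - overlap))))
  s <- seq.int(0L, max(0L, n - patch), by = step)
  last <- n - patch
  if (s[length(s)] != last) s <- c(s, last)
  unique(as.integer(s))
}

#' Enumerate sliding-window patches
#'
#' @param grid_shape integer length-3 grid size (voxels).
#' @param patch integer length-3 patch size; must not exceed `grid_shape`
#'   (smaller grids are padded upstream by [sliding_window_predict()]).
#' @param overlap fractional overlap in `[0, 1)` per axis (default 0.5).
#' @param roi optional [labelmap()] (or integer array): when given, only
#'   patches whose extent intersects a nonzero roi voxel (labels binarized)
#'   are kept. An empty roi raises an error; callers that want graceful
#'   degradation fall back to unmasked enumeration.
#' @return list of [patch_spec()]s.
#' @export
enumerate_patches <- function(grid_shape, patch, overlap = 0.5, roi = NULL) {
  grid_shape <- as.integer(grid_shape); patch <- as.integer(patch)
  stopifnot(length(grid_shape) == 3L, length(patch) == 3L,
            overlap >= 0, overlap < 1)
  if (any(patch > grid_shape))
    stopf("enumerate_patches: patch %s exceeds grid %s (pad the volume first)",
          paste(patch, collapse = "x"), paste(grid_shape, collapse = "x"))
  starts <- lapply(1:3, function(a) axis_starts(grid_shape[a], patch[a], overlap))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  specs <- lapply(seq_len(nrow(grid)), function(i)
    patch_spec(as.integer(grid[i, ]), patch))
  if (!is.null(roi)) {
    m <- labels_of(roi)
    if (!any(m > 0))
      stopf("enumerate_patches: roi is empty; fall back to unmasked inference")
    keep <- vapply(specs, patch_intersects_mask, TRUE, mask = m)
    specs <- specs[keep]
  }
  specs
}

#' Separable Gaussian blending kernel
#'
#' Centred at the patch centre with per-axis sigma `sigma_scale *
#' patch_axis`; floor-clamped to a small positive minimum and normalized to
#' a maximum of 1.
#'
#' @param patch integer length-3 patch size.
#' @param sigma_scale positive scale factor (default 1/8, the customary
#'   sliding-window setting).
#' @return array of strictly positive weights of shape `patch`.
#' @export
gaussian_kernel <- function(patch, sigma_scale = 1 / 8) {
  stopifnot(sigma_scale > 0)
  patch <- as.integer(patch)
  ax <- lapply(1:3, function(a) {
    n <- patch[a]
    ctr <- (n - 1) / 2
    sig <- sigma_scale * n
    exp(-((seq_len(n) - 1 - ctr)^2) / (2 * sig^2))
  })
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  w <- w / max(w)
  pmax(w, 1e-8)
}

#' Finest-level logits of a predictor for one input stack
#'
#' S3 generic so sliding-window inference accepts either a trained
#' `network` or any function mapping an input array `(D, H, W, C)` to a
#' logit array `(D, H, W, n_classes)` (useful for hand-built predictors in
#' equivariance tests).
#'
#' @param net a `network` or a function.
#' @param x input array.
#' @return logit array at the input resolution.
#' @export
predict_logits <- function(net, x) UseMethod("predict_logits")

#' @export
predict_logits.network <- function(net, x) net_forward(net, x)$logits[[1]]

#' @export
predict_logits.function <- function(net, x) net(x)

pad_to <- function(arr, target, fill = 0) {
  d <- dim(arr)
  if (all(d >= target)) return(arr)
  out <- array(fill, dim = pmax(d, target))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

#' Gaussian-weighted sliding-window prediction
#'
#' Accumulates `sum(weight * prob) / sum(weight)` per voxel over all
#' covering patches and takes the per-voxel argmax. With `roi` given, only
#' patches intersecting the binarized roi are inferred and voxels covered
#' by no retained patch are labelled background. Volumes smaller than the
#' patch are zero-padded for inference and cropped back.
#'
#' @param net a `network` (see [build_network()]).
#' @param case a [case_record()].
#' @param recipe a [channel_recipe()]; its channel count must match the
#'   network's `in_channels`.
#' @param patch integer length-3 inference patch size.
#' @param overlap fractional overlap (default 0.5).
#' @param roi optional [labelmap()] restricting the inferred patch set
#'   (e.g. the prior mask). Empty rois fall back to unmasked inference with
#'   a warning.
#' @param sigma_scale Gaussian kernel scale (see [gaussian_kernel()]).
#' @return a [labelmap()] with the case geometry.
#' @export
sliding_window_predict <- function(net, case, recipe = channel_recipe(),
                                   patch = c(32L, 32L, 32L), overlap = 0.5,
                                   roi = NULL, sigma_scale = 1 / 8) {
  stopifnot(inherits(case, "case_record"))
  if (inherits(net, "network") && recipe$n_channels != net$cfg$in_channels)
    stopf("sliding_window_predict: recipe has %d channels but network expects %d",
          recipe$n_channels, net$cfg$in_channels)
  dims <- grid_dims(case)
  patch <- as.integer(patch)
  work <- pmax(dims, patch)
  specs <- tryCatch(
    enumerate_patches(work, patch, overlap,
                      roi = if (!is.null(roi)) pad_to(labels_of(roi), work, 0L)),
    error = function(e) {
      if (grepl("roi is empty", conditionMessage(e))) {
        warnf("empty roi; falling back to unmasked inference")
        enumerate_patches(work, patch, overlap)
      } else stop(e)
    })
  kern <- gaussian_kernel(patch, sigma_scale)
  nc <- NULL
  acc <- NULL
  wsum <- array(0, dim = work)
  # channel stacks are built once on the padded grid via a padded pseudo-case
  padded <- case
  padded$image <- volume3d(pad_to(case$image$data, work), case$image$spacing,
                           case$image$origin)
  padded$reference <- labelmap(pad_to(case$reference$labels, work, 0L),
                               case$image$spacing, case$image$origin)
  if (!is.null(case$prior_image))
    padded$prior_image <- volume3d(pad_to(case$prior_image$data, work),
                                   case$image$spacing, case$image$origin)
  if (!is.null(case$prior_mask))
    padded$prior_mask <- labelmap(pad_to(case$prior_mask$labels, work, 0L),
                                  case$image$spacing, case$image$origin)
  padded <- precompute_norm(padded, recipe)
  for (sp in specs) {
    xt <- extract_patch(padded, sp, recipe)
    logits <- predict_logits(net, xt$input)
    prob <- softmax_channels(logits)
    if (is.null(acc)) {
      nc <- dim(prob)[4]
      acc <- array(0, dim = c(work, nc))
    }
    o <- sp$origin
    ix <- (o[1] + 1L):(o[1] + patch[1])
    iy <- (o[2] + 1L):(o[2] + patch[2])
    iz <- (o[3] + 1L):(o[3] + patch[3])
    for (c in seq_len(nc))
      acc[ix, iy, iz, c] <- acc[ix, iy, iz, c] + kern * prob[, , , c]
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + kern
  }
  lab <- array(0L, dim = work)
  covered <- wsum > 0
  if (!is.null(acc) && any(covered)) {
    accm <- matrix(acc, ncol = nc)
    cov_idx <- which(covered)
    lab[cov_idx] <- max.col(accm[cov_idx, , drop = FALSE], ties.method = "first") - 1L
  }
  lab <- lab[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
  labelmap(lab, case$image$spacing, case$image$origin)
}

#' Blended class probabilities (diagnostic variant of the predictor)
#'
#' Same accumulation as [sliding_window_predict()] but returns the
#' normalized probability array and the coverage mask instead of labels.
#'
#' @inheritParams sliding_window_predict
#' @return list with `prob` (array `(D, H, W, n_classes)`, rows summing to
#'   1 where covered), `covered` (logical array), `n_patches`.
#' @export
sliding_window_probs <- function(net, case, recipe = channel_recipe(),
                                 patch = c(32L, 32L, 32L), overlap = 0.5,
                                 roi = NULL, sigma_scale = 1 / 8) {
  dims <- grid_dims(case)
  patch <- as.integer(patch)
  work <- pmax(dims, patch)
  specs <- enumerate_patches(work, patch, overlap,
                             roi = if (!is.null(roi)) pad_to(labels_of(roi), work, 0L))
  kern <- gaussian_kernel(patch, sigma_scale)
  nc <- NULL
  acc <- NULL
  wsum <- array(0, dim = work)
  padded <- case
  padded$image <- volume3d(pad_to(case$image$data, work), case$image$spacing)
  padded$reference <- labelmap(pad_to(case$reference$labels, work, 0L),
                               case$image$spacing)
  if (!is.null(case$prior_image))
    padded$prior_image <- volume3d(pad_to(case$prior_image$data, work),
                                   case$image$spacing)
  if (!is.null(case$prior_mask))
    padded$prior_mask <- labelmap(pad_to(case$prior_mask$labels, work, 0L),
                                  case$image$spacing)
  padded <- precompute_norm(padded, recipe)
  for (sp in specs) {
    xt <- extract_patch(padded, sp, recipe)
    prob <- softmax_channels(predict_logits(net, xt$input))
    if (is.null(acc)) {
      nc <- dim(prob)[4]
      acc <- array(0, dim = c(work, nc))
    }
    o <- sp$origin
    ix <- (o[1] + 1L):(o[1] + patch[1])
    iy <- (o[2] + 1L):(o[2] + patch[2])
    iz <- (o[3] + 1L):(o[3] + patch[3])
    for (c in seq_len(nc))
      acc[ix, iy, iz, c] <- acc[ix, iy, iz, c] + kern * prob[, , , c]
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + kern
  }
  covered <- wsum > 0
  for (c in seq_len(nc)) {
    pl <- acc[, , , c]
    pl[covered] <- pl[covered] / wsum[covered]
    acc[, , , c] <- pl
  }
  list(prob = acc[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), , drop = FALSE],
       covered = covered[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE],
       n_patches = length(specs))
}

#' Count predicted connected components disjoint from a prior mask
#'
#' Flags "island" artifacts: foreground components of a prediction that do
#' not touch the (binarized) prior mask. 6-connectivity.
#'
#' @param pred a [labelmap()] prediction.
#' @param prior a [labelmap()] prior mask on the same grid.
#' @return list with `n_components` (total foreground components),
#'   `n_islands` (components with no voxel inside the prior), and
#'   `island_sizes`.
#' @export
count_disjoint_components <- function(pred, prior) {
  p <- labels_of(pred) > 0L
  m <- labels_of(prior) > 0L
  stopifnot(identical(dim(p), dim(m)))
  comp <- label_components(p)
  ncomp <- max(comp)
  if (ncomp == 0L)
    return(list(n_components = 0L, n_islands = 0L, island_sizes = integer(0)))
  touches <- tabulate(comp[m & comp > 0L], nbins = ncomp) > 0L
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  list(n_components = ncomp, n_islands = sum(!touches),
       island_sizes = sizes[!touches])
}

# 6-connected component labelling via BFS flood fill.
label_components <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, dim = d)
  idx_all <- which(mask)
  nxt <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx_all) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (k in 1:6) {
        ni <- sweep(ci, 2, offs[k, ], `+`)
        ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
          ni[, 2] >= 1 & ni[, 2] <= d[2] &
          ni[, 3] >= 1 & ni[, 3] <= d[3]
        if (!any(ok)) next
        lin <- ni[ok, 1] + d[1] * (ni[ok, 2] - 1) + d[1] * d[2] * (ni[ok, 3] - 1)
        new <- lin[mask[lin] & comp[lin] == 0L]
        if (length(new)) {
          comp[new] <- nxt
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  comp
}
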