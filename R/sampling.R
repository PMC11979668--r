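# Training-patch sampling and channel stacking.
#
# Two strategies are contrasted: the default sampler draws a configurable
# fraction of patches centred on reference foreground voxels (foreground
# oversampling), the rest uniformly; the mask-guided sampler centres every
# patch on a voxel of a binarized prior mask, so each drawn patch intersects
# the prior. Patch origins are 0-based, extents half-open.

#' Patch specification
#'
#' @param origin integer length-3, 0-based voxel origin.
#' @param size integer length-3, patch extent in voxels.
#' @return a `patch_spec` object; the patch covers
#'   `[origin, origin + size)` per axis.
#' @export
patch_spec <- function(origin, size) {
  origin <- as.integer(origin); size <- as.integer(size)
  stopifnot(length(origin) == 3L, length(size) == 3L, all(size >= 1))
  structure(list(origin = origin, size = size), class = "patch_spec")
}

#' Input channel recipe
#'
#' Determines the channel stack the network sees, in fixed order
#' `[image, prior_image, prior_mask]`:
#' image only (`c1`-style), plus the registered prior image and/or the prior
#' mask as additional channels (`c2`/`c3`-style).
#'
#' @param use_prior_image include the registered prior image channel.
#' @param use_prior_mask include the prior mask as a raw integer-label channel.
#' @return a `channel_recipe`; `n_channels` gives the resulting stack depth.
#' @export
channel_recipe <- function(use_prior_image = FALSE, use_prior_mask = FALSE) {
  structure(list(use_image = TRUE,
                 use_prior_image = isTRUE(use_prior_image),
                 use_prior_mask = isTRUE(use_prior_mask),
                 n_channels = 1L + isTRUE(use_prior_image) + isTRUE(use_prior_mask)),
            class = "channel_recipe")
}

grid_dims <- function(case) dim(case$image$data)

# Clamp a centre voxel (0-based) to a valid patch origin.
origin_from_center <- function(center, size, dims) {
  pmin(pmax(center - size %/% 2L, 0L), pmax(dims - size, 0L))
}

#' Draw a patch with foreground oversampling
#'
#' With probability `fg_fraction` the patch is centred on a uniformly chosen
#' reference foreground voxel (then clipped to bounds), guaranteeing it
#' contains foreground; otherwise the origin is uniform over all valid
#' positions. If the reference holds no foreground at all, sampling falls
#' back to uniform with a warning.
#'
#' @param case a [case_record()].
#' @param size integer length-3 patch size; must not exceed the grid.
#' @param fg_fraction probability in `[0, 1]` of forcing foreground
#'   (default 0.33, the usual foreground-oversampling share).
#' @return a [patch_spec()]. Draws consume the R RNG stream; seed with
#'   `set.seed()` for reproducible sequences.
#' @export
sample_default <- function(case, size, fg_fraction = 0.33) {
  dims <- grid_dims(case)
  size <- as.integer(size)
  stopifnot(length(size) == 3L, fg_fraction >= 0, fg_fraction <= 1)
  if (any(size > dims))
    stopf("sample_default: patch %s exceeds grid %s",
          paste(size, collapse = "x"), paste(dims, collapse = "x"))
  if (fg_fraction > 0 && runif(1) < fg_fraction) {
    fg <- which(case$reference$labels > 0L)
    if (length(fg) == 0L) {
      warnf("case '%s': no foreground in reference; falling back to uniform sampling",
            case$case_id)
    } else {
      v <- fg[sample.int(length(fg), 1L)]
      center <- as.integer(arrayInd(v, dims)) - 1L
      return(patch_spec(origin_from_center(center, size, dims), size))
    }
  }
  origin <- vapply(1:3, function(a)
    sample.int(dims[a] - size[a] + 1L, 1L) - 1L, 0L)
  patch_spec(origin, size)
}

#' Draw a patch centred within a prior mask
#'
#' The patch centre is a uniformly chosen nonzero voxel of the binarized
#' prior (GTVp and GTVn merged), then clipped to bounds; every returned
#' patch therefore intersects the prior mask.
#'
#' @param case a [case_record()].
#' @param prior a [labelmap()] on the case grid; must contain at least one
#'   nonzero voxel. An empty prior raises an error — the training-time
#'   caller is expected to fall back to [sample_default()].
#' @param margin optional dilation margin (voxels) applied to the binarized
#'   prior before choosing the centre; default 0 (no dilation).
#' @inheritParams sample_default
#' @return a [patch_spec()].
#' @export
sample_masked <- function(case, prior, size, margin = 0L) {
  dims <- grid_dims(case)
  size <- as.integer(size)
  if (!identical(dim(prior$labels), dims))
    stopf("sample_masked: prior grid does not match case grid")
  if (any(size > dims))
    stopf("sample_masked: patch %s exceeds grid %s",
          paste(size, collapse = "x"), paste(dims, collapse = "x"))
  elig <- prior$labels > 0L
  if (margin > 0L) elig <- dilate_mask(elig, as.integer(margin))
  nz <- which(elig)
  if (length(nz) == 0L)
    stopf("sample_masked: prior mask is empty; fall back to sample_default")
  v <- nz[sample.int(length(nz), 1L)]
  center <- as.integer(arrayInd(v, dims)) - 1L
  patch_spec(origin_from_center(center, size, dims), size)
}

# cubic dilation of a logical mask by r voxels, via shifted unions
dilate_mask <- function(mask, r) {
  out <- mask
  d <- dim(mask)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift_array(mask, c(dx, dy, dz))
  }
  out
}

# z-score normalize a whole volume; near-constant volumes divide by 1.
zscore <- function(x, eps = 1e-8) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s < eps) s <- 1
  (x - m) / s
}

# Crop [origin, origin+size) from a 3D array, zero-padding out-of-bounds.
crop_pad <- function(arr, origin, size, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = size)
  lo <- pmax(origin, 0L); hi <- pmin(origin + size, d)
  if (any(hi <= lo)) return(out)
  dst_lo <- lo - origin + 1L; dst_hi <- hi - origin
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3]]
  out
}

#' Extract an input stack and target patch
#'
#' Channels appear in fixed order `[image, prior_image?, prior_mask?]`.
#' Image channels are z-score normalized over the whole volume (mean 0,
#' sd 1; near-constant volumes divide by 1); the prior-mask channel carries
#' raw integer labels cast to numeric. Regions outside the grid are
#' zero-padded after normalization. The target is the reference crop.
#'
#' @param case a [case_record()].
#' @param spec a [patch_spec()].
#' @param recipe a [channel_recipe()]; prior flags require the matching
#'   `case` fields.
#' @return list with `input` — array `(D, H, W, n_channels)` — and `target`
#'   — integer array `(D, H, W)`.
#' @export
extract_patch <- function(case, spec, recipe = channel_recipe()) {
  stopifnot(inherits(spec, "patch_spec"), inherits(recipe, "channel_recipe"))
  if (recipe$use_prior_image && is.null(case$prior_image))
    stopf("extract_patch: recipe needs prior_image but case '%s' has none",
          case$case_id)
  if (recipe$use_prior_mask && is.null(case$prior_mask))
    stopf("extract_patch: recipe needs prior_mask but case '%s' has none",
          case$case_id)
  o <- spec$origin; sz <- spec$size
  # whole-volume normalization; cached by precompute_norm() in hot loops
  img_norm <- case$.image_norm %||% zscore(case$image$data)
  chans <- list(crop_pad(img_norm, o, sz))
  if (recipe$use_prior_image) {
    pi_norm <- case$.prior_image_norm %||% zscore(case$prior_image$data)
    chans <- c(chans, list(crop_pad(pi_norm, o, sz)))
  }
  if (recipe$use_prior_mask) {
    pm <- case$prior_mask$labels
    storage.mode(pm) <- "double"
    chans <- c(chans, list(crop_pad(pm, o, sz)))
  }
  input <- array(unlist(chans, use.names = FALSE), dim = c(sz, length(chans)))
  target <- crop_pad(case$reference$labels, o, sz, fill = 0L)
  storage.mode(target) <- "integer"
  list(input = input, target = target)
}

# Attach cached z-scored volumes to a case so repeated extract_patch calls
# skip the whole-volume normalization.
precompute_norm <- function(case, recipe) {
  case$.image_norm <- zscore(case$image$data)
  if (recipe$use_prior_image && !is.null(case$prior_image))
    case$.prior_image_norm <- zscore(case$prior_image$data)
  case
}

#' Does a patch contain at least one nonzero voxel of a mask?
#' @param spec a [patch_spec()].
#' @param mask a [labelmap()] or integer array.
#' @return logical.
#' @export
patch_intersects_mask <- function(spec, mask) {
  m <- labels_of(mask)
  sub <- crop_pad(m, spec$origin, spec$size, fill = 0L)
  any(sub > 0)
}
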