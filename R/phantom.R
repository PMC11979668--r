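# Synthetic longitudinal phantom generator.
#
# Each case is a pair of timepoints: a "pre" scan with one bright GTVp
# ellipsoid and n_gtvn GTVn ellipsoids over a textured background, and a
# "mid" scan with the same anatomy after isotropic lesion shrinkage. The mid
# timepoint carries the pre image and reference as a slightly misaligned
# "registered" prior, emulating the residual error of deformable
# registration by a rigid integer-voxel translation.

#' Phantom generation parameters
#'
#' Defaults describe a desk-scale longitudinal head-and-neck phantom:
#' a 48 x 48 x 32 voxel grid at 1 x 1 x 1.2 mm (mildly anisotropic, as
#' typical for T2 MRI), one primary lesion of 6-10 mm radius, two nodal
#' lesions of 3-5 mm radius, lesion/background contrast an order of
#' magnitude above the noise floor, 40% linear shrinkage mid-treatment and
#' up to 2 mm prior misalignment.
#'
#' @param shape integer length-3, grid size in voxels.
#' @param spacing numeric length-3, mm per voxel.
#' @param n_gtvn number of nodal lesions (label 2); may be 0.
#' @param gtvp_radius_range,gtvn_radius_range numeric length-2, min/max
#'   mean lesion radius in mm (per-axis radii vary +-20% around the mean).
#' @param lesion_contrast intensity added inside lesions, in units of the
#'   background noise scale.
#' @param noise_sd standard deviation of additive white Gaussian noise.
#' @param shrink_factor mid-treatment radius multiplier, in (0, 1].
#' @param prior_jitter_mm upper bound (mm) on the rigid translation applied
#'   to the "registered" prior image and mask.
#' @param seed integer seed; generation is bit-reproducible given
#'   identical parameters and seed.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(48, 48, 32),
                           spacing = c(1, 1, 1.2),
                           n_gtvn = 2,
                           gtvp_radius_range = c(6, 10),
                           gtvn_radius_range = c(3, 5),
                           lesion_contrast = 3,
                           noise_sd = 0.3,
                           shrink_factor = 0.6,
                           prior_jitter_mm = 2,
                           seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            n_gtvn >= 0,
            length(gtvp_radius_range) == 2L, length(gtvn_radius_range) == 2L)
  if (any(gtvp_radius_range <= 0) || diff(gtvp_radius_range) < 0 ||
      any(gtvn_radius_range <= 0) || diff(gtvn_radius_range) < 0)
    stopf("phantom_params: radius ranges must be positive and ordered")
  if (shrink_factor <= 0 || shrink_factor > 1)
    stopf("phantom_params: shrink_factor must lie in (0, 1]")
  if (prior_jitter_mm < 0) stopf("phantom_params: prior_jitter_mm must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_gtvn = as.integer(n_gtvn),
                 gtvp_radius_range = as.numeric(gtvp_radius_range),
                 gtvn_radius_range = as.numeric(gtvn_radius_range),
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 shrink_factor = shrink_factor,
                 prior_jitter_mm = prior_jitter_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# World (mm) coordinates of voxel centres along each axis, 0-based indices.
axis_coords <- function(shape, spacing)
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])

# Logical mask of voxels whose centre lies inside the ellipsoid
# sum(((x - centre) / radii)^2) <= 1, with centre and radii in mm.
voxelize_ellipsoid <- function(shape, spacing, center, radii) {
  cc <- axis_coords(shape, spacing)
  u <- (cc[[1]] - center[1]) / radii[1]
  v <- (cc[[2]] - center[2]) / radii[2]
  w <- (cc[[3]] - center[3]) / radii[3]
  q <- outer(outer(u^2, v^2, `+`), w^2, `+`)
  q <= 1
}

# Smooth low-frequency field: coarse seeded Gaussian grid, trilinearly
# upsampled. Emulates MRI bias-field-like background variation.
smooth_field <- function(shape, coarse = 6L) {
  cs <- pmax(2L, pmin(shape, coarse))
  g <- array(rnorm(prod(cs)), dim = cs)
  idx <- lapply(1:3, function(a) {
    if (shape[a] == 1L) rep(1, 1)
    else seq(1, cs[a], length.out = shape[a])
  })
  lin <- function(pos, n) {
    lo <- pmin(floor(pos), n - 1L); hi <- lo + 1L; w <- pos - lo
    list(lo = as.integer(lo), hi = as.integer(hi), w = w)
  }
  ix <- lin(idx[[1]], cs[1]); iy <- lin(idx[[2]], cs[2]); iz <- lin(idx[[3]], cs[3])
  out <- array(0, dim = shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- if (dx == 0) ix$lo else ix$hi
    yi <- if (dy == 0) iy$lo else iy$hi
    zi <- if (dz == 0) iz$lo else iz$hi
    wx <- if (dx == 0) 1 - ix$w else ix$w
    wy <- if (dy == 0) 1 - iy$w else iy$w
    wz <- if (dz == 0) 1 - iz$w else iz$w
    out <- out + array(g[xi, yi, zi, drop = FALSE], dim = shape) *
      outer(outer(wx, wy), wz)
  }
  out
}

place_lesions <- function(params) {
  ext <- (params$shape - 1) * params$spacing
  draw_one <- function(rng) {
    rmean <- runif(1, rng[1], rng[2])
    radii <- rmean * runif(3, 0.8, 1.2)
    list(radii = radii, rmax = max(radii))
  }
  lesions <- list()
  n_total <- 1L + params$n_gtvn
  for (k in seq_len(n_total)) {
    rng <- if (k == 1L) params$gtvp_radius_range else params$gtvn_radius_range
    placed <- FALSE
    for (attempt in 1:100) {
      les <- draw_one(rng)
      margin <- les$rmax + 1
      if (any(ext - 2 * margin <= 0))
        stopf("phantom: lesion radius %.1f mm does not fit grid extent %s mm; increase 'shape'",
              les$rmax, paste(round(ext, 1), collapse = "x"))
      ctr <- vapply(1:3, function(a) runif(1, margin, ext[a] - margin), 0)
      ok <- TRUE
      for (o in lesions) {
        if (sqrt(sum((ctr - o$center)^2)) < les$rmax + o$rmax + 1) { ok <- FALSE; break }
      }
      if (ok) {
        les$center <- ctr
        les$label <- if (k == 1L) 1L else 2L
        lesions[[k]] <- les
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("phantom: could not place %d non-overlapping lesions in 100 attempts; increase 'shape'",
            n_total)
  }
  lesions
}

render_reference <- function(params, lesions, scale = 1) {
  lab <- array(0L, dim = params$shape)
  for (les in lesions) {
    m <- voxelize_ellipsoid(params$shape, params$spacing, les$center,
                            les$radii * scale)
    lab[m] <- les$label
  }
  lab
}

render_image <- function(params, bg, lesions, scale = 1) {
  img <- bg
  for (les in lesions) {
    m <- voxelize_ellipsoid(params$shape, params$spacing, les$center,
                            les$radii * scale)
    img[m] <- img[m] + params$lesion_contrast
  }
  img + array(rnorm(prod(params$shape), sd = params$noise_sd),
              dim = params$shape)
}

# Translate an array by an integer voxel shift, zero-filling exposed voxels.
shift_array <- function(arr, shift) {
  out <- array(if (is.integer(arr)) 0L else 0, dim = dim(arr))
  d <- dim(arr)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else        { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate one longitudinal phantom case pair
#'
#' @param params a [phantom_params()] object.
#' @param case_id character scalar.
#' @return a list with elements `pre` and `mid`, both [case_record()]s. The
#'   mid record carries `prior_image` / `prior_mask`: the pre image and
#'   reference translated by a rigid jitter of magnitude at most
#'   `prior_jitter_mm`.
#' @export
make_case <- function(params, case_id = "case_001") {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    lesions <- place_lesions(params)
    bg <- smooth_field(params$shape) * 0.5
    pre_img <- render_image(params, bg, lesions, scale = 1)
    pre_ref <- render_reference(params, lesions, scale = 1)
    mid_img <- render_image(params, bg, lesions, scale = params$shrink_factor)
    mid_ref <- render_reference(params, lesions, scale = params$shrink_factor)
    # rigid translation: direction uniform on the sphere, magnitude uniform
    # in [0, prior_jitter_mm]; truncation to whole voxels guarantees the
    # realised shift never exceeds the bound
    dirv <- rnorm(3)
    dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-12)
    t_mm <- dirv * runif(1, 0, params$prior_jitter_mm)
    shift_vox <- trunc(t_mm / params$spacing)
    sp <- params$spacing
    pre <- case_record(paste0(case_id, "_pre"),
                       image = volume3d(pre_img, sp),
                       reference = labelmap(pre_ref, sp))
    mid <- case_record(paste0(case_id, "_mid"),
                       image = volume3d(mid_img, sp),
                       reference = labelmap(mid_ref, sp),
                       prior_image = volume3d(shift_array(pre_img, shift_vox), sp),
                       prior_mask = labelmap(shift_array(pre_ref, shift_vox), sp))
    list(pre = pre, mid = mid)
  })
}

#' Inject a bright decoy blob into a case image
#'
#' Adds a lesion-like ellipsoid to the image only — the reference and any
#' prior mask are left untouched — providing a tumour-mimicking distractor
#' outside the prior region. Useful for studying island artifacts of
#' mask-sampled models under unrestricted inference.
#'
#' @param case a [case_record()].
#' @param radius_mm decoy radius (mm, isotropic).
#' @param contrast intensity added inside the decoy.
#' @param center_mm optional length-3 centre (mm); by default the voxel
#'   farthest from all reference/prior foreground (and from the grid
#'   boundary) is chosen.
#' @return the modified [case_record()]; attribute `decoy_center_mm` holds
#'   the centre used.
#' @export
add_decoy_lesion <- function(case, radius_mm = 4, contrast = 3,
                             center_mm = NULL) {
  stopifnot(inherits(case, "case_record"))
  sp <- case$image$spacing
  shape <- dim(case$image$data)
  if (is.null(center_mm)) {
    fg <- case$reference$labels > 0L
    if (!is.null(case$prior_mask)) fg <- fg | case$prior_mask$labels > 0L
    idx <- which(fg)
    fgc <- if (length(idx)) (arrayInd(idx, shape) - 1) %*% diag(sp)
           else matrix(numeric(0), ncol = 3)
    ext <- (shape - 1) * sp
    margin <- radius_mm + 1
    cand <- as.matrix(expand.grid(
      seq(margin, ext[1] - margin, length.out = 5),
      seq(margin, ext[2] - margin, length.out = 5),
      seq(margin, ext[3] - margin, length.out = 5)))
    dmin <- if (nrow(fgc)) apply(cand, 1, function(p)
      min(sqrt(colSums((t(fgc) - p)^2)))) else rep(Inf, nrow(cand))
    center_mm <- cand[which.max(dmin), ]
  }
  m <- voxelize_ellipsoid(shape, sp, center_mm, rep(radius_mm, 3))
  case$image$data[m] <- case$image$data[m] + contrast
  case$.image_norm <- NULL
  attr(case, "decoy_center_mm") <- center_mm
  case
}

#' Generate a cohort of phantom case pairs
#'
#' Per-case seeds are derived deterministically from `seed`, so lesion
#' geometry varies across cases while the whole cohort is reproducible.
#'
#' @inheritParams make_case
#' @param n_cases number of case pairs (>= 1).
#' @param seed cohort seed; overrides `params$seed` per case.
#' @return a list of `n_cases` elements, each as returned by [make_case()].
#' @export
make_cohort <- function(params, n_cases, seed = params$seed) {
  stopifnot(inherits(params, "phantom_params"), n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    p <- params
    p$seed <- as.integer(derive_seed(seed, i))
    make_case(p, sprintf("case_%03d", i))
  })
}
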