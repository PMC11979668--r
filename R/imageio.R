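# Volume / label-map containers and NIfTI IO.
#
# Axis convention: arrays are indexed (x, y, z), matching the first three
# axes of the NIfTI affine. Only axis-aligned grids are supported; an affine
# with rotational components is rejected. Voxel coordinates are 0-based and
# patch extents are half-open [origin, origin + size).

#' Construct a 3D scalar volume
#'
#' A `volume3d` couples a numeric 3D array with its voxel spacing (mm per
#' voxel along x, y, z) and world origin (mm).
#'
#' @param data numeric 3D array, indexed (x, y, z).
#' @param spacing numeric length-3, mm per voxel; all components finite and > 0.
#' @param origin numeric length-3, mm; defaults to the zero vector.
#' @return an object of class `volume3d` with fields `data`, `spacing`, `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume3d: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("volume3d: spacing must be three finite positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("volume3d: origin must be three finite numbers")
  if (any(!is.finite(data)))
    stopf("volume3d: data contains NaN or Inf voxels")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Construct an integer label map
#'
#' A `labelmap` shares the geometry conventions of [volume3d()] but holds
#' integer class labels: 0 background, 1 primary gross tumour volume (GTVp),
#' 2 nodal gross tumour volume (GTVn).
#'
#' @param labels integer-valued 3D array with values in \{0, 1, 2\}.
#' @inheritParams volume3d
#' @return an object of class `labelmap` with fields `labels`, `spacing`, `origin`.
#' @export
labelmap <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("labelmap: 'labels' must be a 3D array")
  if (any(!is.finite(labels)))
    stopf("labelmap: labels contain NaN or Inf")
  if (any(labels != round(labels)) || any(labels < 0) || any(labels > 2))
    stopf("labelmap: labels must be integers in {0, 1, 2}")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("labelmap: spacing must be three finite positive numbers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "labelmap")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s, spacing %s mm, origin %s mm>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.labelmap <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<labelmap %s, spacing %s mm; bg/GTVp/GTVn voxels %s>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(tab, collapse = "/")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  da <- dim(a$data %||% a$labels); db <- dim(b$data %||% b$labels)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Assemble a patient case
#'
#' @param case_id character scalar identifier.
#' @param image [volume3d()]: the timepoint to segment.
#' @param reference [labelmap()]: reference segmentation for `image`.
#' @param prior_image optional [volume3d()]: registered earlier-timepoint image.
#' @param prior_mask optional [labelmap()]: earlier-timepoint segmentation
#'   (or a first-stage output) on the same grid.
#' @return an object of class `case_record`.
#' @export
case_record <- function(case_id, image, reference,
                        prior_image = NULL, prior_mask = NULL) {
  stopifnot(inherits(image, "volume3d"), inherits(reference, "labelmap"))
  if (!same_geometry(image, reference))
    stopf("case '%s': image and reference grids differ (shape/spacing/origin)",
          case_id)
  for (nm in c("prior_image", "prior_mask")) {
    p <- get(nm)
    if (!is.null(p) && !same_geometry(image, p))
      stopf("case '%s': %s grid differs from image grid", case_id, nm)
  }
  structure(list(case_id = as.character(case_id), image = image,
                 reference = reference, prior_image = prior_image,
                 prior_mask = prior_mask),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record '%s' %s%s>\n", x$case_id,
              paste(dim(x$image$data), collapse = "x"),
              if (!is.null(x$prior_mask)) " +prior" else ""))
  invisible(x)
}

nifti_geometry <- function(img, path) {
  x <- unclass(RNifti::xform(img))
  rot <- x[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stopf("'%s': affine has rotational components; only axis-aligned grids are supported",
          path)
  sp <- RNifti::pixdim(img)[1:3]
  list(spacing = as.numeric(sp), origin = as.numeric(x[1:3, 4]))
}

#' Read a 3D volume from NIfTI
#'
#' Spacing is taken from the header `pixdim`; the affine must be axis-aligned
#' (diagonal up to numerical noise), otherwise an error is raised. Volumes
#' containing NaN or Inf voxels are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("read_volume: file not found: '%s'", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stopf("'%s': expected a 3D volume, got %dD", path, length(dim(arr)))
  if (any(!is.finite(arr)))
    stopf("'%s': volume contains NaN/Inf voxels", path)
  g <- nifti_geometry(img, path)
  # plain array, shedding the niftiImage class and header attributes
  arr <- array(as.numeric(arr), dim = dim(arr)[1:3])
  volume3d(arr, spacing = g$spacing, origin = g$origin)
}

#' Read a label map from NIfTI
#'
#' @inheritParams read_volume
#' @return a [labelmap()]; voxel values must be in \{0, 1, 2\}.
#' @export
read_labelmap <- function(path) {
  v <- read_volume(path)
  if (any(v$data != round(v$data)) || any(v$data < 0) || any(v$data > 2))
    stopf("'%s': label values outside {0, 1, 2}", path)
  lab <- v$data
  storage.mode(lab) <- "integer"
  labelmap(lab, spacing = v$spacing, origin = v$origin)
}

write_nifti_grid <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 3D volume to NIfTI
#'
#' @param vol a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  write_nifti_grid(vol$data, vol$spacing, vol$origin, path, "double")
}

#' Write a label map to NIfTI (integer dtype)
#'
#' Writing then reading with [read_labelmap()] round-trips labels bit-exactly.
#'
#' @param map a [labelmap()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_labelmap <- function(map, path) {
  stopifnot(inherits(map, "labelmap"))
  if (any(map$labels < 0) || any(map$labels > 2))
    stopf("write_labelmap: labels outside {0, 1, 2}")
  write_nifti_grid(map$labels, map$spacing, map$origin, path, "int16")
}

#' Load a case from an on-disk layout
#'
#' Expects `<case_dir>/image.nii.gz` and `<case_dir>/ref.nii.gz`, plus
#' optionally `prior_image.nii.gz` and `prior_mask.nii.gz`. Geometry
#' consistency across all present grids is enforced.
#'
#' @param case_dir directory holding one case.
#' @param needs_prior if `TRUE`, missing prior files raise a configuration
#'   error instead of yielding empty prior fields.
#' @return a [case_record()]; `case_id` is the directory basename.
#' @export
load_case <- function(case_dir, needs_prior = FALSE) {
  if (!dir.exists(case_dir)) stopf("load_case: no such directory: '%s'", case_dir)
  pth <- function(nm) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(case_dir, paste0(nm, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }
  ip <- pth("image"); rp <- pth("ref")
  if (is.na(ip) || is.na(rp))
    stopf("load_case: '%s' must contain image and ref NIfTI files", case_dir)
  pi_p <- pth("prior_image"); pm_p <- pth("prior_mask")
  if (needs_prior && (is.na(pi_p) || is.na(pm_p)))
    stopf("load_case: '%s' lacks prior files but the configuration requires a prior",
          case_dir)
  case_record(basename(normalizePath(case_dir)),
              image = read_volume(ip),
              reference = read_labelmap(rp),
              prior_image = if (!is.na(pi_p)) read_volume(pi_p),
              prior_mask = if (!is.na(pm_p)) read_labelmap(pm_p))
}

#' Write a case to the on-disk layout understood by [load_case()]
#'
#' @param case a [case_record()].
#' @param dir output directory root; the case is written to `<dir>/<case_id>/`.
#' @return the case directory, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "case_record"))
  cd <- file.path(dir, case$case_id)
  dir.create(cd, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$image, file.path(cd, "image.nii.gz"))
  write_labelmap(case$reference, file.path(cd, "ref.nii.gz"))
  if (!is.null(case$prior_image))
    write_volume(case$prior_image, file.path(cd, "prior_image.nii.gz"))
  if (!is.null(case$prior_mask))
    write_labelmap(case$prior_mask, file.path(cd, "prior_mask.nii.gz"))
  invisible(cd)
}
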