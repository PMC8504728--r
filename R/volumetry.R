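#' Construct a mask stack
#'
#' A mask stack is an ordered sequence of 2D binary masks (one per axial CT
#' slice) plus the pixel spacing and slice thickness needed to convert pixel
#' counts into physical volume. The study geometry uses 5 mm thick slices.
#'
#' @param slices A list of logical (or 0/1) matrices, all the same
#'   dimensions, ordered inferior to superior; or a 3D logical array with
#'   slices along the third dimension.
#' @param pixel_spacing Numeric length-2, (row mm, column mm); both > 0.
#' @param slice_thickness Slice thickness in mm (> 0). Default 5.
#' @param specimen_id Identifier carried through to the volume report.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(slices, pixel_spacing = c(1, 1), slice_thickness = 5,
                       specimen_id = "specimen") {
  if (is.array(slices) && length(dim(slices)) == 3L) {
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  }
  if (!is.list(slices) || length(slices) < 1L) {
    abort_pelvi("A mask stack needs at least one slice.", "schema_error")
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_pelvi("All slices in a mask stack must have identical dimensions.",
                "schema_error")
  }
  slices <- lapply(slices, .as_binary_mask)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    abort_pelvi("pixel_spacing must be two positive numbers (mm).", "schema_error")
  }
  if (!is.finite(slice_thickness) || slice_thickness <= 0) {
    abort_pelvi("slice_thickness must be a positive number (mm).", "schema_error")
  }
  structure(
    list(slices = slices, pixel_spacing = pixel_spacing,
         slice_thickness = as.numeric(slice_thickness),
         specimen_id = as.character(specimen_id)),
    class = "mask_stack"
  )
}

.as_binary_mask <- function(m) {
  if (is.logical(m)) return(m)
  if (is.numeric(m) && all(m %in% c(0, 1))) return(m == 1)
  abort_pelvi("Mask slices must be logical or 0/1 valued.", "invalid_mask_error")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf(
    "<mask_stack '%s': %d slices of %d x %d px, spacing %.3g x %.3g mm, thickness %.3g mm>\n",
    x$specimen_id, length(x$slices), d[1], d[2],
    x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness
  ))
  invisible(x)
}

#' Segmented area of one slice
#'
#' Area of the positive (intestine) pixels of a binary mask: pixel count
#' times the pixel footprint.
#'
#' @param mask A logical or 0/1 matrix.
#' @param pixel_spacing Numeric length-2, (row mm, column mm).
#' @return Area in mm^2.
#' @export
slice_area <- function(mask, pixel_spacing = c(1, 1)) {
  mask <- .as_binary_mask(mask)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0)) {
    abort_pelvi("pixel_spacing must be positive (mm).", "schema_error")
  }
  sum(mask) * pixel_spacing[1] * pixel_spacing[2]
}

#' Gut volume by slice summation
#'
#' CT volumetry: the segmented area of each slice is multiplied by the
#' slice thickness (slab model: the mask is taken constant through the full
#' thickness, with no inter-slice interpolation) and the per-slice volumes
#' are summed. The result is reported in cubic centimetres.
#'
#' @param stack A [mask_stack()].
#' @return A tibble with columns `specimen_id`, `volume_cc`,
#'   `n_slices_nonempty`.
#' @export
#' @examples
#' s <- mask_stack(list(matrix(TRUE, 10, 10)), pixel_spacing = c(1, 1),
#'                 slice_thickness = 5)
#' gut_volume(s) # 0.5 cc
gut_volume <- function(stack) {
  if (!inherits(stack, "mask_stack")) stack <- do.call(mask_stack, stack)
  areas <- vapply(stack$slices, slice_area, numeric(1),
                  pixel_spacing = stack$pixel_spacing)
  tibble(
    specimen_id = stack$specimen_id,
    volume_cc = sum(areas) * stack$slice_thickness / 1000,
    n_slices_nonempty = sum(areas > 0)
  )
}

#' Analytic phantom mask stacks
#'
#' Rasterises an analytic solid (cylinder with axis along the slice
#' direction, sphere, or axis-aligned ellipsoid) onto a slice grid for
#' volumetry validation. A pixel is counted as inside the solid iff its
#' centre is inside; slices sample the solid at their centre plane
#' (matching the slab summation model), so the estimate converges to the
#' analytic volume first-order as the grid is refined.
#'
#' @param shape `"cylinder"`, `"sphere"` or `"ellipsoid"`.
#' @param params Named list: cylinder needs `radius`, `height`; sphere
#'   needs `radius`; ellipsoid needs semi-axes `a`, `b`, `c` (mm; `c` along
#'   the slice axis). Solids are centred in the grid.
#' @param pixel_spacing Numeric length-2, (row mm, column mm).
#' @param slice_thickness Slice thickness in mm.
#' @param margin_mm Extra grid padding around the solid on every side.
#' @param specimen_id Identifier for the stack.
#' @return A [mask_stack()].
#' @export
make_phantom <- function(shape = c("cylinder", "sphere", "ellipsoid"),
                         params, pixel_spacing = c(1, 1), slice_thickness = 5,
                         margin_mm = 2, specimen_id = paste0(shape[1], "_phantom")) {
  shape <- match.arg(shape)
  semi <- switch(shape,
    cylinder  = c(params$radius, params$radius, params$height / 2),
    sphere    = c(params$radius, params$radius, params$radius),
    ellipsoid = c(params$a, params$b, params$c)
  )
  if (any(!is.finite(semi)) || any(semi <= 0)) {
    abort_pelvi("Phantom dimensions must be positive.", "bounds_error")
  }

  half_x <- semi[1] + margin_mm
  half_y <- semi[2] + margin_mm
  n_row <- ceiling(2 * half_x / pixel_spacing[1])
  n_col <- ceiling(2 * half_y / pixel_spacing[2])
  # slabs tile the solid's z-extent symmetrically about its centre, so a
  # solid spanning m slabs is sampled at m mid-slab planes (and a solid
  # thinner than one slab sits at a slab centre)
  n_slice <- max(1L, ceiling(2 * semi[3] / slice_thickness))
  # pixel centres (solid centred at the origin); slice centres mid-slab
  xs <- (seq_len(n_row) - (n_row + 1) / 2) * pixel_spacing[1]
  ys <- (seq_len(n_col) - (n_col + 1) / 2) * pixel_spacing[2]
  zs <- (seq_len(n_slice) - (n_slice + 1) / 2) * slice_thickness
  if (max(abs(xs)) + 0 < semi[1] || max(abs(ys)) < semi[2]) {
    abort_pelvi("Phantom solid exceeds the raster grid.", "bounds_error")
  }

  r2 <- outer(xs^2 / semi[1]^2, ys^2 / semi[2]^2, `+`)
  slices <- lapply(zs, function(z) {
    if (shape == "cylinder") {
      if (abs(z) > semi[3]) matrix(FALSE, n_row, n_col) else r2 <= 1
    } else {
      r2 <= 1 - z^2 / semi[3]^2
    }
  })
  mask_stack(slices, pixel_spacing = pixel_spacing,
             slice_thickness = slice_thickness, specimen_id = specimen_id)
}

#' Read a binary mask stack from NIfTI
#'
#' Pixel spacing and slice thickness are taken from the NIfTI header
#' (`pixdim`); voxel values must be 0/1.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param specimen_id Identifier; defaults to the file stem.
#' @return A [mask_stack()].
#' @export
read_mask_nifti <- function(path, specimen_id = NULL) {
  rlang::check_installed("RNifti")
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    abort_pelvi("Expected a 3D NIfTI volume.", "schema_error")
  }
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  mask_stack(arr != 0, pixel_spacing = pd[1:2], slice_thickness = pd[3],
             specimen_id = specimen_id)
}

#' Write a mask stack to NIfTI
#'
#' @param stack A [mask_stack()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(stack, path) {
  rlang::check_installed("RNifti")
  arr <- simplify2array(lapply(stack$slices, function(m) m * 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(stack$pixel_spacing, stack$slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask stack from multi-page TIFF plus JSON sidecar
#'
#' The TIFF holds one binary page per slice; the sidecar (same path with
#' `.json` appended, or given explicitly) supplies
#' `{"pixel_spacing_mm": [r, c], "slice_thickness_mm": t}`.
#'
#' @param path Path to a multi-page `.tif`/`.tiff` file.
#' @param sidecar Optional explicit path to the JSON metadata.
#' @param specimen_id Identifier; defaults to the file stem.
#' @return A [mask_stack()].
#' @export
read_mask_tiff <- function(path, sidecar = NULL, specimen_id = NULL) {
  rlang::check_installed("tiff")
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort_pelvi(sprintf("TIFF sidecar '%s' not found.", sidecar), "schema_error")
  }
  meta <- jsonlite::fromJSON(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.tiff?$", "", basename(path))
  }
  mask_stack(lapply(pages, function(p) p > 0.5),
             pixel_spacing = meta$pixel_spacing_mm,
             slice_thickness = meta$slice_thickness_mm,
             specimen_id = specimen_id)
}

#' Write a mask stack to multi-page TIFF plus JSON sidecar
#'
#' @param stack A [mask_stack()].
#' @param path Output `.tif` path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(stack, path) {
  rlang::check_installed("tiff")
  tiff::writeTIFF(lapply(stack$slices, function(m) m * 1), path)
  jsonlite::write_json(
    list(pixel_spacing_mm = stack$pixel_spacing,
         slice_thickness_mm = stack$slice_thickness),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
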