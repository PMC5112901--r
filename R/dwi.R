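#' Diffusion-weighted dataset
#'
#' Bundles the 4-D signal array with its gradient scheme, grid and masks.
#'
#' @param signals 4-D numeric array (x, y, z, volume); finite, >= 0.
#' @param scheme \code{lcfp_scheme} whose length matches dim 4.
#' @param grid \code{lcfp_grid} matching the spatial dimensions.
#' @param brain_mask logical 3-D array; default all TRUE.
#' @param ventricle_mask logical 3-D array marking a free-water reference
#'   region (used to estimate the SDF normalization constant); optional.
#' @return object of class \code{lcfp_dwi}.
#' @export
dwi_dataset <- function(signals, scheme, grid,
                        brain_mask = NULL, ventricle_mask = NULL) {
  stopifnot(inherits(scheme, "lcfp_scheme"), inherits(grid, "lcfp_grid"))
  d <- dim(signals)
  if (length(d) != 4L) stop("signals must be 4-D (x, y, z, volume)")
  if (!identical(as.integer(d[1:3]), grid$dim))
    stop("signal dimensions do not match grid")
  if (d[4] != length(scheme$b_values))
    stop("4th dimension must equal scheme length")
  if (any(!is.finite(signals)) || any(signals < 0))
    stop("signals must be finite and non-negative")
  chk_mask <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!identical(as.integer(dim(m)), grid$dim))
      stop(what, " must match the signal's spatial dimensions")
    array(as.logical(m), dim = grid$dim)
  }
  if (is.null(brain_mask)) brain_mask <- array(TRUE, grid$dim)
  structure(list(signals = signals, scheme = scheme, grid = grid,
                 brain_mask = chk_mask(brain_mask, "brain_mask"),
                 ventricle_mask = chk_mask(ventricle_mask, "ventricle_mask")),
            class = "lcfp_dwi")
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_from_grid <- function(arr, grid) {
  im <- RNifti::asNifti(arr)
  RNifti::qform(im) <- grid_affine_ras(grid)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(grid$spacing, rep(1, nd - 3L))
  im
}

# Read a NIfTI volume, reorient to LPS, return list(data, grid).
read_nifti_lps <- function(path) {
  im <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(im), "LPS"))
    RNifti::orientation(im) <- "LPS"
  aff <- RNifti::xform(im)
  rot <- aff[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  if (any(abs(abs(rot) - diag(sp)) > 1e-3 * max(sp)))
    stop("oblique affines are not supported; resample to an axis-aligned grid")
  # affine is RAS; LPS origin flips x and y
  origin <- c(-aff[1, 4], -aff[2, 4], aff[3, 4])
  d <- dim(im)
  grid <- make_grid(d[1:3], sp, origin)
  list(data = as.array(im), grid = grid)
}

#' Read a diffusion dataset from NIfTI + b-table
#'
#' @param dwi_path 4-D NIfTI file (.nii or .nii.gz).
#' @param btable_path plain-text b-table ("b gx gy gz" per row).
#' @param brain_mask_path,ventricle_mask_path optional 3-D NIfTI masks
#'   (nonzero = included).
#' @return \code{lcfp_dwi}.
#' @export
read_dwi <- function(dwi_path, btable_path,
                     brain_mask_path = NULL, ventricle_mask_path = NULL) {
  v <- read_nifti_lps(dwi_path)
  scheme <- read_btable(btable_path)
  rd_mask <- function(p) if (is.null(p)) NULL else read_nifti_lps(p)$data != 0
  dwi_dataset(v$data, scheme, v$grid,
              brain_mask = rd_mask(brain_mask_path),
              ventricle_mask = rd_mask(ventricle_mask_path))
}

#' Write a volume on an \code{lcfp_grid} as NIfTI
#'
#' @param arr 3-D or 4-D array.
#' @param grid \code{lcfp_grid}.
#' @param path output path (.nii or .nii.gz).
#' @export
write_nifti_lps <- function(arr, grid, path) {
  RNifti::writeNifti(nifti_from_grid(arr, grid), path)
  invisible(path)
}
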