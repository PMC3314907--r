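# NIfTI / bval / bvec input-output. FSL conventions: bval is one row of
# b-values, bvec three rows (x, y, z) in the image coordinate frame; on
# reading, directions are rotated to world coordinates by the rotational
# part of the NIfTI affine, because the perturbation field lives in the
# scanner frame.

#' Read FSL-style bval/bvec files
#'
#' Transposed bvec layouts (N x 3) are auto-detected when unambiguous.
#'
#' @param bval_path path to the b-value file (one row).
#' @param bvec_path path to the gradient-direction file (3 x N).
#' @return list with `bvals` (numeric) and `bvecs` (3 x N matrix).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3) stop("bvec file must be 3 x N or N x 3")
  list(bvals = bvals, bvecs = bvecs)
}

#' Write FSL-style bval/bvec files
#'
#' @param scheme a [gradient_scheme].
#' @param bval_path,bvec_path output paths.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  utils::write.table(scheme$bvecs, bvec_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

# attach an affine to an array and write as NIfTI
write_nifti_with_affine <- function(data, affine, path, voxel_mm = NULL) {
  img <- RNifti::asNifti(data)
  if (is.null(voxel_mm)) voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- if (length(dim(data)) == 4) c(voxel_mm, 1) else voxel_mm
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a DWI dataset bundle
#'
#' Reads the NIfTI volumes together with the bval/bvec scheme, validates
#' that volume counts match (errors name the mismatch), unit-normalizes
#' directions (tolerance 1e-3, errors name the volume index) and rotates
#' them from the image frame to world coordinates.
#'
#' @param dwi_path 4-D NIfTI path.
#' @param bval_path,bvec_path FSL scheme files.
#' @param mask_path optional 3-D NIfTI mask (> 0 is inside).
#' @param rotate_bvecs rotate directions by the affine's rotational part
#'   (default `TRUE`).
#' @return list: `dwi` (4-D array), `scheme` (a [gradient_scheme]),
#'   `affine`, `mask` (or `NULL`).
#' @export
read_dwi_bundle <- function(dwi_path, bval_path, bvec_path,
                            mask_path = NULL, rotate_bvecs = TRUE) {
  if (!file.exists(dwi_path)) stop(sprintf("file not found: %s", dwi_path))
  img <- RNifti::readNifti(dwi_path)
  dwi <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dwi)) != 4) stop("DWI NIfTI must be 4-D")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  sch <- read_bvals_bvecs(bval_path, bvec_path)
  n <- dim(dwi)[4]
  if (length(sch$bvals) != n || ncol(sch$bvecs) != n) {
    stop(sprintf("volume count mismatch: NIfTI has %d volumes, bval lists %d, bvec lists %d",
                 n, length(sch$bvals), ncol(sch$bvecs)))
  }
  bvecs <- sch$bvecs
  if (rotate_bvecs) {
    R <- affine[1:3, 1:3]
    R <- sweep(R, 2, sqrt(colSums(R^2)), "/")
    bvecs <- R %*% bvecs
  }
  scheme <- gradient_scheme(sch$bvals, bvecs)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m) > 0, dim = dim(m)[1:3])
  }
  list(dwi = dwi, scheme = scheme, affine = affine, mask = mask)
}

#' Write a simulated DWI bundle to disk
#'
#' @param phantom output of [synthesize_phantom].
#' @param prefix path prefix; writes `<prefix>dwi.nii.gz`, `<prefix>bval`,
#'   `<prefix>bvec`, `<prefix>mask.nii.gz`.
#' @return character vector of the written paths.
#' @export
write_dwi_bundle <- function(phantom, prefix) {
  paths <- c(dwi = paste0(prefix, "dwi.nii.gz"),
             bval = paste0(prefix, "bval"),
             bvec = paste0(prefix, "bvec"),
             mask = paste0(prefix, "mask.nii.gz"))
  write_nifti_with_affine(phantom$dwi, phantom$affine, paths["dwi"])
  write_bvals_bvecs(phantom$scheme, paths["bval"], paths["bvec"])
  write_nifti_with_affine(phantom$mask + 0, phantom$affine, paths["mask"])
  paths
}

#' Write a tensor field as a 6-volume NIfTI
#'
#' Volumes are the lower-triangular components in the order Dxx, Dxy, Dyy,
#' Dxz, Dyz, Dzz (recorded in the header description field).
#'
#' @param field a [tensor_field].
#' @param path output NIfTI path.
#' @export
write_tensor_field <- function(field, path) {
  img <- RNifti::asNifti(field$data)
  voxel_mm <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(voxel_mm, 1)
  RNifti::sform(img) <- structure(field$affine, code = 2L)
  RNifti::qform(img) <- structure(field$affine, code = 2L)
  img <- RNifti::asNifti(img, reference = list(
    descrip = "tensor lower-tri: Dxx Dxy Dyy Dxz Dyz Dzz"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tensor field written by [write_tensor_field]
#'
#' @param path 6-volume NIfTI path.
#' @param mask optional logical 3-D array.
#' @return a [tensor_field].
#' @export
read_tensor_field <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4 || dim(data)[4] != 6) {
    stop("tensor NIfTI must have 6 volumes (lower-triangular components)")
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  tensor_field(data, affine, mask)
}

#' Write scalar maps and a JSON run report
#'
#' @param maps named list of 3-D arrays (e.g. `fa`, `md`, `trace`).
#' @param affine 4x4 affine shared by the maps.
#' @param prefix output path prefix (`<prefix><name>.nii.gz`).
#' @param report optional list serialized to `<prefix>report.json`.
#' @return character vector of written paths.
#' @export
write_maps <- function(maps, affine, prefix, report = NULL) {
  paths <- character(0)
  for (nm in names(maps)) {
    p <- paste0(prefix, nm, ".nii.gz")
    m <- maps[[nm]]
    m[is.na(m)] <- 0
    write_nifti_with_affine(m, affine, p)
    paths <- c(paths, p)
  }
  if (!is.null(report)) {
    p <- paste0(prefix, "report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  paths
}
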