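# NIfTI entry points for real acquisitions: a series is stored as one 3-D
# volume (5 slices = 5 effective TEs or 5 interleaves) plus a matching mask
# volume. Pixel geometry is carried in the NIfTI header (pixdim, mm).

read_mask_2d <- function(msk) {
  m <- array(as.numeric(msk), dim = dim(msk))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write / read a T2-prepared series as NIfTI
#'
#' @param series A `t2prep_series`.
#' @param image_path,mask_path Output NIfTI paths (`.nii` or `.nii.gz`).
#' @return Paths, invisibly.
#' @export
write_t2prep_nifti <- function(series, image_path, mask_path) {
  pix_mm <- sqrt(series$pixel_area) * 10 # cm^2/pixel -> mm edge
  img <- RNifti::asNifti(series$images)
  RNifti::pixdim(img) <- c(pix_mm, pix_mm, 1)
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.numeric(series$roi_mask),
                               dim = dim(series$roi_mask)))
  RNifti::pixdim(msk) <- c(pix_mm, pix_mm)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname write_t2prep_nifti
#' @param effective_tes Effective echo times of the five slices, ms
#'   (required on read; TE values are not stored in NIfTI headers).
#' @param acquisition_id Identifier for the series.
#' @export
read_t2prep_nifti <- function(image_path, mask_path, effective_tes,
                              acquisition_id = basename(image_path)) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  pixdim <- RNifti::pixdim(img)
  pixel_area <- prod(pixdim[1:2]) / 100 # mm^2 -> cm^2
  imgs <- array(as.numeric(img), dim = dim(img))
  if (length(dim(imgs)) != 3L || dim(imgs)[3] != length(effective_tes)) {
    abort("Image volume must be rows x cols x n_TE.")
  }
  structure(
    list(
      images = imgs, effective_tes = as.numeric(effective_tes),
      roi_mask = read_mask_2d(msk),
      pixel_area = pixel_area, acquisition_id = acquisition_id,
      t2_blood = NA_real_
    ),
    class = "t2prep_series"
  )
}

#' Write / read a velocity-map series as NIfTI
#'
#' @param series A `velocity_series`.
#' @param image_path,mask_path Output NIfTI paths.
#' @return Paths, invisibly.
#' @export
write_velocity_nifti <- function(series, image_path, mask_path) {
  pix_mm <- sqrt(series$pixel_area) * 10
  img <- RNifti::asNifti(series$velocity_maps)
  RNifti::pixdim(img) <- c(pix_mm, pix_mm, 1)
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.numeric(series$roi_mask),
                               dim = dim(series$roi_mask)))
  RNifti::pixdim(msk) <- c(pix_mm, pix_mm)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname write_velocity_nifti
#' @param venc Velocity-encoding limit of the acquisition, cm/s.
#' @param acquisition_id Identifier for the series.
#' @export
read_velocity_nifti <- function(image_path, mask_path, venc = Inf,
                                acquisition_id = basename(image_path)) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  pixdim <- RNifti::pixdim(img)
  pixel_area <- prod(pixdim[1:2]) / 100
  maps <- array(as.numeric(img), dim = dim(img))
  if (length(dim(maps)) != 3L) abort("Velocity volume must be 3-D.")
  structure(
    list(
      velocity_maps = maps, pixel_area = pixel_area,
      roi_mask = read_mask_2d(msk),
      venc = venc, acquisition_id = acquisition_id
    ),
    class = "velocity_series"
  )
}
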