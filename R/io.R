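#' Write a volume to NIfTI-1 with grid metadata
#'
#' The affine is diagonal with the grid spacing and translates by the
#' world position of the first voxel centre, so round-tripping through
#' [read_volume()] recovers the [grid_spec()] exactly.
#'
#' @param vol numeric, integer or logical 3-D array.
#' @param grid the [grid_spec()] the array lives on.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar optional named list written as a JSON sidecar next to
#'   the image (echo times, dose, delay, half-life, seed, ...).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, grid, path, sidecar = NULL) {
  storage <- if (is.logical(vol) || is.integer(vol)) "int16" else "double"
  affine <- diag(4)
  diag(affine)[1:3] <- grid$spacing
  affine[1:3, 4] <- grid$origin + grid$spacing / 2
  img <- RNifti::asNifti(array(if (storage == "int16") as.integer(vol)
                               else as.numeric(vol), grid$shape),
                         datatype = storage)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path NIfTI file path.
#' @return list with `vol` (array), `grid` ([grid_spec()]), and `sidecar`
#'   (parsed JSON sidecar, or `NULL` if absent).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4] - spacing / 2
  grid <- grid_spec(dim(img), spacing, origin)
  sc <- sidecar_path(path)
  sidecar <- if (file.exists(sc)) jsonlite::read_json(sc) else NULL
  list(vol = array(as.numeric(img), dim(img)), grid = grid,
       sidecar = sidecar)
}

#' Write a ROI set as one multi-label NIfTI plus a JSON label dictionary
#'
#' Masks are encoded as bit flags (lung = 1, vessels = 2, lesion_short =
#' 4, lesion_long = 8, edema = 16, tissue = 32) so overlapping ROIs are
#' preserved; the sidecar records the flag dictionary.
#'
#' @param rois a [roi_set()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  nms <- c("lung", "vessels", "lesion_short", "lesion_long", "edema",
           "tissue")
  flags <- stats::setNames(2^(seq_along(nms) - 1), nms)
  lab <- array(0L, rois$grid$shape)
  for (nm in nms) lab <- lab + as.integer(flags[[nm]]) * rois[[nm]]
  write_volume(lab, rois$grid, path, sidecar = as.list(flags))
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  v <- read_volume(path)
  flags <- v$sidecar
  masks <- lapply(flags, function(f)
    array(bitwAnd(as.integer(v$vol), as.integer(f)) > 0L, v$grid$shape))
  do.call(roi_set, c(list(grid = v$grid), masks))
}

#' Read a CT table from CSV
#'
#' @param path CSV with columns `sample`, `group`, `day`, `gene`, `ct`
#'   (optionally `is_reference`).
#' @return validated tibble.
#' @export
read_ct_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_ct_table(tab)
  tab
}
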