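#' 3-D connected components (6-connectivity)
#'
#' @param mask 3-D logical array.
#' @return integer array of component labels, 0 for background; label 1 is
#'   the largest component, labels ordered by decreasing size.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  .cc_label_3d(as.logical(mask), as.integer(dim(mask)))
}

#' Keep the n largest connected components of a mask
#' @param mask 3-D logical array.
#' @param n how many components to keep.
#' @param min_size drop components smaller than this many voxels instead
#'   (alternative to `n`; applied after `n` if both given).
#' @return logical array.
#' @export
largest_components <- function(mask, n = 1L, min_size = 0L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  keep <- seq_len(min(n, max(lab)))
  if (min_size > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- keep[sizes[keep] >= min_size]
  }
  array(lab %in% keep, dim(mask))
}

#' Remove connected components below a voxel-count threshold
#' @param mask 3-D logical array.
#' @param min_size minimum component size in voxels; components strictly
#'   smaller are removed.
#' @return logical array.
#' @export
remove_small_components <- function(mask, min_size) {
  if (min_size <= 1L) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  array(lab > 0L & sizes[pmax(lab, 1L)] >= min_size, dim(mask))
}

#' Fill interior holes of a 3-D mask
#'
#' A hole is a background component (6-connectivity) that does not touch
#' the array boundary.
#' @param mask 3-D logical array.
#' @return logical array with holes set TRUE.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  mask | array(lab > 0L & !(lab %in% border_labels), d)
}

#' Euclidean distance (mm) to the nearest TRUE voxel
#'
#' Exact anisotropic Euclidean distance transform; distances are measured
#' between voxel centres.
#' @param mask 3-D logical array; must contain at least one TRUE voxel.
#' @param grid [grid_spec()] providing the spacing.
#' @return numeric array of distances in mm (0 on the mask itself).
#' @export
distance_transform <- function(mask, grid) {
  stopifnot(all(dim(mask) == grid$shape))
  if (!any(mask)) stop("distance_transform: mask is empty")
  .edt_3d(as.logical(mask), as.integer(dim(mask)), as.numeric(grid$spacing))
}

# TRUE where `a` has a 6-neighbour inside `b` (both logical 3-D arrays).
adjacent_to <- function(a, b) {
  d <- dim(b)
  nb <- array(FALSE, d)
  shift_or <- function(acc, src, axis, by) {
    idx_to <- lapply(d, seq_len)
    idx_from <- idx_to
    if (by == 1L) {
      idx_to[[axis]] <- seq_len(d[axis] - 1L)
      idx_from[[axis]] <- 2L:d[axis]
    } else {
      idx_to[[axis]] <- 2L:d[axis]
      idx_from[[axis]] <- seq_len(d[axis] - 1L)
    }
    acc_part <- do.call(`[`, c(list(acc), idx_to))
    src_part <- do.call(`[`, c(list(src), idx_from))
    acc <- do.call(`[<-`, c(list(acc), idx_to, list(acc_part | src_part)))
    acc
  }
  for (axis in 1:3) for (by in c(1L, -1L)) nb <- shift_or(nb, b, axis, by)
  a & nb
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @return 2|A intersect B| / (|A| + |B|); 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
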