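#' Tissue label codes used throughout the package
#'
#' Label maps are integer 3D arrays with one label per voxel: 0 background,
#' 1 CSF (ventricles), 2 grey matter, 3 white matter (NAWM, since lesional
#' voxels carry their own label), 4 T2 lesion.
#'
#' @return named integer vector of label codes.
#' @export
tissue_labels <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L, lesion = 4L)
}

#' Physical voxel-centre coordinates
#'
#' Coordinates in mm for each axis, centred so that the left-right midline
#' (axis 1) lies at x = 0 between the two central voxel columns when the
#' extent is even. With extent n and spacing d, voxel i sits at
#' (i - (n + 1) / 2) * d.
#'
#' @param shape integer length-3 grid extent.
#' @param pixdim numeric length-3 voxel spacing in mm.
#' @return list of three numeric vectors (mm).
#' @keywords internal
axis_coords_mm <- function(shape, pixdim) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * pixdim[a])
}

#' Reflect a mask or volume across the brain midline
#'
#' The midline is the inter-columnar plane of the (even) left-right axis, so
#' reflection is an exact voxel permutation (index i maps to n + 1 - i along
#' axis 1) and an involution: reflecting twice restores the input bit-exactly.
#'
#' @param vol 3D array (any mode).
#' @param axis left-right axis index (default 1).
#' @return array of the same shape and mode.
#' @export
reflect_across_midline <- function(vol, axis = 1L) {
  d <- dim(vol)
  if (length(d) != 3L) stop("reflect_across_midline: expected a 3D array")
  if (d[axis] %% 2L != 0L)
    stop("reflect_across_midline: left-right extent must be even (got ",
         d[axis], "); midline must fall between two voxel columns")
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(d[axis]))
  out <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
  attributes(out) <- attributes(vol)
  out
}

#' Integer voxel offsets within a physical radius
#'
#' All integer offsets o with ||o * pixdim||_2 strictly below `dist_mm`,
#' including the zero offset. Used to build exclusion zones: a voxel is
#' within `dist_mm` of a mask iff shifting the mask by one of these offsets
#' covers it.
#'
#' @param pixdim voxel spacing (mm).
#' @param dist_mm strict distance bound (mm).
#' @return integer matrix, one offset per row.
#' @keywords internal
offsets_within_mm <- function(pixdim, dist_mm) {
  r <- pmax(ceiling(dist_mm / pixdim) - 1L, 0L)
  g <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  d2 <- (g[, 1] * pixdim[1])^2 + (g[, 2] * pixdim[2])^2 + (g[, 3] * pixdim[3])^2
  g[d2 < dist_mm^2, , drop = FALSE]
}

# Shift a logical array by an integer offset, zero-filling the exposed edge.
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- seq_len(d[a] - o) + o }
    else        { src[[a]] <- seq_len(d[a] + o) - o; dst[[a]] <- seq_len(d[a] + o) }
    if (length(src[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dilate a binary mask by a set of voxel offsets
#'
#' @param mask logical 3D array.
#' @param offsets integer matrix of offsets (rows), e.g. from
#'   [offsets_within_mm()] or a 26-neighbourhood.
#' @return logical array: union of the shifted masks.
#' @keywords internal
dilate_mask <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets))) out <- out | shift_mask(mask, offsets[i, ])
  out
}

# 26-connectivity neighbourhood (excluding the centre).
neigh26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Label 26-connected components of a binary mask
#'
#' Breadth-first flood fill over the 26-neighbourhood. Component ids are
#' assigned in increasing order of the first (column-major) voxel index, so
#' labelling is deterministic.
#'
#' @param mask logical 3D array.
#' @return integer array, 0 outside the mask, component id inside.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  vox <- which(mask)
  if (length(vox) == 0) return(lab)
  coords <- arrayInd(vox, d)
  inmask <- array(FALSE, d); inmask[vox] <- TRUE
  nb <- neigh26()
  nextlab <- 0L
  for (v in vox) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    lab[v] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(nb))) {
        p <- ci + nb[k, ]
        if (any(p < 1L) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1L) + d[1] * d[2] * (p[3] - 1L)
        if (inmask[li] && lab[li] == 0L) {
          lab[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' Minimum physical distance from query voxels to a mask
#'
#' Exact Euclidean distance (mm, anisotropic spacing respected) from each
#' query voxel centre to the nearest voxel centre of `target`, by direct
#' enumeration. Intended for small query sets (ROI candidates); use
#' [offsets_within_mm()] dilation for whole-volume exclusion zones.
#'
#' @param query logical array or n x 3 integer matrix of voxel indices.
#' @param target logical 3D array.
#' @param pixdim voxel spacing (mm).
#' @return numeric vector of distances (Inf if `target` is empty).
#' @export
distance_to_mask <- function(query, target, pixdim) {
  qi <- if (is.matrix(query)) query else arrayInd(which(query), dim(query))
  ti <- arrayInd(which(target), dim(target))
  if (nrow(qi) == 0) return(numeric(0))
  if (nrow(ti) == 0) return(rep(Inf, nrow(qi)))
  q <- sweep(qi, 2, pixdim, `*`)
  t <- sweep(ti, 2, pixdim, `*`)
  out <- rep(Inf, nrow(q))
  for (k in seq_len(nrow(t))) {
    d2 <- (q[, 1] - t[k, 1])^2 + (q[, 2] - t[k, 2])^2 + (q[, 3] - t[k, 3])^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

#' Voxels strictly within a physical distance of a mask
#'
#' The exclusion zone of the ROI criteria: voxels whose centre lies at
#' Euclidean distance < `dist_mm` from any voxel of `mask` ("at least 2 mm
#' away" is read inclusively, so a voxel at exactly `dist_mm` survives).
#'
#' @param mask logical 3D array.
#' @param pixdim voxel spacing (mm).
#' @param dist_mm strict exclusion radius (mm, default 2).
#' @return logical array.
#' @export
exclusion_zone <- function(mask, pixdim, dist_mm = 2) {
  if (!any(mask)) return(array(FALSE, dim(mask)))
  dilate_mask(mask, offsets_within_mm(pixdim, dist_mm))
}
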