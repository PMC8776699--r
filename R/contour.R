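# Offsets (voxel steps) within a Euclidean ball of radius_mm for a given
# anisotropic spacing; always includes the origin.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= radius_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

# shift a 3D logical array by integer voxel offsets, padding with `pad`
shift_mask <- function(m, off, pad = FALSE) {
  d <- dim(m)
  out <- array(pad, d)
  src <- dst <- vector("list", 3)
  for (j in 1:3) {
    o <- off[j]
    if (abs(o) >= d[j]) return(out)
    if (o >= 0) {
      dst[[j]] <- (1 + o):d[j]; src[[j]] <- 1:(d[j] - o)
    } else {
      dst[[j]] <- 1:(d[j] + o); src[[j]] <- (1 - o):d[j]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate <- function(m, radius_mm, spacing) {
  if (radius_mm <= 0) return(m)
  offs <- ball_offsets(radius_mm, spacing)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mask(m, as.numeric(offs[i, ]), pad = FALSE)
  }
  out
}

binary_erode <- function(m, radius_mm, spacing) {
  if (radius_mm <= 0) return(m)
  offs <- ball_offsets(radius_mm, spacing)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_mask(m, as.numeric(offs[i, ]), pad = FALSE)
  }
  out
}

binary_close <- function(m, radius_mm, spacing) {
  if (radius_mm <= 0) return(m)
  binary_erode(binary_dilate(m, radius_mm, spacing), radius_mm, spacing)
}

#' Select the vertebral levels forming the registration landmark
#'
#' Implements the in-house landmark protocol: a lesion confined to one or two
#' vertebrae is extended by one vertebral body (and its hardware) above and
#' below, giving 3-4 landmark vertebrae; a lesion spanning three or more
#' vertebrae is used as-is. Extension is clipped at the ends of the imaged
#' stack.
#'
#' @param lesion_levels 1-based, contiguous indices of lesioned vertebrae.
#' @param n_levels Number of vertebral levels in the volume.
#' @return Sorted integer vector of landmark level indices.
#' @export
select_landmark_levels <- function(lesion_levels, n_levels) {
  lv <- sort(unique(as.integer(lesion_levels)))
  if (length(lv) == 0L)
    stop("lesion annotation is empty", call. = FALSE)
  if (any(lv < 1L) || any(lv > n_levels))
    stop("lesion levels outside 1..n_levels", call. = FALSE)
  if (length(lv) > 1L && any(diff(lv) != 1L))
    stop("lesion levels must be contiguous", call. = FALSE)
  if (length(lv) <= 2L) {
    lv <- c(min(lv) - 1L, lv, max(lv) + 1L)
    lv <- lv[lv >= 1L & lv <= n_levels]
  }
  lv
}

#' Extract the bone + hardware landmark mask
#'
#' Thresholds the planning CT at `hu_threshold` (capturing cortical bone and
#' metal hardware, whose HU exceeds bone) within the craniocaudal range of
#' the selected levels, then applies morphological closing and dilation so
#' thin cortical shells survive noise and a margin of adjacent tissue enters
#' the similarity computation.
#'
#' @param ct Primary `image_volume` (plain planning CT).
#' @param levels Landmark level indices (from [select_landmark_levels()]).
#' @param level_boundaries n_levels x 2 matrix of per-level CC ranges in mm.
#' @param hu_threshold Threshold in HU; must exceed soft-tissue HU. The
#'   default 650 also exceeds contrast-enhanced CSF so myelographic contrast
#'   can never enter the landmark mask.
#' @param dilation_mm Dilation margin, mm.
#' @param closing_mm Morphological closing radius, mm.
#' @return An object of class `contour_mask`: logical `mask` on the primary
#'   grid, the covered CC `level_range` (mm), `voxel_count`, and the grid
#'   geometry (`spacing`, `origin`).
#' @export
extract_landmark_mask <- function(ct, levels, level_boundaries,
                                  hu_threshold = 650, dilation_mm = 2,
                                  closing_mm = 1) {
  stopifnot(inherits(ct, "image_volume"))
  levels <- sort(as.integer(levels))
  if (any(levels < 1L) || any(levels > nrow(level_boundaries)))
    stop("levels outside the annotated boundaries", call. = FALSE)
  z0 <- min(level_boundaries[levels, 1])
  z1 <- max(level_boundaries[levels, 2])
  d <- dim(ct$voxels)
  zc <- ct$origin[3] + (seq_len(d[3]) - 1) * ct$spacing[3]
  in_range <- zc >= z0 & zc <= z1
  m <- ct$voxels >= hu_threshold
  m[, , !in_range] <- FALSE
  if (!any(m))
    stop("landmark extraction failed: no voxels above ", hu_threshold,
         " HU in the selected levels", call. = FALSE)
  m <- binary_close(m, closing_mm, ct$spacing)
  m <- binary_dilate(m, dilation_mm, ct$spacing)
  structure(list(mask = m,
                 level_range = c(z0 - dilation_mm, z1 + dilation_mm),
                 voxel_count = sum(m),
                 spacing = ct$spacing, origin = ct$origin,
                 levels = levels),
            class = "contour_mask")
}

#' @export
print.contour_mask <- function(x, ...) {
  cat(sprintf("Landmark contour: %d voxels over levels %s (CC %.1f-%.1f mm)\n",
              x$voxel_count, paste(x$levels, collapse = ","),
              x$level_range[1], x$level_range[2]))
  invisible(x)
}

#' Centroid of a contour mask
#'
#' World coordinates (mm, LPS) of the mask's center of mass — the canonical
#' rotation center for reporting transforms and errors, since the contour is
#' the registration target and its centroid minimizes translation/rotation
#' coupling.
#' @param cm A `contour_mask`.
#' @return Length-3 numeric (mm).
#' @export
mask_centroid <- function(cm) {
  idx <- which(cm$mask, arr.ind = TRUE)
  cm$origin + (colMeans(idx) - 1) * cm$spacing
}

#' Read a lesion annotation JSON
#'
#' The annotation carries `lesion_levels` (1-based) and
#' `level_boundaries_mm`, one `[z0, z1]` pair per vertebral level.
#'
#' @param path JSON file path.
#' @return A list with `lesion_levels` and `level_boundaries` (matrix).
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$lesion_levels) || is.null(obj$level_boundaries_mm))
    stop("annotation must contain lesion_levels and level_boundaries_mm",
         call. = FALSE)
  lb <- obj$level_boundaries_mm
  if (is.list(lb)) lb <- do.call(rbind, lb)
  list(lesion_levels = as.integer(obj$lesion_levels),
       level_boundaries = matrix(as.numeric(lb), ncol = 2))
}

#' @rdname read_annotation
#' @param annotation A list as returned by `read_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(
    list(lesion_levels = annotation$lesion_levels,
         level_boundaries_mm = apply(annotation$level_boundaries, 1,
                                     function(r) c(r[1], r[2]),
                                     simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
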