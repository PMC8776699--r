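#' 3D CT volumes in the LPS patient frame
#'
#' An `image_volume` is a 3D array of Hounsfield units with voxel spacing
#' (mm) and the world position (mm, LPS) of the center of voxel (1,1,1).
#' Array axis 1 runs left, axis 2 posterior, axis 3 superior.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Positive length-3 numeric, mm per voxel.
#' @param origin Length-3 numeric, mm position of the first voxel center.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 2L))
    stop("all volume dimensions must be >= 2", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite", call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 frame = "LPS"),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("origin (%.2f, %.2f, %.2f) mm [LPS]; HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# world coordinates (n x 3, mm LPS) of every voxel center, column-major order
voxel_world_coords <- function(vol) {
  d <- dim(vol$voxels)
  cbind(rep(vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
            times = d[2] * d[3]),
        rep(rep(vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
                each = d[1]), times = d[3]),
        rep(vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3],
            each = d[1] * d[2]))
}

# world (mm) -> continuous 0-based voxel index
world_to_index0 <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image and reconciles its orientation to the internal
#' LPS frame. Only axis-aligned orientations (possibly permuted or flipped)
#' are supported; oblique acquisitions raise an error naming the offending
#' orientation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  # voxel->RAS affine; convert to voxel->LPS by negating the first two rows
  aff <- RNifti::xform(img)
  A <- diag(c(-1, -1, 1)) %*% aff[1:3, 1:3]
  shift <- as.vector(diag(c(-1, -1, 1)) %*% aff[1:3, 4])
  perm <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    i <- which.max(abs(A[, j]))
    if (sum(abs(A[, j]) > 1e-6 * max(abs(A[, j]))) != 1L)
      stop("unsupported oblique orientation (orientation code ",
           RNifti::orientation(img), ")", call. = FALSE)
    perm[j] <- i
    sgn[j] <- sign(A[i, j])
  }
  if (anyDuplicated(perm))
    stop("degenerate orientation matrix in ", path, call. = FALSE)
  # reorder voxel axes so axis j maps to world axis j with positive step
  arr <- aperm(arr, order(perm))
  A <- A[, order(perm), drop = FALSE]
  sgn <- sgn[order(perm)]
  d <- dim(arr)
  spacing <- numeric(3); origin <- numeric(3)
  for (j in 1:3) {
    step <- A[j, j]
    if (sgn[j] < 0) {
      arr <- switch(j,
                    arr[d[1]:1, , , drop = FALSE],
                    arr[, d[2]:1, , drop = FALSE],
                    arr[, , d[3]:1, drop = FALSE])
      origin[j] <- shift[j] + step * (d[j] - 1)
    } else {
      origin[j] <- shift[j]
    }
    spacing[j] <- abs(step)
  }
  image_volume(arr, spacing, origin)
}

#' Write a volume as NIfTI-1
#'
#' Values that are integral and within the signed 16-bit range are stored as
#' int16 (the natural CT representation); anything else as float32. The
#' header's spacing and sform encode the volume's LPS geometry.
#'
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  v <- vol$voxels
  integral <- all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
  dt <- if (integral) "int16" else "float"
  # LPS-diagonal geometry expressed in the RAS-based NIfTI affine
  aff <- diag(4)
  aff[1, 1] <- -vol$spacing[1]; aff[1, 4] <- -vol$origin[1]
  aff[2, 2] <- -vol$spacing[2]; aff[2, 4] <- -vol$origin[2]
  aff[3, 3] <- vol$spacing[3];  aff[3, 4] <- vol$origin[3]
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 1L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 1L))
  tryCatch(RNifti::writeNifti(img, path, datatype = dt),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a per-case results table as CSV
#'
#' @param records A data.frame, or a list of lists/rows sharing one schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0L)
      stop("no records to write", call. = FALSE)
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  }
  if (nrow(df) == 0L) stop("no records to write", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
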