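# clip to [lo, hi] and map to 1-based uniform bin index
intensity_bins <- function(v, bins, lo, hi) {
  v <- pmin(pmax(v, lo), hi)
  pmin(1L + as.integer((v - lo) / (hi - lo) * bins), bins)
}

# paired intensity samples: primary voxel values inside the mask against the
# secondary interpolated at the transform-mapped location; NA marks pairs
# mapping outside the secondary volume
paired_samples <- function(primary, secondary, t = rigid_transform(),
                           mask = NULL) {
  stopifnot(inherits(primary, "image_volume"),
            inherits(secondary, "image_volume"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "contour_mask"))
    sel <- which(mask$mask)
  } else {
    sel <- seq_along(primary$voxels)
  }
  pts <- voxel_world_coords(primary)[sel, , drop = FALSE]
  mapped <- transform_points(t, pts)
  idx <- world_to_index0(secondary, mapped)
  b <- cpp_sample_trilinear(secondary$voxels, dim(secondary$voxels), idx,
                            NA_real_)
  list(a = primary$voxels[sel], b = b)
}

#' Joint intensity histogram under a candidate transform
#'
#' For every primary voxel inside the mask (or all voxels when `mask` is
#' NULL), samples the secondary volume with trilinear interpolation at the
#' transform-mapped location, drops pairs mapping outside the secondary,
#' clips both intensities to `clip_range` and accumulates uniform 2D bins.
#'
#' @param primary,secondary `image_volume`s.
#' @param t Candidate `rigid_transform` mapping primary-space points to their
#'   sampling location in the secondary.
#' @param mask Optional `contour_mask` on the primary grid.
#' @param bins Bins per intensity axis (default 64).
#' @param clip_range HU clipping range, default (-200, 1500): soft tissue
#'   through hardware, extreme metal values compressed into the top bin.
#' @return Object of class `joint_histogram`: `counts` (bins x bins), the
#'   bin `edges`, and `n` retained pairs.
#' @export
joint_histogram <- function(primary, secondary, t = rigid_transform(),
                            mask = NULL, bins = 64,
                            clip_range = c(-200, 1500)) {
  stopifnot(bins >= 2, clip_range[1] < clip_range[2])
  s <- paired_samples(primary, secondary, t, mask)
  keep <- !is.na(s$b)
  n <- sum(keep)
  if (n == 0L)
    stop("degenerate overlap: no paired samples inside the secondary volume",
         call. = FALSE)
  ab <- intensity_bins(s$a, bins, clip_range[1], clip_range[2])
  counts <- cpp_joint_hist(ab, s$b, bins, clip_range[1], clip_range[2])
  edges <- seq(clip_range[1], clip_range[2], length.out = bins + 1)
  structure(list(counts = counts, edges_primary = edges,
                 edges_secondary = edges, n = n),
            class = "joint_histogram")
}

new_joint_histogram <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0), sum(counts) >= 1)
  structure(list(counts = counts, edges_primary = NULL,
                 edges_secondary = NULL, n = sum(counts)),
            class = "joint_histogram")
}

#' Marginal and joint Shannon entropies of a joint histogram
#'
#' @param jh A `joint_histogram` (or a plain count matrix).
#' @return Named numeric vector `c(H_A, H_B, H_AB)` in nats, with the
#'   convention 0 log 0 = 0.
#' @export
entropies <- function(jh) {
  if (!inherits(jh, "joint_histogram")) jh <- new_joint_histogram(jh)
  p <- jh$counts / sum(jh$counts)
  h <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  c(H_A = h(rowSums(p)), H_B = h(colSums(p)), H_AB = h(p))
}

#' Normalized mutual information on a 0-1 scale
#'
#' Returns MI / H(A,B) where MI = H(A) + H(B) - H(A,B). This equals
#' Studholme's overlap-invariant measure (H(A)+H(B))/H(A,B) minus 1, mapping
#' its 1-2 range onto 0-1 so that identical, perfectly aligned images score
#' exactly 1. When H(A,B) = 0 (both images constant — a degenerate exact
#' match) the value is 1 by convention. The result is clamped to [0, 1]
#' against floating-point drift and is invariant to the logarithm base.
#'
#' @param jh A `joint_histogram` (or count matrix).
#' @return NMI value in [0, 1].
#' @export
nmi <- function(jh) {
  e <- entropies(jh)
  if (e[["H_AB"]] <= 0) return(1)
  mi <- e[["H_A"]] + e[["H_B"]] - e[["H_AB"]]
  min(1, max(0, mi / e[["H_AB"]]))
}

#' Masked NMI of two volumes under a transform
#'
#' Convenience wrapper: joint histogram then [nmi()].
#' @inheritParams joint_histogram
#' @return NMI value in [0, 1].
#' @export
masked_nmi <- function(primary, secondary, t = rigid_transform(),
                       mask = NULL, bins = 64, clip_range = c(-200, 1500)) {
  nmi(joint_histogram(primary, secondary, t, mask, bins, clip_range))
}

#' Pearson correlation of paired intensities under a transform
#'
#' Uses the same sampling rule as [joint_histogram()] (trilinear secondary
#' samples at mask voxels, out-of-volume pairs dropped) but unbinned and
#' unclipped.
#'
#' @inheritParams joint_histogram
#' @return Sample correlation coefficient in [-1, 1].
#' @export
pearson_cc <- function(primary, secondary, t = rigid_transform(),
                       mask = NULL) {
  s <- paired_samples(primary, secondary, t, mask)
  keep <- !is.na(s$b)
  if (sum(keep) < 2L)
    stop("degenerate overlap: fewer than 2 paired samples", call. = FALSE)
  a <- s$a[keep]; b <- s$b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a paired series is constant", call. = FALSE)
  stats::cor(a, b)
}
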