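# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a digital spine phantom pair
#'
#' Describes a stack of vertebral bodies with posterior arches around a
#' spinal canal (cord + CSF), pedicle-screw fixation hardware two levels
#' above and below the lesioned vertebrae, a lytic lesion replacing bone by
#' soft tissue, additive Gaussian CT noise, and a known rigid misalignment
#' applied to the secondary (CT-myelogram) volume. In the myelogram phase the
#' CSF carries intrathecal contrast; everything else is shared anatomy.
#'
#' @param n_levels Number of vertebral levels in the stack.
#' @param level_height Craniocaudal height of one level, mm.
#' @param lesion_levels 1-based indices of the lesioned vertebrae
#'   (contiguous).
#' @param fixation_extent Levels above/below the lesion carrying screws.
#' @param hu_soft,hu_bone,hu_metal,hu_cord,hu_csf_plain,hu_csf_contrast
#'   Mean HU per tissue; must satisfy
#'   `hu_metal > hu_bone > hu_csf_contrast > hu_soft > hu_cord`.
#' @param noise_sd Standard deviation of additive Gaussian noise, HU.
#' @param true_transform `rigid_transform` misaligning the secondary volume.
#' @param spacing Voxel spacing, mm (LR, AP, CC).
#' @param nx,ny In-plane grid size in voxels.
#' @param seed Integer seed controlling the noise realisation.
#' @param lesion_seed Seed for the lesion blob geometry; independent of
#'   `seed` so structure masks do not vary with the noise realisation.
#' @param distractor_shift_mm Craniocaudal displacement of an anterior
#'   soft-tissue mass between the two phases (0 = no distractor); used to
#'   create anatomy that disagrees outside the bony landmarks.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_levels = 8, level_height = 20,
                         lesion_levels = c(4, 5), fixation_extent = 2,
                         hu_soft = 40, hu_bone = 700, hu_metal = 3000,
                         hu_cord = 30, hu_csf_plain = 15,
                         hu_csf_contrast = 600, noise_sd = 15,
                         true_transform = rigid_transform(),
                         spacing = c(1.074, 1.074, 1.0),
                         nx = 96, ny = 96,
                         seed = 1, lesion_seed = 42,
                         distractor_shift_mm = 0) {
  lesion_levels <- sort(as.integer(lesion_levels))
  if (length(lesion_levels) < 1L || length(lesion_levels) > n_levels ||
      any(lesion_levels < 1L) || any(lesion_levels > n_levels))
    stop("lesion_levels must be a non-empty subset of 1..n_levels",
         call. = FALSE)
  if (!(hu_metal > hu_bone && hu_bone > hu_csf_contrast &&
        hu_csf_contrast > hu_soft && hu_soft > hu_cord))
    stop("HU palette must satisfy metal > bone > contrast CSF > soft > cord",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(is_rigid_transform(true_transform))
  structure(list(n_levels = as.integer(n_levels),
                 level_height = level_height,
                 lesion_levels = lesion_levels,
                 fixation_extent = as.integer(fixation_extent),
                 hu_soft = hu_soft, hu_bone = hu_bone, hu_metal = hu_metal,
                 hu_cord = hu_cord, hu_csf_plain = hu_csf_plain,
                 hu_csf_contrast = hu_csf_contrast, noise_sd = noise_sd,
                 true_transform = true_transform, spacing = spacing,
                 nx = as.integer(nx), ny = as.integer(ny),
                 seed = as.integer(seed), lesion_seed = as.integer(lesion_seed),
                 distractor_shift_mm = distractor_shift_mm),
            class = "phantom_spec")
}

# label codes for the analytic anatomy
LBL <- c(air = 0L, soft = 1L, bone = 2L, metal = 3L, cord = 4L, csf = 5L,
         mass = 6L)

# fixation levels: fixation_extent levels above and below the lesion block
fixation_levels <- function(spec) {
  lo <- min(spec$lesion_levels); hi <- max(spec$lesion_levels)
  lv <- c(seq(lo - spec$fixation_extent, lo - 1),
          seq(hi + 1, hi + spec$fixation_extent))
  lv[lv >= 1 & lv <= spec$n_levels]
}

# lesion blob parameters (center offsets + radius), seeded independently of
# the noise seed so the geometry is identical across noise realisations
lesion_blobs <- function(spec) {
  with_seed(spec$lesion_seed, {
    lapply(spec$lesion_levels, function(l) {
      list(level = l,
           jx = stats::runif(1, -3, 3), jy = stats::runif(1, -3, 3),
           jz = stats::runif(1, -2, 2), radius = 8 + stats::runif(1, 0, 2))
    })
  })
}

# Analytic tissue labels at arbitrary world points (n x 3 mm, LPS).
# phase: "primary" or "secondary" — only the distractor mass position differs.
phantom_labels <- function(spec, pts, phase = "primary") {
  H <- spec$level_height
  ext_x <- (spec$nx - 1) * spec$spacing[1]
  ext_y <- (spec$ny - 1) * spec$spacing[2]
  ext_z <- spec$n_levels * H
  cx <- ext_x / 2; cy <- ext_y / 2
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  lab <- rep(LBL[["air"]], length(x))

  # paraspinal soft-tissue block
  body <- ((x - cx) / 48)^2 + ((y - cy) / 42)^2 <= 1 & z >= 0 & z <= ext_z
  lab[body] <- LBL[["soft"]]

  # vertebral bodies + posterior arches, with 3 mm disc gaps between levels;
  # body radius tapers caudally (as thoracic to lumbar vertebrae grow), which
  # also breaks the craniocaudal level-to-level translation symmetry
  zin <- z >= 0 & z < ext_z
  zb <- numeric(length(z)); zb[zin] <- z[zin] %% H
  lvl <- numeric(length(z)); lvl[zin] <- z[zin] %/% H # 0-based level index
  in_band <- zin & zb >= 1.5 & zb <= H - 1.5
  body_r <- 13 + 0.9 * lvl
  r2_body <- (x - cx)^2 + (y - (cy - 10))^2
  r2_canal <- (x - cx)^2 + (y - (cy + 8))^2
  # body cylinder, posterior arch, spinous and transverse processes — the
  # posterior elements break in-plane rotational symmetry as real vertebrae do
  bone <- in_band & (r2_body <= body_r^2 |
                       (r2_canal > 7^2 & r2_canal <= 11^2) |
                       (abs(x - cx) <= 3.5 & y >= cy + 11 & y <= cy + 30) |
                       (abs(y - (cy + 8)) <= 3 & abs(x - cx) >= 11 &
                          abs(x - cx) <= 26))
  lab[bone] <- LBL[["bone"]]

  # lytic lesion: bone replaced by soft tissue inside a seeded blob
  for (bl in lesion_blobs(spec)) {
    zc <- (bl$level - 0.5) * H
    inside <- (x - (cx + bl$jx))^2 + (y - (cy - 10 + bl$jy))^2 +
      (z - (zc + bl$jz))^2 <= bl$radius^2
    lab[inside & lab == LBL[["bone"]]] <- LBL[["soft"]]
  }

  # spinal canal: CSF with cord inside, continuous along CC
  canal <- zin & r2_canal <= 7^2
  lab[canal] <- LBL[["csf"]]
  lab[zin & r2_canal <= 3.5^2] <- LBL[["cord"]]

  # pedicle screws at fixation levels: paired rods through the pedicles
  for (l in fixation_levels(spec)) {
    zc <- (l - 0.5) * H
    for (sx in c(-12, 12)) {
      screw <- abs(x - (cx + sx)) <= 2.5 & abs(z - zc) <= 2.5 &
        y >= cy - 18 & y <= cy + 14
      lab[screw & lab != LBL[["csf"]] & lab != LBL[["cord"]]] <- LBL[["metal"]]
    }
  }

  # optional anterior soft-tissue mass that moves between phases
  if (spec$distractor_shift_mm != 0) {
    zd <- ext_z / 2 + if (phase == "secondary") spec$distractor_shift_mm else 0
    my <- cy - 0.34 * ext_y
    mr <- 0.18 * ext_y
    mass <- (x - cx)^2 + (y - my)^2 + (z - zd)^2 <= mr^2
    lab[mass & lab == LBL[["soft"]]] <- LBL[["mass"]]
  }
  lab
}

phantom_hu_map <- function(spec, csf_hu) {
  c(-1000, spec$hu_soft, spec$hu_bone, spec$hu_metal, spec$hu_cord,
    csf_hu, 300)
}

# Smooth anatomical texture (trabecular bone, soft-tissue heterogeneity)
# evaluated in anatomy coordinates, so it is rigidly carried along with the
# structures and provides the sub-voxel intensity gradients real CT has.
# Zero-mean by construction; periods are incommensurate with the grid.
phantom_texture <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  0.5 * (sin(2 * pi * x / 7.3) * cos(2 * pi * y / 5.9) +
           sin(2 * pi * z / 6.1) * cos(2 * pi * (x + y) / 8.7))
}

# per-tissue texture amplitude (HU): metal and air are homogeneous
phantom_texture_amp <- function() c(0, 15, 60, 0, 5, 5, 15)

phantom_hu <- function(spec, pts, lab, csf_hu) {
  phantom_hu_map(spec, csf_hu)[lab + 1L] +
    phantom_texture_amp()[lab + 1L] * phantom_texture(pts)
}

#' Generate a paired planning-CT / CT-myelogram phantom
#'
#' Builds the primary (planning CT) volume on a regular grid and the
#' secondary (CT-myelogram) volume by evaluating the same analytic anatomy —
#' with contrast-enhanced CSF — at coordinates mapped through the inverse of
#' the true misalignment, so the secondary is exactly the anatomy resampled
#' under `spec$true_transform`. Independent Gaussian noise is added to each
#' volume. Identical spec and seed give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_pair` with elements `primary` and
#'   `secondary` (`image_volume`s) and `truth`: the true transform, named
#'   logical structure masks (`bone`, `hardware`, `cord`, `csf`) on the
#'   primary grid, and per-level craniocaudal boundaries in mm.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- round(spec$n_levels * spec$level_height / spec$spacing[3])
  d <- c(spec$nx, spec$ny, nz)
  tmpl <- image_volume(array(0, d), spec$spacing, c(0, 0, 0))
  pts <- voxel_world_coords(tmpl)

  lab1 <- phantom_labels(spec, pts, phase = "primary")
  hu1 <- phantom_hu(spec, pts, lab1, spec$hu_csf_plain)

  pts2 <- transform_points(invert(spec$true_transform), pts)
  lab2 <- phantom_labels(spec, pts2, phase = "secondary")
  hu2 <- phantom_hu(spec, pts2, lab2, spec$hu_csf_contrast)

  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(2 * length(hu1), 0, spec$noise_sd))
    hu1 <- hu1 + noise[seq_along(hu1)]
    hu2 <- hu2 + noise[length(hu1) + seq_along(hu2)]
  }
  primary <- image_volume(array(hu1, d), spec$spacing, c(0, 0, 0))
  secondary <- image_volume(array(hu2, d), spec$spacing, c(0, 0, 0))

  masks <- list(bone = array(lab1 == LBL[["bone"]], d),
                hardware = array(lab1 == LBL[["metal"]], d),
                cord = array(lab1 == LBL[["cord"]], d),
                csf = array(lab1 == LBL[["csf"]], d))
  bounds <- cbind(z0 = (seq_len(spec$n_levels) - 1) * spec$level_height,
                  z1 = seq_len(spec$n_levels) * spec$level_height)
  truth <- list(true_transform = spec$true_transform,
                structure_masks = masks,
                level_boundaries = bounds,
                lesion_levels = spec$lesion_levels)
  structure(list(primary = primary, secondary = secondary, truth = truth,
                 spec = spec),
            class = "phantom_pair")
}

#' Resample a volume under a rigid transform
#'
#' The output grid equals the input grid; output voxel at world position p
#' takes the value of `vol` at the inverse-transformed location T^-1(p).
#' Samples falling outside the volume are filled with -1000 HU (air).
#'
#' @param vol An `image_volume`.
#' @param t A `rigid_transform`.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return An `image_volume` on the same grid.
#' @export
apply_rigid_resample <- function(vol, t,
                                 interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(vol, "image_volume"), is_rigid_transform(t))
  interpolation <- match.arg(interpolation)
  pts <- transform_points(invert(t), voxel_world_coords(vol))
  idx <- world_to_index0(vol, pts)
  d <- dim(vol$voxels)
  vals <- if (interpolation == "trilinear") {
    cpp_sample_trilinear(vol$voxels, d, idx, -1000)
  } else {
    cpp_sample_nearest(vol$voxels, d, idx, -1000)
  }
  image_volume(array(vals, d), vol$spacing, vol$origin)
}
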