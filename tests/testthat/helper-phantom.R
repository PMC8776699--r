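# Small phantom fixtures used across test files. The reduced grid (64x64x64,
# 4 levels of 16 mm) keeps registration tests fast while preserving every
# structure: vertebrae, arches, canal, cord, CSF, screws, lesion.

small_spec <- function(noise_sd = 0, ...) {
  phantom_spec(n_levels = 4, level_height = 16, lesion_levels = 2,
               nx = 64, ny = 64, noise_sd = noise_sd, ...)
}

small_center <- function(spec) {
  c((spec$nx - 1) / 2 * spec$spacing[1],
    (spec$ny - 1) / 2 * spec$spacing[2],
    spec$n_levels * spec$level_height / 2)
}

# cache the most frequently used noise-free pair
.fixture_env <- new.env(parent = emptyenv())

small_pair_identity <- function() {
  if (is.null(.fixture_env$pair))
    .fixture_env$pair <- generate_phantom_pair(small_spec())
  .fixture_env$pair
}

phantom_annot <- function(pair) {
  list(lesion_levels = pair$truth$lesion_levels,
       level_boundaries = pair$truth$level_boundaries)
}

# tiny volume whose voxel values are the given vector (recycled to 2x2xk)
tiny_volume <- function(values, k = length(values) / 4) {
  image_volume(array(values, c(2, 2, k)), c(1, 1, 1))
}

random_small_transform <- function(max_t = 5, max_r = 10,
                                   center = c(0, 0, 0)) {
  rigid_transform(runif(1, -max_t, max_t), runif(1, -max_t, max_t),
                  runif(1, -max_t, max_t), runif(1, -max_r, max_r),
                  runif(1, -max_r, max_r), runif(1, -max_r, max_r),
                  center = center)
}
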