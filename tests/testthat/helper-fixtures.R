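# Shared fixtures for the test suite; everything is generated in code.

random_volume <- function(shape = c(8L, 8L, 8L), spacing = 0.4, seed = 42L) {
  set.seed(seed)
  pa_volume(array(stats::rnorm(prod(shape)), dim = shape), spacing = spacing)
}

# straight-tube volume: capsule between a and b (0-based voxel coords)
tube_volume <- function(shape = c(40L, 40L, 40L), a = c(5, 20, 20),
                        b = c(34, 20, 20), radius = 3, spacing = 1) {
  tube <- vesselreg:::rasterize_capsules(shape, matrix(a, 1), matrix(b, 1),
                                         radius)
  pa_volume(tube, spacing = spacing, frame_tag = "tube")
}

# small desk phantom used by registration smoke tests (48^3, 3 levels)
small_phantom <- function(seed = 5L, noise = 0.02) {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L),
                       segment_length_vox = 16, root_radius_vox = 3,
                       tree_depth = 3L, noise_sigma = noise, seed = seed)
  rasterize_phantom(generate_vessel_tree(spec), spec)
}

# tiny network for derivative checks
tiny_model <- function(seed = 7L, layers = 3L, units = 16L) {
  init_network(network_arch(n_hidden_layers = layers,
                            units_per_layer = units, omega = 30,
                            seed = seed))
}

expect_all_finite <- function(x) {
  testthat::expect_true(all(is.finite(x)))
}
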