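# Shared fixture builders. All phantoms are generated in code; nothing
# binary ships with the package.

# Single-organ phantom on matched small grids.
one_organ_spec <- function(target_suv = 2, noise_sd = 0, seed = 1L,
                           rescale_slope = 0.5) {
  g <- volume_grid(c(16, 16, 12), c(3, 3, 3))
  organ <- organ_spec("liver", center = c(22.5, 22.5, 16.5),
                      semi_axes = c(14, 12, 10), ct_value = 60,
                      suv = target_suv)
  phantom_spec(g, g, list(organ), noise_sd = noise_sd, seed = seed,
               suv_params = default_suv_params(rescale_slope))
}

# Tumor-in-breast phantom (dual grid, desk scale).
tumor_spec <- function(tumor_suv = 8, noise_sd = 0, seed = 1L) {
  example_phantom_spec("desk", tumor_suv = tumor_suv, noise_sd = noise_sd,
                       seed = seed)
}

expect_grid_equal <- function(a, b, tol = 1e-6) {
  expect_true(grid_equal(a, b, tol = tol))
}
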