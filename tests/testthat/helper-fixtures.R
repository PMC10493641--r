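# Shared fixtures. The full-scale synthetic study (n = 76, the reference
# cohort size) is expensive, so it is built once per test run on first use
# and cached for every test that needs it.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

demo_config <- function() run_config(seed = 1L)

demo_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulate_study(demo_config())
  .fixtures$study
}

demo_connectome <- function() {
  if (is.null(.fixtures$connectome))
    .fixtures$connectome <- simulate_connectome(demo_study())
  .fixtures$connectome
}

demo_results <- function() {
  if (is.null(.fixtures$results))
    .fixtures$results <- analyse_study(demo_study(), demo_connectome())
  .fixtures$results
}

# A small homogeneous-conductivity image for solver tests.
homogeneous_sigma <- function(nvox = 21L, spacing = 0.75, sigma = 0.2,
                              centre = c(0, 0, 0)) {
  grid <- make_grid(rep(nvox, 3L), spacing = spacing, centre = centre)
  img_like(grid, array(sigma, dim = img_dim(grid)))
}

# A minimal atlas for unit tests that do not need the full default grid.
small_atlas <- function() {
  if (is.null(.fixtures$small_atlas))
    .fixtures$small_atlas <- make_toy_atlas(c(40L, 40L, 40L), 1)
  .fixtures$small_atlas
}

# Fabricated VTA: a spherical mask on a fine local grid, no solve.
fake_vta <- function(centre, radius = 3, resolution = 0.5, margin = 6,
                     hemisphere = "right") {
  nvox <- 2L * ceiling(margin / resolution) + 1L
  grid <- make_grid(rep(nvox, 3L), spacing = resolution, centre = centre)
  xyz <- voxel_centres(grid)
  inside <- rowSums(sweep(xyz, 2, centre)^2) <= radius^2
  mask <- img_like(grid, array(inside, dim = img_dim(grid)))
  ef <- img_like(grid, array(inside * 0.3, dim = img_dim(grid)))
  structure(list(efield = ef, mask = mask, threshold = 0.2,
                 patient_id = NA_character_, hemisphere = hemisphere),
            class = "vta_result")
}
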