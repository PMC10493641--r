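test_that("contact centres are placed from the tip along the trajectory", {
  lead <- build_lead(c(12, -13, -9), c(0, 0, 1))
  expect_equal(lead$contact_centres[, 3], -9 + 0.75 + 2 * (0:3))
  expect_equal(lead$contact_centres[, 1], rep(12, 4))
  # direction is normalised, so scaling it changes nothing
  lead2 <- build_lead(c(12, -13, -9), c(0, 0, 2))
  expect_identical(lead, lead2)
  # determinism
  expect_identical(lead, build_lead(c(12, -13, -9), c(0, 0, 1)))
  expect_error(build_lead(c(0, 0, 0), c(0, 0, 0)), "nonzero")
  expect_error(build_lead(c(0, 0, 0), c(0, 0, 1), active_contact_index = 4L),
               "existing contact")
})

test_that("lead YAML sidecar round trips", {
  lead <- build_lead(c(-11.2, -13.5, -9.1), c(0.1, 0, 1),
                     hemisphere = "left", active_contact_index = 2L)
  f <- tempfile(fileext = ".yaml")
  write_lead(lead, f)
  back <- read_lead(f)
  expect_equal(back$contact_centres, lead$contact_centres, tolerance = 1e-8)
  expect_identical(back$hemisphere, "left")
  expect_identical(back$active_contact_index, 2L)
})

test_that("conductivity rasterisation partitions the grid into 4 compartments", {
  atlas <- small_atlas()
  lead <- build_lead(c(12, -13, -9.75), c(0, 0, 1), active_contact_index = 1L)
  grid <- make_grid(c(25, 25, 25), 0.5, centre = active_contact_centre(lead))
  model <- conductivity_model()
  sig <- rasterize_conductivity(lead, atlas, grid, model)
  vals <- sort(unique(as.vector(sig$data)))
  expect_true(all(vals %in% c(model$sigma_insulation, model$sigma_white,
                              model$sigma_grey, model$sigma_contact)))
  # every voxel in exactly one compartment
  expect_equal(sum(table(sig$data)), prod(img_dim(grid)))
  # a voxel inside the STN (grey label), away from the lead
  probe <- matrix(c(14.5, -13, -7), 1)
  expect_equal(sample_at(sig, probe), model$sigma_grey)
  # a voxel on the shaft between contacts 1 and 2 is insulation
  mid <- active_contact_centre(lead) + c(0, 0, 1)  # spacing gap above contact 1
  expect_equal(sample_at(sig, matrix(mid, 1)), model$sigma_insulation)
  # far white-matter background
  expect_equal(sample_at(sig, matrix(c(8, -9, -4), 1)), model$sigma_white)
})

test_that("conductivity model rejects non-physical values", {
  expect_error(conductivity_model(sigma_grey = -1), "positive")
  expect_error(conductivity_model(sigma_contact = 0.1, sigma_grey = 0.33),
               ">>")
})

test_that("zero amplitude gives a zero potential and doubling is linear", {
  sig <- homogeneous_sigma(nvox = 15L, spacing = 1)
  lead <- build_lead(c(0, 0, -5), c(0, 0, 1))
  phi0 <- solve_potential(sig, lead, stimulation_setting(0))
  expect_true(all(phi0$data == 0))
  phi1 <- solve_potential(sig, lead, stimulation_setting(1.3))
  phi2 <- solve_potential(sig, lead, stimulation_setting(2.6))
  expect_equal(phi2$data, 2 * phi1$data, tolerance = 1e-12)
})

test_that("field magnitude recovers exact gradients of linear potentials", {
  grid <- make_grid(c(9, 9, 9), 1)
  xyz <- voxel_centres(grid)
  # slope 1 V/mm in x
  phi <- img_like(grid, array(xyz[, 1], dim = img_dim(grid)))
  ef <- efield_magnitude(phi)
  expect_equal(unique(round(as.vector(ef$data), 12)), 1)
  # constant potential: zero field
  ef0 <- efield_magnitude(img_like(grid, array(5, dim = img_dim(grid))))
  expect_true(all(ef0$data == 0))
  # x + y: sqrt(2)
  phi2 <- img_like(grid, array(xyz[, 1] + xyz[, 2], dim = img_dim(grid)))
  ef2 <- efield_magnitude(phi2)
  expect_equal(unique(round(as.vector(ef2$data), 12)), round(sqrt(2), 12))
  expect_error(efield_magnitude(image3d(array(0, dim = c(1, 5, 5)))),
               "single-voxel")
})

test_that("thresholding is elementwise and rejects bad thresholds", {
  grid <- make_grid(c(5, 5, 5), 1)
  hi <- threshold_vta(img_like(grid, array(0.3, dim = c(5, 5, 5))))
  expect_true(all(hi$mask$data))
  lo <- threshold_vta(img_like(grid, array(0.1, dim = c(5, 5, 5))))
  expect_false(any(lo$mask$data))
  expect_error(threshold_vta(hi$efield, threshold = 0), "> 0")
})

test_that("VTA masks are nested and non-decreasing in amplitude", {
  atlas <- small_atlas()
  lead <- build_lead(c(12, -13, -9.75), c(0, 0, 1), active_contact_index = 2L)
  masks <- lapply(1:4, function(a)
    compute_vta(lead, stimulation_setting(a), atlas = atlas,
                resolution = 0.75, margin = 6)$mask$data)
  for (k in 1:3) {
    expect_true(all(masks[[k + 1]][masks[[k]]]))           # nested
    expect_lte(sum(masks[[k]]), sum(masks[[k + 1]]))       # non-decreasing
  }
})

test_that("a mirrored conductivity volume yields the mirrored VTA", {
  atlas <- small_atlas()
  spec <- default_lead_spec()
  lead_r <- build_lead(c(12, -13, -9.75), c(0, 0, 1), spec, "right", 2L)
  lead_l <- build_lead(c(-12, -13, -9.75), c(0, 0, 1), spec, "left", 2L)
  grid_r <- make_grid(rep(25L, 3), 0.5, centre = active_contact_centre(lead_r))
  grid_l <- make_grid(rep(25L, 3), 0.5, centre = active_contact_centre(lead_l))
  sig_r <- rasterize_conductivity(lead_r, atlas, grid_r)
  sig_l <- img_like(grid_l, sig_r$data[25:1, , ])   # mirrored sigma
  setting <- stimulation_setting(2.4)
  mask_r <- threshold_vta(efield_magnitude(
    solve_potential(sig_r, lead_r, setting)))$mask$data
  mask_l <- threshold_vta(efield_magnitude(
    solve_potential(sig_l, lead_l, setting)))$mask$data
  expect_identical(mask_l, mask_r[25:1, , ])
})

test_that("finite-difference solve matches the analytic monopole at coarse scale", {
  # open-boundary solve in a homogeneous medium vs c/r fitted at r = 3 mm
  sig <- homogeneous_sigma(nvox = 21L, spacing = 0.75, sigma = 0.2)
  spec <- default_lead_spec(n_contacts = 1L, contact_length = 1.5,
                            contact_spacing = 0.5, contact_radius = 0.635)
  lead <- build_lead(c(0, 0, -0.75), c(0, 0, 1), spec)
  phi <- solve_potential(sig, lead, stimulation_setting(1), boundary = "open")
  xyz <- voxel_centres(phi)
  r <- sqrt(rowSums(xyz^2))
  probe <- abs(xyz[, 3]) < 1e-9 & abs(xyz[, 2]) < 1e-9  # x axis
  rr <- r[probe]; vv <- as.vector(phi$data)[probe]
  cfit <- vv[which.min(abs(rr - 3))] * rr[which.min(abs(rr - 3))]
  sel <- rr >= 2 & rr <= 6
  expect_lt(max(abs(cfit / rr[sel] - vv[sel]) / vv[sel]), 0.05)
})

test_that("halving the voxel size changes the VTA volume by less than 10%", {
  atlas <- small_atlas()
  lead <- build_lead(c(12, -13, -9.75), c(0, 0, 1), active_contact_index = 2L)
  v1 <- vta_volume(compute_vta(lead, stimulation_setting(2.4), atlas = atlas,
                               resolution = 0.5, margin = 5))
  v2 <- vta_volume(compute_vta(lead, stimulation_setting(2.4), atlas = atlas,
                               resolution = 0.25, margin = 5))
  expect_lt(abs(v1 - v2) / v2, 0.10)
})
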