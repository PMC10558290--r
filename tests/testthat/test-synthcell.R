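test_that("ground-truth fraction hits its defining limits", {
  none <- generate_cell_stack(synth_params(n_structures = 0, seed = 2))
  expect_equal(none$truth$true_cytosolic_fraction, 1)

  dark <- generate_cell_stack(synth_params(cytosol_intensity = 0,
                                           n_structures = 5, seed = 2))
  expect_equal(dark$truth$true_cytosolic_fraction, 0)

  # structures carrying one-third of the total signal -> fraction 2/3
  twothirds <- generate_cell_stack(synth_params(target_fraction = 2 / 3,
                                                seed = 5))
  expect_equal(twothirds$truth$true_cytosolic_fraction, 2 / 3)
  ints <- twothirds$truth$integrals
  expect_equal(ints$structure / (ints$cytosol + ints$structure), 1 / 3)
})

test_that("pre-noise signal is conserved through the PSF blur", {
  sim <- generate_cell_stack(synth_params(target_fraction = 0.5, seed = 8))
  ints <- sim$truth$integrals
  expect_equal(ints$cytosol_blurred, ints$cytosol, tolerance = 0.01)
  expect_equal(ints$structure_blurred, ints$structure, tolerance = 0.01)
  # hence the ground-truth fraction is blur-invariant
  blurred_fr <- ints$cytosol_blurred /
    (ints$cytosol_blurred + ints$structure_blurred)
  expect_equal(blurred_fr, sim$truth$true_cytosolic_fraction,
               tolerance = 0.01)
})

test_that("stacks are bitwise reproducible under a fixed seed", {
  a <- generate_cell_stack(synth_params(seed = 31))
  b <- generate_cell_stack(synth_params(seed = 31))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$true_cytosolic_fraction,
                   b$truth$true_cytosolic_fraction)
  c <- generate_cell_stack(synth_params(seed = 32))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("noisy voxels average back to the noise-free field", {
  # structure-free cell so geometry is seed-independent; average many
  # noise realisations at reduced size and compare to a fresh
  # noise-suppressed render
  base <- synth_params(n_structures = 0, cell_radius = 0.6, margin = 4,
                       n_slices = 9, read_noise_sd = 2, seed = 1)
  acc <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    p <- base; p$seed <- 1000L + s
    acc <- acc + generate_cell_stack(p)$stack$voxels[, , , "abp"]
  }
  avg <- acc / n_rep
  interior <- generate_cell_stack(base)$truth$cell_mask
  # compare in-cell means (clipping at 0 makes dark voxels slightly biased)
  clean <- synth_params(n_structures = 0, cell_radius = 0.6, margin = 4,
                        n_slices = 9, read_noise_sd = 0, seed = 1)
  expect_equal(mean(avg[interior]),
               mean(generate_cell_stack(clean)$stack$voxels[, , , "abp"][interior]),
               tolerance = 0.05)
})

test_that("structures that cannot fit in the cell are rejected", {
  expect_error(generate_cell_stack(
    synth_params(cell_radius = 0.5, n_structures = 500,
                 structure_size = 0.2, margin = 4, seed = 1)),
    "exceed")
  expect_error(synth_params(cell_radius = 5),  # 10 um cell in a 7 um stack
               "axial")
})

test_that("populations follow the requested fraction law", {
  const <- generate_population(50, fraction_law = "constant",
                               fraction = 0.8, seed = 12)
  expect_equal(const$manifest$true_fraction, rep(0.8, 50))
  expect_true(all(const$manifest$area_um2 >= 12 &
                    const$manifest$area_um2 <= 36))

  lin0 <- generate_population(50, fraction_law = "linear_in_area",
                              fraction = 0.8, slope = 0, seed = 12)
  expect_equal(lin0$manifest$true_fraction, const$manifest$true_fraction)

  lin <- generate_population(50, fraction_law = "linear_in_area",
                             fraction = 0.7, slope = 0.005, seed = 12)
  fit <- lm(true_fraction ~ area_um2, data = lin$manifest)
  expect_equal(unname(coef(fit)[2]), 0.005, tolerance = 1e-10)

  again <- generate_population(50, fraction_law = "constant",
                               fraction = 0.8, seed = 12)
  expect_identical(again$manifest, const$manifest)
  expect_error(generate_population(5, area_range = c(10, 10)), "empty")
})

test_that("rendered population cells carry their manifest ground truth", {
  pop <- generate_population(2, fraction = 0.65, seed = 77, render = TRUE)
  expect_length(pop$cells, 2L)
  for (i in 1:2) {
    expect_equal(pop$cells[[i]]$truth$true_cytosolic_fraction, 0.65,
                 tolerance = 1e-10)
    expect_equal(pop$cells[[i]]$truth$cell_area,
                 pop$manifest$area_um2[i], tolerance = 0.05)
  }
})

test_that("stacks round-trip through TIFF plus JSON sidecar", {
  sim <- generate_cell_stack(synth_params(cell_radius = 0.6, margin = 4,
                                          n_slices = 7, seed = 3))
  stem <- file.path(withr::local_tempdir(), "stack")
  write_image_stack(sim$stack, stem)
  back <- read_image_stack(stem)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$z_step, sim$stack$z_step)
  expect_equal(back$voxels, sim$stack$voxels,
               tolerance = 1e-6)
})
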