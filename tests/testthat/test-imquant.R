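test_that("projections compute pixelwise mean and max over z", {
  # two slices with values 1 and 3 in every pixel
  s1 <- matrix(1, 4, 4); s2 <- matrix(3, 4, 4)
  stk <- tiny_stack(array(c(s1, s2), dim = c(4, 4, 2)))
  expect_equal(project(stk, "abp", "average")$pixels, matrix(2, 4, 4))
  expect_equal(project(stk, "abp", "maximum")$pixels, matrix(3, 4, 4))

  single <- tiny_stack(array(7, dim = c(3, 3, 1)))
  expect_equal(project(single, "abp", "average")$pixels, matrix(7, 3, 3))
  expect_equal(project(single, "abp", "maximum")$pixels, matrix(7, 3, 3))

  # average never exceeds maximum
  set.seed(4)
  rnd <- tiny_stack(array(runif(4 * 4 * 5), dim = c(4, 4, 5)))
  expect_true(all(project(rnd, "abp", "average")$pixels <=
                    project(rnd, "abp", "maximum")$pixels))
})

test_that("segmentation finds synthetic cells and flags the border", {
  sim <- fixture_patch_cell()
  proj <- project(sim$stack, "abp", "average")
  cells <- segment_cells(proj)
  expect_length(cells, 1L)
  truth2d <- apply(sim$truth$cell_mask, c(1, 2), any)
  overlap <- sum(cells[[1]]$mask & truth2d) / sum(truth2d)
  expect_gte(overlap, 0.95)
  expect_false(cells[[1]]$border)
  expect_equal(cells[[1]]$area_um2, sim$truth$cell_area, tolerance = 0.1)

  blank <- as_projection(matrix(0, 32, 32), 0.065)
  expect_warning(res <- segment_cells(blank), "no cell")
  expect_length(res, 0L)

  # two well-separated cells in one composite field of view
  two <- as_projection(cbind(proj$pixels, proj$pixels), proj$pixel_size)
  expect_length(segment_cells(two), 2L)
})

test_that("background estimation scales with the autofluorescence level", {
  zero <- generate_cell_stack(synth_params(structure_kind = "none",
                                           n_structures = 0,
                                           cytosol_intensity = 0,
                                           autofluorescence = 0,
                                           read_noise_sd = 0, seed = 6))
  expect_equal(estimate_background(project(zero$stack, "abp", "average")), 0,
               tolerance = 1e-6)

  mk <- function(af, seed) {
    s <- generate_cell_stack(synth_params(structure_kind = "none",
                                          n_structures = 0,
                                          cytosol_intensity = 0,
                                          autofluorescence = af,
                                          seed = seed))
    estimate_background(project(s$stack, "abp", "average"))
  }
  b10 <- mk(10, 61); b20 <- mk(20, 61)
  expect_gt(b10, 0)
  # proportional up to segmentation of the dim boundary ring
  expect_equal(b20 / b10, 2, tolerance = 0.1)

  # background larger than the cell signal is flagged downstream
  sim <- fixture_patch_cell()
  m <- measure_stack(sim$stack, background = 0)
  expect_error(cytosolic_fraction(project(sim$stack, "abp", "average"),
                                  m$cell_mask, m$structure_mask,
                                  background = 1e6),
               "not positive")
})

test_that("structure masks threshold the marker and shrink monotonically", {
  sim <- fixture_patch_cell()
  marker <- project(sim$stack, "marker", "maximum")
  expect_true(all(make_structure_mask(marker, 0)))
  expect_warning(empty <- make_structure_mask(marker,
                                              max(marker$pixels) + 1),
                 "empty mask")
  expect_false(any(empty))
  sps <- quantile(marker$pixels, c(0.5, 0.7, 0.9, 0.99))
  masks <- lapply(sps, function(sp) make_structure_mask(marker, sp))
  for (i in 2:4) expect_true(all(masks[[i]] <= masks[[i - 1]]))

  # the automatic set point captures the ground-truth structure cores
  cmask <- apply(sim$truth$cell_mask, c(1, 2), any)
  sp <- default_set_point(marker, cmask)
  smask <- make_structure_mask(marker, sp)
  truth_px <- apply(sim$truth$structure_voxels, c(1, 2), any)
  expect_gte(sum(smask & truth_px) / sum(truth_px), 0.95)
})

test_that("cytosolic fraction has the right fixed points and errors", {
  flat <- as_projection(matrix(5, 8, 8), 0.1)
  cmask <- matrix(TRUE, 8, 8)
  smask <- matrix(FALSE, 8, 8); smask[3:4, 3:4] <- TRUE
  r <- cytosolic_fraction(flat, cmask, smask)
  expect_equal(r$cytosolic_fraction, 1)   # uniform cell: means equal
  expect_false(r$flagged)
  expect_error(cytosolic_fraction(flat, cmask, cmask), "undefined fraction")
  expect_error(cytosolic_fraction(flat, matrix(FALSE, 8, 8), smask),
               "empty cell mask")
})

test_that("measured fraction recovers the generator ground truth", {
  bg <- fixture_background()
  sim <- generate_cell_stack(synth_params(target_fraction = 0.75,
                                          seed = 301))
  m <- measure_stack(sim$stack, background = bg)
  expect_equal(m$result$cytosolic_fraction, 0.75, tolerance = 0.07)
  expect_equal(m$result$cell_area, sim$truth$cell_area, tolerance = 0.1)
})

test_that("the measurement is invariant to a global intensity rescaling", {
  bg <- fixture_background()
  sim <- fixture_patch_cell()
  m <- measure_stack(sim$stack, background = bg)
  abp <- project(sim$stack, "abp", "average")
  scaled <- as_projection(3 * abp$pixels, abp$pixel_size)
  r1 <- cytosolic_fraction(abp, m$cell_mask, m$structure_mask,
                           background = bg)
  r2 <- cytosolic_fraction(scaled, m$cell_mask, m$structure_mask,
                           background = 3 * bg)
  expect_equal(r2$cytosolic_fraction, r1$cytosolic_fraction,
               tolerance = 1e-12)
})

test_that("fraction tends to 1 as the set point removes the mask", {
  bg <- fixture_background()
  sim <- fixture_patch_cell()
  abp <- project(sim$stack, "abp", "average")
  marker <- project(sim$stack, "marker", "maximum")
  m <- measure_stack(sim$stack, background = bg)
  huge <- suppressWarnings(make_structure_mask(marker,
                                               max(marker$pixels) + 1))
  r <- cytosolic_fraction(abp, m$cell_mask, huge, background = bg)
  expect_equal(r$cytosolic_fraction, 1)
})

test_that("structure-free cells measure a fraction of one within noise", {
  bg <- fixture_background()
  frs <- vapply(1:8, function(s) {
    sim <- generate_cell_stack(synth_params(n_structures = 0,
                                            seed = 500L + s))
    # the marker channel carries no structure signal: the automatic set
    # point warns and yields an empty mask
    suppressWarnings(
      measure_stack(sim$stack, background = bg)$result$cytosolic_fraction)
  }, numeric(1))
  expect_equal(mean(frs), 1, tolerance = 0.02)
})

test_that("threshold sweep reports sensitivity and validates inputs", {
  bg <- fixture_background()
  sim <- fixture_patch_cell()
  abp <- project(sim$stack, "abp", "average")
  marker <- project(sim$stack, "marker", "maximum")
  m <- measure_stack(sim$stack, background = bg)
  sw <- threshold_sweep(abp, m$cell_mask, marker, m$set_point,
                        background = bg)
  expect_length(sw$fractions, 3L)
  expect_lt(sw$sensitivity, 0.05)
  expect_equal(sw$set_points, m$set_point * c(0.75, 1, 1.25))
  expect_error(threshold_sweep(abp, m$cell_mask, marker, 0), "> 0")

  # uniform cell: every threshold yields exactly 1
  flat <- tiny_stack(array(10, dim = c(12, 12, 3)))
  fa <- project(flat, "abp", "average")
  fm <- project(flat, "marker", "maximum")
  sw0 <- suppressWarnings(
    threshold_sweep(fa, matrix(TRUE, 12, 12), fm, set_point = 15))
  expect_equal(sw0$fractions, rep(1, 3))
  expect_equal(sw0$sensitivity, 0)
})

test_that("cable cells are measured with a modest downward bias", {
  bg <- fixture_background()
  sim <- generate_cell_stack(synth_params(structure_kind = "cable",
                                          n_structures = 5,
                                          target_fraction = 0.85,
                                          seed = 21))
  m <- measure_stack(sim$stack, background = bg)
  # masking whole stripes of the projection removes thick central
  # columns of cytosol, so the cable measurement reads low
  expect_lt(m$result$cytosolic_fraction, 0.9)
  expect_equal(m$result$cytosolic_fraction, 0.85, tolerance = 0.2)
})

test_that("population measurement table matches the generator manifest", {
  bg <- fixture_background()
  pop <- generate_population(3, fraction = 0.7, seed = 41, render = TRUE)
  tbl <- measure_population(pop, background = bg)
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$true_fraction, rep(0.7, 3))
  expect_equal(tbl$fraction, tbl$true_fraction, tolerance = 0.1)
  expect_equal(tbl$area_um2, pop$manifest$area_um2, tolerance = 0.05)
})
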