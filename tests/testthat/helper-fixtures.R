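# Shared fixtures for the imaging tests. The background estimate and a
# couple of standard stacks are computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Background level measured from a label-free (autofluorescence-only)
# synthetic cell, as the pipeline would in a real session.
fixture_background <- function() {
  if (is.null(.fixture_cache$bg)) {
    blank <- generate_cell_stack(synth_params(
      structure_kind = "none", n_structures = 0,
      cytosol_intensity = 0, seed = 9901L))
    .fixture_cache$bg <- estimate_background(
      project(blank$stack, "abp", "average"))
  }
  .fixture_cache$bg
}

# One default patch cell reused across read-only checks.
fixture_patch_cell <- function() {
  if (is.null(.fixture_cache$patch)) {
    .fixture_cache$patch <- generate_cell_stack(
      synth_params(target_fraction = 0.7, seed = 4242L))
  }
  .fixture_cache$patch
}

# A tiny stack built by hand: 2 slices, known voxel values.
tiny_stack <- function(vals_abp, vals_marker = vals_abp,
                       pixel_size = 0.1, z_step = 0.2) {
  stopifnot(identical(dim(vals_abp), dim(vals_marker)))
  voxels <- array(c(vals_abp, vals_marker), dim = c(dim(vals_abp), 2))
  image_stack(voxels, pixel_size, z_step)
}
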