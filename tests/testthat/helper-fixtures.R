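# Shared fixtures, built in code at test time.

# Small uniform-background test grid (no phantom geometry), for noise and
# mask arithmetic.
uniform_image <- function(value = 10, n = c(24L, 24L, 12L), voxel = 2) {
  g <- build_grid(n, in_plane_fov = n[1L] * voxel, slice_thickness = voxel)
  image3d(array(value, dim = n), g)
}

# A single hot sphere in a warm cylinder on a small isotropic grid; cheap
# enough for repeated rasterize/blur cycles.
single_sphere_phantom <- function(diameter = 19.8, contrast = 3.88,
                                  background = 4.8) {
  phantom_spec(cylinder_radius = 40, cylinder_height = 70,
               background_concentration = background,
               spheres = list(sphere_spec(c(0, 0, 0), diameter,
                                          contrast * background)))
}

small_grid <- function(n = c(48L, 48L, 40L), voxel = 2) {
  build_grid(n, in_plane_fov = n[1L] * voxel, slice_thickness = voxel)
}

# Default study phantom on the coarse (phantom-reconstruction) grid.
study_phantom_image <- function(subsample = 2L) {
  ph <- contrast_phantom()
  g <- build_grid(c(128L, 128L, 89L), 356, 2.78)
  list(phantom = ph, grid = g,
       img = rasterize_phantom(ph, g, subsample = subsample))
}
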