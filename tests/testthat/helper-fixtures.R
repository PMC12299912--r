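# Shared, lazily built fixtures. The 3D slab operator and its SVD are the
# expensive objects (~1 s each); build once per test run.
.fx <- new.env(parent = emptyenv())

fx_grid3d <- function() {
  if (is.null(.fx$grid3d)) .fx$grid3d <- imaging_grid(spacing = 5,
                                                      z = c(40, 160))
  .fx$grid3d
}

fx_op3d <- function() {
  if (is.null(.fx$op3d))
    .fx$op3d <- assemble_operator(default_array(), fx_grid3d())
  .fx$op3d
}

fx_svd3d <- function() {
  if (is.null(.fx$svd3d)) .fx$svd3d <- decompose(fx_op3d())
  .fx$svd3d
}

fx_grid2d <- function() {
  if (is.null(.fx$grid2d)) .fx$grid2d <- imaging_grid(spacing = 5, z = 100)
  .fx$grid2d
}

fx_op2d <- function() {
  if (is.null(.fx$op2d))
    .fx$op2d <- assemble_operator(default_array(), fx_grid2d())
  .fx$op2d
}

# Differential S-vector of one scenario on the 3D operator.
fx_ds <- function(label, center, diameter) {
  op <- fx_op3d()
  forward_dS(op, true_contrast(stroke_scenario(label, center = center,
                                               diameter = diameter),
                               op$grid, op$frequency))
}

# Toy operator: full 10-antenna array on a coarse single-slice grid with
# more voxels than channels (fat matrix), cheap enough for dense algebra.
fx_toy_op <- function() {
  if (is.null(.fx$toy_op)) {
    g <- imaging_grid(spacing = 18, z = 100)
    .fx$toy_op <- assemble_operator(default_array(), g)
  }
  .fx$toy_op
}
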