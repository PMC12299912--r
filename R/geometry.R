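# Container geometry: a 10-sided oval tank, inner cross-section 220 x 180 mm.
# Coordinates: origin at the XY center of the container, z = 0 at the
# container bottom, antenna ring plane at z = 100 mm. All lengths in mm.
.SEMI_AXES <- c(110, 90)
.RING_Z <- 100

#' Test whether XY points lie inside the head oval
#'
#' The oval cross-section is modeled as the ellipse with semi-axes
#' 110 x 90 mm (half the 220 x 180 mm inner dimensions), optionally shrunk
#' by a margin (used to keep a sphere of that radius fully inside).
#'
#' @param x,y Coordinates in mm (vectorized).
#' @param margin Shrink both semi-axes by this many mm (default 0).
#' @param semi_axes Length-2 vector `(a, b)` in mm.
#' @param strict Require the strict interior (excludes the boundary,
#'   where the antennas sit).
#' @return Logical vector.
#' @export
in_head_oval <- function(x, y, margin = 0, semi_axes = .SEMI_AXES,
                         strict = FALSE) {
  a <- semi_axes[1] - margin
  b <- semi_axes[2] - margin
  if (a <= 0 || b <= 0) stop("margin larger than the oval semi-axes")
  q <- (x / a)^2 + (y / b)^2
  if (strict) q < 1 - 1e-9 else q <= 1
}

#' Antenna array constructor
#'
#' @param positions Numeric 10 x 3 matrix of antenna positions (x, y, z) mm.
#'   All antennas must share the same z (single ring).
#' @param frequency Operating frequency in Hz.
#' @return An object of class `antenna_array`.
#' @export
antenna_array <- function(positions, frequency = 1e9) {
  positions <- as.matrix(positions)
  if (nrow(positions) != 10L || ncol(positions) != 3L)
    stop("positions must be a 10 x 3 matrix")
  if (diff(range(positions[, 3])) > 1e-9)
    stop("all antennas must lie in one plane (equal z)")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(positions = unname(positions), frequency = frequency),
            class = "antenna_array")
}

#' Default 10-antenna ring
#'
#' Places the 10 antennas at the wall centers of a decagonal approximation
#' of the 220 x 180 mm oval: angles `theta_i = 2 pi i / 10 + pi / 10`
#' (i = 0..9) on the ellipse `(110 cos theta, 90 sin theta)`, ring plane at
#' z = 100 mm. The half-angle offset centers each antenna on a wall rather
#' than a vertex, giving a layout symmetric under point reflection through
#' the container center.
#'
#' @param frequency Operating frequency in Hz (default 1 GHz).
#' @param ring_z Ring plane height in mm (default 100).
#' @param semi_axes Oval semi-axes `(a, b)` in mm.
#' @return An `antenna_array`.
#' @export
default_array <- function(frequency = 1e9, ring_z = .RING_Z,
                          semi_axes = .SEMI_AXES) {
  theta <- 2 * pi * (0:9) / 10 + pi / 10
  antenna_array(cbind(semi_axes[1] * cos(theta),
                      semi_axes[2] * sin(theta),
                      ring_z),
                frequency = frequency)
}

#' Imaging grid over the head region
#'
#' Regular, axis-aligned voxel grid restricted to the oval head
#' cross-section. With a single z level this is the in-plane (XY) grid used
#' for slice imaging; with a z range it is a 3D slab for out-of-plane
#' studies.
#'
#' @param spacing Isotropic voxel pitch in mm (default 5).
#' @param z Either a single z level in mm (2D slice grid) or a length-2
#'   range `c(zmin, zmax)` discretized at `spacing`.
#' @param semi_axes Oval semi-axes `(a, b)` in mm.
#' @return An object of class `imaging_grid` with fields `centers`
#'   (N x 3 mm), `voxel_volume` (mm^3), `spacing`, axis vectors
#'   `xs`, `ys`, `zs` and integer voxel indices `ix`, `iy`, `iz`.
#' @export
imaging_grid <- function(spacing = 5, z = .RING_Z, semi_axes = .SEMI_AXES) {
  stopifnot(spacing > 0)
  xs <- seq(-semi_axes[1], semi_axes[1], by = spacing)
  ys <- seq(-semi_axes[2], semi_axes[2], by = spacing)
  zs <- if (length(z) == 1L) z else seq(z[1], z[2], by = spacing)
  full <- expand.grid(ix = seq_along(xs), iy = seq_along(ys),
                      iz = seq_along(zs))
  cx <- xs[full$ix]; cy <- ys[full$iy]; cz <- zs[full$iz]
  keep <- in_head_oval(cx, cy, semi_axes = semi_axes, strict = TRUE)
  structure(list(centers = cbind(x = cx[keep], y = cy[keep], z = cz[keep]),
                 voxel_volume = spacing^3,
                 spacing = spacing,
                 xs = xs, ys = ys, zs = zs,
                 ix = full$ix[keep], iy = full$iy[keep], iz = full$iz[keep],
                 semi_axes = semi_axes),
            class = "imaging_grid")
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("<imaging_grid> %d voxels, %.3g mm pitch, %d z level(s)\n",
              nrow(x$centers), x$spacing, length(x$zs)))
  invisible(x)
}

n_voxels <- function(grid) nrow(grid$centers)

# Identity check used to guard operator/contrast grid mismatches.
same_grid <- function(g1, g2) {
  nrow(g1$centers) == nrow(g2$centers) &&
    isTRUE(all.equal(g1$centers, g2$centers, tolerance = 1e-12))
}
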