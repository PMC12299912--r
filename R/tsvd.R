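#' Singular value decomposition of the Born operator
#'
#' Offline stage of the imaging pipeline: decompose the 55 x N operator
#' as `L = U diag(S) V^H` (complex SVD). Reconstruction then only needs
#' the factors, so the decomposition can be cached and reused across
#' measurements.
#'
#' @param operator A [born_operator] with finite entries.
#' @return An object of class `operator_svd` with fields `u` (55 x r),
#'   `d` (nonincreasing singular values), `v` (N x r) and `operator`.
#' @export
decompose <- function(operator) {
  stopifnot(inherits(operator, "born_operator"))
  if (!all(is.finite(Re(operator$matrix)) & is.finite(Im(operator$matrix))))
    stop("operator has non-finite entries")
  s <- svd(operator$matrix)
  structure(list(u = s$u, d = s$d, v = s$v, operator = operator),
            class = "operator_svd")
}

#' @export
print.operator_svd <- function(x, ...) {
  cat(sprintf("<operator_svd> rank %d, sigma_1 = %.4g, sigma_r = %.4g\n",
              length(x$d), x$d[1], x$d[length(x$d)]))
  invisible(x)
}

#' TSVD reconstruction of the contrast change
#'
#' Online stage: regularized inversion of the differential S-vector by the
#' truncated SVD pseudo-inverse,
#' `dO = sum_{n=1..nT} (u_n^H dS / sigma_n) v_n`.
#' Truncation discards the small singular components that would amplify
#' measurement noise; the default truncation index is 50.
#'
#' @param svd An [decompose()] result.
#' @param dS Complex differential S-vector (length 55).
#' @param nT Truncation index, `1 <= nT <= rank`.
#' @return A complex [contrast_map] on the operator grid.
#' @export
reconstruct <- function(svd, dS, nT = 50) {
  stopifnot(inherits(svd, "operator_svd"))
  if (length(dS) != nrow(svd$u))
    stop("dS length ", length(dS), " does not match the operator's ",
         nrow(svd$u), " channels")
  r <- length(svd$d)
  if (nT < 1 || nT > r)
    stop("nT out of range: must be between 1 and ", r)
  coef <- drop(Conj(t(svd$u[, 1:nT, drop = FALSE])) %*% dS) / svd$d[1:nT]
  values <- drop(svd$v[, 1:nT, drop = FALSE] %*% coef)
  contrast_map(values, svd$operator$grid, kind = "complex")
}

#' Magnitude image
#'
#' Replaces each voxel value by its modulus `|dO|`; the reconstructed
#' images are interpreted through the absolute contrast change only.
#'
#' @param map A complex [contrast_map].
#' @return A [contrast_map] of kind `"magnitude"`.
#' @export
magnitude_image <- function(map) {
  stopifnot(inherits(map, "contrast_map"))
  contrast_map(Mod(map$values), map$grid, kind = "magnitude")
}

#' 3 x 3 box blur of a 2D image
#'
#' Uniform averaging filter: convolution with a 3 x 3 matrix of ones
#' normalized by 9 so amplitudes stay comparable before and after
#' blurring. Edges are reflect-padded, so a constant image is preserved
#' exactly.
#'
#' @param img Numeric matrix, at least 3 x 3.
#' @return Blurred matrix of the same size.
#' @export
box_blur <- function(img) {
  img <- as.matrix(img)
  n <- nrow(img); m <- ncol(img)
  if (n < 3 || m < 3) stop("image slice must be at least 3 x 3")
  ri <- c(1, 1:n, n)            # reflect padding indices
  ci <- c(1, 1:m, m)
  p <- img[ri, ci]
  out <- matrix(0, n, m)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + 1:n, dc + 1:m]
  out / 9
}

#' Extract a 2D slice from a contrast map
#'
#' Returns the map restricted to one grid plane as a dense matrix (voxels
#' outside the head oval are zero), with the axis coordinates attached.
#'
#' @param map A [contrast_map].
#' @param plane `"xy"` (slice at a z level) or `"xz"` (slice at a y
#'   level).
#' @param at Coordinate of the slice in mm; defaults to the level nearest
#'   the middle of the corresponding axis. Snapped to the nearest grid
#'   level.
#' @return A list with `values` (matrix, rows = first axis), `a1`, `a2`
#'   (axis coordinate vectors in mm), and `plane`.
#' @export
slice_map <- function(map, plane = c("xy", "xz"), at = NULL) {
  plane <- match.arg(plane)
  g <- map$grid
  vals <- if (is.complex(map$values)) Mod(map$values) else map$values
  if (plane == "xy") {
    levels <- g$zs
    coord <- g$centers[, 3]
    a1 <- g$xs; a2 <- g$ys; i1 <- g$ix; i2 <- g$iy
  } else {
    levels <- g$ys
    coord <- g$centers[, 2]
    a1 <- g$xs; a2 <- g$zs; i1 <- g$ix; i2 <- g$iz
  }
  if (is.null(at)) at <- levels[ceiling(length(levels) / 2)]
  lv <- levels[which.min(abs(levels - at))]
  sel <- abs(coord - lv) < 1e-9
  out <- matrix(0, length(a1), length(a2))
  out[cbind(i1[sel], i2[sel])] <- vals[sel]
  list(values = out, a1 = a1, a2 = a2, plane = plane, at = lv)
}

#' Slice-wise blurred magnitude map
#'
#' Applies [magnitude_image()] and then the 3 x 3 box blur to every XY
#' slice of the map (matching the slice-wise presentation of the images).
#' Voxels outside the head oval enter the blur as zeros.
#'
#' @param map A [contrast_map].
#' @return A [contrast_map] of kind `"blurred-magnitude"`.
#' @export
blur_map <- function(map) {
  stopifnot(inherits(map, "contrast_map"))
  g <- map$grid
  vals <- if (is.complex(map$values)) Mod(map$values) else map$values
  out <- numeric(length(vals))
  for (z in g$zs) {
    sel <- abs(g$centers[, 3] - z) < 1e-9
    full <- matrix(0, length(g$xs), length(g$ys))
    full[cbind(g$ix[sel], g$iy[sel])] <- vals[sel]
    b <- box_blur(full)
    out[sel] <- b[cbind(g$ix[sel], g$iy[sel])]
  }
  contrast_map(out, g, kind = "blurred-magnitude")
}

#' Localize the reconstructed inclusion
#'
#' Returns the voxel-center coordinates of the maximum of the (blurred)
#' magnitude image. Ties are broken deterministically by the lowest voxel
#' index. An all-zero image yields a flagged no-detection result rather
#' than a coordinate.
#'
#' @param map A [contrast_map] (any kind; complex maps are reduced to
#'   magnitude first).
#' @return A list with `detected` (logical), `coords` (length-3 mm vector
#'   or NULL) and `value` (peak magnitude).
#' @export
localize <- function(map) {
  stopifnot(inherits(map, "contrast_map"))
  vals <- if (is.complex(map$values)) Mod(map$values) else map$values
  if (length(vals) == 0L) stop("empty image")
  if (max(vals) <= 0)
    return(list(detected = FALSE, coords = NULL, value = 0))
  i <- which.max(vals)   # which.max returns the first (lowest-index) max
  list(detected = TRUE, coords = as.numeric(map$grid$centers[i, ]),
       value = vals[i])
}

#' Truncation-index sweep
#'
#' L-curve style diagnostic around the default truncation index: for each
#' `nT` the data residual `||L dO - dS||` and the solution norm `||dO||`.
#' The residual is nonincreasing and the solution norm nondecreasing in
#' `nT`.
#'
#' @param svd An [decompose()] result.
#' @param dS Complex differential S-vector (length 55).
#' @param nT_list Integer vector of truncation indices.
#' @param file Optional CSV path to write the table to.
#' @return A data.frame with columns `nT`, `residual`, `solution_norm`.
#' @export
truncation_sweep <- function(svd, dS, nT_list = c(5, 10, 20, 30, 40, 50),
                             file = NULL) {
  stopifnot(inherits(svd, "operator_svd"))
  L <- svd$operator$matrix
  rows <- lapply(nT_list, function(nT) {
    m <- reconstruct(svd, dS, nT = nT)
    data.frame(nT = nT,
               residual = sqrt(sum(Mod(L %*% m$values - dS)^2)),
               solution_norm = sqrt(sum(Mod(m$values)^2)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Heatmap of a map slice
#'
#' Renders one slice of a contrast map with [graphics::image()]; used by
#' the pipeline to emit PNG reconstructions.
#'
#' @param map A [contrast_map].
#' @param plane,at Passed to [slice_map()].
#' @param main Plot title.
#' @return The slice (invisibly).
#' @export
plot_slice <- function(map, plane = "xy", at = NULL, main = NULL) {
  sl <- slice_map(map, plane = plane, at = at)
  graphics::image(sl$a1, sl$a2, sl$values, col = grDevices::hcl.colors(64),
                  xlab = "x (mm)",
                  ylab = if (sl$plane == "xy") "y (mm)" else "z (mm)",
                  main = if (is.null(main))
                    sprintf("|dO| %s slice at %g mm", sl$plane, sl$at)
                  else main,
                  asp = 1, useRaster = TRUE)
  invisible(sl)
}
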