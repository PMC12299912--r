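# Channel bookkeeping: the 10x10 reciprocal S-matrix has 55 independent
# entries. Canonical ordering is the upper triangle, row-major, 1-based:
# (1,1),(1,2),...,(1,10),(2,2),...,(10,10).

#' Canonical channel ordering of the reciprocal 10-port S-matrix
#'
#' @return A 55 x 2 integer matrix of (m, n) antenna index pairs, m <= n.
#' @export
channel_pairs <- function() {
  m <- rep(1:10, times = 10:1)
  n <- unlist(lapply(1:10, function(i) i:10))
  cbind(m = m, n = n)
}

.CHANNEL_ORDER_STRING <- "upper-triangle row-major 1-based (1,1)..(10,10)"

#' S-matrix constructor
#'
#' A complex 10 x 10 single-frequency scattering matrix. Reciprocity
#' `S[m,n] == S[n,m]` is required within `tol` (synthetic data is exactly
#' reciprocal; imported data is checked with tolerance).
#'
#' @param entries Complex 10 x 10 matrix.
#' @param frequency Frequency in Hz.
#' @param tol Reciprocity tolerance (default 1e-8).
#' @return An object of class `smatrix`.
#' @export
smatrix <- function(entries, frequency = 1e9, tol = 1e-8) {
  entries <- as.matrix(entries)
  if (!all(dim(entries) == c(10L, 10L)))
    stop("entries must be a 10 x 10 matrix")
  storage.mode(entries) <- "complex"
  if (max(Mod(entries - t(entries))) > tol)
    stop("S-matrix is not reciprocal within tolerance ", tol)
  structure(list(entries = unname(entries), frequency = frequency),
            class = "smatrix")
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("<smatrix> 10x10 at %.4g GHz, max |S| = %.4g\n",
              x$frequency / 1e9, max(Mod(x$entries))))
  invisible(x)
}

#' Pack a reciprocal S-matrix into its 55 independent channels
#' @param s An [smatrix] (or bare 10 x 10 complex matrix).
#' @return Complex vector of length 55 in canonical channel order.
#' @export
pack_channels <- function(s) {
  e <- if (inherits(s, "smatrix")) s$entries else s
  ch <- channel_pairs()
  e[cbind(ch[, 1], ch[, 2])]
}

#' Unpack 55 channel values into a symmetric 10 x 10 matrix
#' @param values Complex vector of length 55 in canonical channel order.
#' @return Complex 10 x 10 symmetric matrix.
#' @export
unpack_channels <- function(values) {
  if (length(values) != 55L) stop("expected 55 channel values")
  out <- matrix(complex(1), 10, 10)
  ch <- channel_pairs()
  out[cbind(ch[, 1], ch[, 2])] <- values
  out[cbind(ch[, 2], ch[, 1])] <- values
  out
}

#' Scalar point-source field in the lossy background
#'
#' The scalar Green's function `G(R) = exp(-j k_b R) / (4 pi R)` (R in
#' metres) is used as the analytic stand-in for the empty-system fields
#' radiated by each antenna: amplitude falls as 1/R and the lossy
#' background adds exponential attenuation through `Im(k_b) < 0`.
#'
#' @param antenna_position,voxel_position Length-3 positions in mm.
#' @param k_b Complex background wavenumber in rad/m.
#' @return Complex field sample.
#' @export
antenna_field <- function(antenna_position, voxel_position, k_b) {
  R <- sqrt(sum((antenna_position - voxel_position)^2)) * 1e-3
  if (R < 1e-12) stop("coincident antenna and voxel positions (singular)")
  exp(-1i * k_b * R) / (4 * pi * R)
}

#' Assemble the linear Born scattering operator
#'
#' Builds the 55 x N_voxels operator mapping a voxelized contrast map to
#' the 55-channel differential S-vector under the first-order Born
#' approximation. The entry for channel (m, n) and voxel v is
#' `c0 * k_b^2 * G(r_m, r_v) * G(r_n, r_v) * dV` with `dV` the voxel
#' volume in m^3 and `c0` a fixed calibration constant (default 1, so
#' reconstructions are in relative contrast units). Reciprocity holds by
#' construction since G enters symmetrically in m and n.
#'
#' Instead of the analytic point-source fields, externally computed field
#' maps (e.g. full-wave solver exports) can be supplied as a complex
#' 10 x N_voxels matrix via `fields`.
#'
#' @param array An [antenna_array].
#' @param grid An [imaging_grid] masked to the head region.
#' @param background Background [medium].
#' @param c0 Calibration constant (default 1).
#' @param fields Optional 10 x N_voxels complex matrix of per-antenna
#'   field samples overriding the analytic Green's function.
#' @return An object of class `born_operator` with the 55 x N matrix, the
#'   grid, `k_b`, `c0` and the channel ordering.
#' @export
assemble_operator <- function(array, grid, background = head_media()$head,
                              c0 = 1, fields = NULL) {
  stopifnot(inherits(array, "antenna_array"), inherits(grid, "imaging_grid"))
  kb <- background_wavenumber(background, array$frequency)
  N <- n_voxels(grid)
  if (is.null(fields)) {
    # 10 x N distances in metres, vectorized over voxels
    G <- matrix(complex(1), 10, N)
    for (a in 1:10) {
      d <- sqrt((grid$centers[, 1] - array$positions[a, 1])^2 +
                (grid$centers[, 2] - array$positions[a, 2])^2 +
                (grid$centers[, 3] - array$positions[a, 3])^2) * 1e-3
      bad <- d < 1e-9
      if (any(bad)) {
        warning(sum(bad), " voxel(s) coincident with antenna ", a,
                " excluded from the operator")
        d[bad] <- NA_real_
      }
      G[a, ] <- exp(-1i * kb * d) / (4 * pi * d)
    }
  } else {
    G <- as.matrix(fields)
    if (!all(dim(G) == c(10L, N)))
      stop("fields must be a 10 x N_voxels complex matrix")
  }
  dV <- grid$voxel_volume * 1e-9   # mm^3 -> m^3
  ch <- channel_pairs()
  L <- (c0 * kb^2 * dV) * G[ch[, 1], , drop = FALSE] *
    G[ch[, 2], , drop = FALSE]
  L[!is.finite(L)] <- 0 + 0i       # excluded (coincident) voxels
  structure(list(matrix = L, grid = grid, k_b = kb, c0 = c0,
                 frequency = array$frequency, array = array,
                 background = background,
                 channel_order = .CHANNEL_ORDER_STRING),
            class = "born_operator")
}

#' @export
print.born_operator <- function(x, ...) {
  cat(sprintf("<born_operator> 55 x %d, k_b = %.4g%+.4gi rad/m, c0 = %g\n",
              ncol(x$matrix), Re(x$k_b), Im(x$k_b), x$c0))
  invisible(x)
}

#' Forward differential scattering
#'
#' Applies the Born operator to a contrast map: the differential S-vector
#' is the matrix-vector product `L . dO`, linear in the contrast. Only the
#' nonzero support of the map is touched, so compact inclusions are cheap.
#'
#' @param operator A [born_operator].
#' @param contrast A [contrast_map] on the operator's grid.
#' @return Complex differential S-vector of length 55 (canonical channel
#'   order).
#' @export
forward_dS <- function(operator, contrast) {
  stopifnot(inherits(operator, "born_operator"),
            inherits(contrast, "contrast_map"))
  if (!same_grid(operator$grid, contrast$grid))
    stop("contrast map is not defined on the operator's grid")
  idx <- which(Mod(contrast$values) > 0)
  if (length(idx) == 0L) return(complex(55))
  drop(operator$matrix[, idx, drop = FALSE] %*% contrast$values[idx])
}

#' Default stroke-free reference S-matrix
#'
#' The generator's "empty system" (homogeneous head phantom, no stroke)
#' reference. The absolute level is immaterial to differential imaging;
#' a fixed, documented offset is used: reflection coefficients of -0.30
#' on the diagonal and a weak transmission of 0.01 - 0.01i elsewhere.
#'
#' @param frequency Frequency in Hz.
#' @return An [smatrix].
#' @export
default_background_smatrix <- function(frequency = 1e9) {
  e <- matrix(complex(real = 0.01, imaginary = -0.01), 10, 10)
  diag(e) <- -0.30 + 0i
  smatrix(e, frequency = frequency)
}

#' Synthesize a measured S-matrix
#'
#' Runs the differential-measurement model in reverse: the synthetic
#' measurement is the stroke-free reference plus the unpacked differential
#' S-vector plus reciprocity-preserving complex Gaussian measurement
#' noise. The noise standard deviation (per complex entry,
#' `sqrt(E|n|^2)`) is `noise_level * ref_rms`, where `ref_rms` is the RMS
#' of `|dS|` over the reference dataset; by default the RMS of the
#' supplied `dS` itself is used, and dataset builders pass the
#' dataset-wide value so that the noise floor is common to all samples.
#'
#' @param background_S Reference [smatrix].
#' @param dS Complex differential S-vector (length 55) or NULL for a
#'   stroke-free sample.
#' @param noise_level Relative noise level, >= 0.
#' @param seed Optional integer seed for the noise draw.
#' @param ref_rms Reference RMS of `|dS|`; see Details.
#' @return An [smatrix].
#' @export
synthesize_smatrix <- function(background_S, dS = NULL, noise_level = 0,
                               seed = NULL, ref_rms = NULL) {
  stopifnot(inherits(background_S, "smatrix"), noise_level >= 0)
  if (is.null(dS)) dS <- complex(55)
  if (length(dS) != 55L) stop("dS must have length 55")
  if (is.null(ref_rms)) ref_rms <- sqrt(mean(Mod(dS)^2))
  if (!is.null(seed)) set.seed(seed)
  e <- background_S$entries + unpack_channels(dS)
  if (noise_level > 0 && ref_rms > 0) {
    std <- noise_level * ref_rms
    noise <- complex(real = stats::rnorm(55, 0, std / sqrt(2)),
                     imaginary = stats::rnorm(55, 0, std / sqrt(2)))
    e <- e + unpack_channels(noise)   # symmetrized: reciprocity preserved
  }
  smatrix(e, frequency = background_S$frequency)
}
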