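# Physical constants (SI)
.EPS0 <- 8.8542e-12    # vacuum permittivity, F/m
.C0   <- 299792458     # speed of light, m/s

#' Dielectric medium
#'
#' A lossy dielectric characterized by its relative permittivity and
#' conductivity at the operating frequency.
#'
#' @param eps_r Relative permittivity (dimensionless), >= 1.
#' @param sigma Conductivity in S/m, >= 0.
#' @param name Optional label.
#' @return An object of class `medium`.
#' @examples
#' medium(41.40, 1.04, "head")
#' @export
medium <- function(eps_r, sigma, name = NULL) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1L, is.finite(eps_r),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (eps_r < 1) stop("eps_r must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(eps_r = eps_r, sigma = sigma, name = name),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium%s> eps_r = %.4g, sigma = %.4g S/m\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$eps_r, x$sigma))
  invisible(x)
}

#' Reference media of the head phantom experiment
#'
#' Nominal dielectric properties at 1 GHz of the homogeneous liquid head
#' phantom and of the ischemic / hemorrhagic stroke inclusions. Ischemic
#' tissue has a lower permittivity than healthy brain (blood deficit);
#' hemorrhagic tissue a higher one (blood excess), which is what makes the
#' two stroke types distinguishable in the scattered signal.
#'
#' @return Named list of [medium] objects: `head`, `ischemic`, `hemorrhagic`.
#' @export
head_media <- function() {
  list(head        = medium(41.40, 1.04, "head"),
       ischemic    = medium(31.72, 0.92, "ischemic"),
       hemorrhagic = medium(52.73, 2.85, "hemorrhagic"))
}

#' Complex relative permittivity
#'
#' Converts a lossy medium into a single complex relative permittivity
#' under the `e^{+j omega t}` time-harmonic convention:
#' `eps_c = eps_r - j sigma / (2 pi f eps_0)`. With this sign convention
#' lossy media have a negative imaginary part and decaying plane waves
#' carry `Im(k) < 0`.
#'
#' @param medium A [medium].
#' @param frequency Frequency in Hz, > 0.
#' @return A complex scalar.
#' @examples
#' complex_permittivity(medium(41.40, 1.04), 1e9)  # 41.40 - 18.69i
#' @export
complex_permittivity <- function(medium, frequency) {
  stopifnot(inherits(medium, "medium"))
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("frequency must be a positive number (Hz)")
  complex(real = medium$eps_r,
          imaginary = -medium$sigma / (2 * pi * frequency * .EPS0))
}

#' Background wavenumber
#'
#' Complex wavenumber `k_b = (2 pi f / c0) sqrt(eps_c)` of the homogeneous
#' background medium, with the branch chosen so that `Re(k_b) > 0` and
#' `Im(k_b) <= 0` (decaying forward waves under the `e^{+j omega t}`
#' convention).
#'
#' @param background A [medium].
#' @param frequency Frequency in Hz.
#' @return Complex wavenumber in rad/m.
#' @export
background_wavenumber <- function(background, frequency) {
  eps_c <- complex_permittivity(background, frequency)
  k <- (2 * pi * frequency / .C0) * sqrt(eps_c)
  if (Re(k) < 0) k <- -k
  if (Im(k) > 0) k <- Conj(k)
  k
}
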