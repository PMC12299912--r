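#' Stroke scenario (generative ground truth)
#'
#' Describes one measurement scene: the stroke label, the spherical
#' inclusion's center and diameter, and the media involved. For `noStroke`
#' the center and diameter are ignored.
#'
#' @param label One of `"iStroke"`, `"hStroke"`, `"noStroke"`.
#' @param center Sphere center `(x, y, z)` in mm (stroke labels only).
#' @param diameter Sphere diameter in mm, > 0. The phantom campaigns use
#'   20, 30 or 40 mm.
#' @param stroke_medium [medium] of the inclusion; defaults to the
#'   ischemic or hemorrhagic reference medium matching `label`.
#' @param background_medium [medium] of the homogeneous head liquid.
#' @return An object of class `stroke_scenario`.
#' @export
stroke_scenario <- function(label = c("iStroke", "hStroke", "noStroke"),
                            center = NULL, diameter = NULL,
                            stroke_medium = NULL,
                            background_medium = head_media()$head) {
  label <- match.arg(label)
  if (label != "noStroke") {
    if (is.null(center) || length(center) != 3L)
      stop("stroke scenarios need a length-3 center (x, y, z) in mm")
    if (is.null(diameter) || diameter <= 0)
      stop("stroke scenarios need a positive diameter in mm")
    if (is.null(stroke_medium))
      stroke_medium <- switch(label,
                              iStroke = head_media()$ischemic,
                              hStroke = head_media()$hemorrhagic)
  } else {
    center <- NULL; diameter <- NULL; stroke_medium <- NULL
  }
  structure(list(label = label, center = center, diameter = diameter,
                 stroke_medium = stroke_medium,
                 background_medium = background_medium),
            class = "stroke_scenario")
}

#' @export
print.stroke_scenario <- function(x, ...) {
  if (x$label == "noStroke") cat("<stroke_scenario> noStroke\n")
  else cat(sprintf("<stroke_scenario> %s, d = %g mm at (%g, %g, %g) mm\n",
                   x$label, x$diameter,
                   x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Ground-truth dielectric contrast map
#'
#' Discretizes the object function of a scenario on an imaging grid:
#' `dO(v) = (eps_c_stroke - eps_c_bg) / eps_c_bg` for voxels whose center
#' lies inside the sphere, 0 elsewhere. A `noStroke` scenario yields the
#' all-zero map. Ischemic inclusions give a negative real contrast,
#' hemorrhagic a positive one.
#'
#' @param scenario A [stroke_scenario].
#' @param grid An [imaging_grid].
#' @param frequency Frequency in Hz at which permittivities are evaluated.
#' @return A `contrast_map` (complex values per voxel, kind `"complex"`).
#' @export
true_contrast <- function(scenario, grid, frequency = 1e9) {
  stopifnot(inherits(scenario, "stroke_scenario"),
            inherits(grid, "imaging_grid"))
  if (n_voxels(grid) == 0L) stop("empty imaging grid")
  values <- complex(n_voxels(grid))
  if (scenario$label != "noStroke") {
    r <- scenario$diameter / 2
    ctr <- scenario$center
    if (!in_head_oval(ctr[1], ctr[2], margin = r, semi_axes = grid$semi_axes) ||
        (length(grid$zs) > 1L &&
         (ctr[3] - r < min(grid$zs) || ctr[3] + r > max(grid$zs))))
      warning("stroke sphere extends outside the imaged head region; ",
              "contrast truncated")
    d2 <- (grid$centers[, 1] - ctr[1])^2 +
          (grid$centers[, 2] - ctr[2])^2 +
          (grid$centers[, 3] - ctr[3])^2
    inside <- d2 <= r^2
    eb <- complex_permittivity(scenario$background_medium, frequency)
    es <- complex_permittivity(scenario$stroke_medium, frequency)
    values[inside] <- (es - eb) / eb
  }
  contrast_map(values, grid, kind = "complex")
}

#' Contrast map container
#'
#' Per-voxel object-function values on an imaging grid. `kind` records
#' whether the values are the raw complex contrast, its magnitude, or a
#' blurred magnitude image.
#'
#' @param values Complex (or numeric) vector, one entry per grid voxel.
#' @param grid The [imaging_grid] the values live on.
#' @param kind One of `"complex"`, `"magnitude"`, `"blurred-magnitude"`.
#' @return An object of class `contrast_map`.
#' @export
contrast_map <- function(values, grid,
                         kind = c("complex", "magnitude",
                                  "blurred-magnitude")) {
  kind <- match.arg(kind)
  if (length(values) != n_voxels(grid))
    stop("values length does not match the grid voxel count")
  structure(list(values = values, grid = grid, kind = kind),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  nz <- sum(Mod(x$values) > 0)
  cat(sprintf("<contrast_map:%s> %d voxels, %d nonzero, max |dO| = %.4g\n",
              x$kind, length(x$values), nz, max(Mod(x$values), 0)))
  invisible(x)
}
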