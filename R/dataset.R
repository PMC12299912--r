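.DATASET_FORMAT <- "mwstroke-dataset-v1"

#' The 20 fixed stroke positions of the training campaign
#'
#' Twenty distinct XY positions (mm) evenly distributed over the head
#' cross-section, all inside the oval shrunk by the 20 mm maximum stroke
#' radius so every sphere size fits. The exact measured layout is not
#' published; this default places two documented positions, (20, 30) and
#' (10, 10), plus an inner ring of 6 and an outer ring of 12 points on
#' concentric ellipses. Fully configurable by passing your own matrix to
#' the dataset builders.
#'
#' @return A 20 x 2 numeric matrix of (x, y) positions in mm.
#' @export
fixed_positions_m1 <- function() {
  inner <- 2 * pi * (0:5) / 6
  outer <- 2 * pi * (0:11) / 12 + pi / 12
  pos <- rbind(c(20, 30),
               c(10, 10),
               cbind(0.35 * 90 * cos(inner), 0.35 * 70 * sin(inner)),
               cbind(0.70 * 90 * cos(outer), 0.70 * 70 * sin(outer)))
  colnames(pos) <- c("x", "y")
  round(pos, 1)
}

#' Uniform random stroke positions inside the admissible region
#'
#' Rejection sampling of XY positions uniformly over the head oval shrunk
#' by `margin` (mm), so that spheres of radius up to `margin` stay fully
#' inside.
#'
#' @param n Number of positions.
#' @param margin Shrink margin in mm (default 20, the largest stroke
#'   radius).
#' @param semi_axes Oval semi-axes in mm.
#' @return An n x 2 matrix of (x, y) positions in mm.
#' @export
sample_positions <- function(n, margin = 20, semi_axes = c(110, 90)) {
  a <- semi_axes[1] - margin
  b <- semi_axes[2] - margin
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  got <- 0L
  while (got < n) {
    need <- n - got
    x <- stats::runif(2 * need, -a, a)
    y <- stats::runif(2 * need, -b, b)
    ok <- which((x / a)^2 + (y / b)^2 <= 1)
    take <- utils::head(ok, need)
    if (length(take)) {
      out[got + seq_along(take), 1] <- x[take]
      out[got + seq_along(take), 2] <- y[take]
      got <- got + length(take)
    }
  }
  out
}

#' Labeled S-matrix dataset builder
#'
#' Generates one labeled dataset in the style of the phantom measurement
#' campaigns: every stroke position is combined with every diameter and
#' both stroke types, plus `n_nostroke` stroke-free noise replicates. The
#' per-entry noise standard deviation is `noise_level` times the RMS of
#' `|dS|` over all stroke samples of this dataset, so the noise floor is
#' common to all samples and self-normalizing across operator scalings.
#'
#' @param operator A [born_operator] built on the scenario grid.
#' @param positions Matrix of XY stroke positions (mm); spheres are
#'   centered at the antenna-ring plane z.
#' @param diameters Stroke diameters in mm (default 20, 30, 40).
#' @param n_nostroke Number of stroke-free replicates (default 40).
#' @param noise_level Relative measurement-noise level (default 0.01).
#' @param seed Integer seed; the build is bit-reproducible.
#' @param media Named list with `head`, `ischemic`, `hemorrhagic`
#'   [medium] objects (default [head_media()]).
#' @param background_S Reference [smatrix] of the stroke-free system.
#' @param name Dataset tag (e.g. `"M1"`).
#' @param ring_z z of the stroke centers in mm (default 100, the antenna
#'   plane).
#' @return A `labeled_dataset`.
#' @export
build_dataset <- function(operator, positions, diameters = c(20, 30, 40),
                          n_nostroke = 40, noise_level = 0.01, seed = 1,
                          media = head_media(),
                          background_S = default_background_smatrix(),
                          name = "dataset", ring_z = 100) {
  stopifnot(inherits(operator, "born_operator"))
  positions <- as.matrix(positions)
  labels_types <- c(iStroke = "ischemic", hStroke = "hemorrhagic")
  scen <- list(); ds_list <- list(); meta <- list()
  i <- 0L
  for (lab in names(labels_types)) {
    for (p in seq_len(nrow(positions))) {
      for (d in diameters) {
        i <- i + 1L
        sc <- stroke_scenario(lab,
                              center = unname(c(positions[p, 1],
                                                positions[p, 2], ring_z)),
                              diameter = d,
                              stroke_medium = media[[labels_types[[lab]]]],
                              background_medium = media$head)
        scen[[i]] <- sc
        ds_list[[i]] <- forward_dS(operator,
                                   true_contrast(sc, operator$grid,
                                                 operator$frequency))
      }
    }
  }
  ref_rms <- sqrt(mean(unlist(lapply(ds_list, function(v) Mod(v)^2))))
  set.seed(seed)
  samples <- vector("list", i + n_nostroke)
  for (j in seq_len(i)) {
    samples[[j]] <- list(
      s_matrix = synthesize_smatrix(background_S, ds_list[[j]],
                                    noise_level = noise_level,
                                    ref_rms = ref_rms),
      label = scen[[j]]$label,
      center = scen[[j]]$center,
      diameter = scen[[j]]$diameter,
      replicate = 1L)
  }
  for (r in seq_len(n_nostroke)) {
    samples[[i + r]] <- list(
      s_matrix = synthesize_smatrix(background_S, NULL,
                                    noise_level = noise_level,
                                    ref_rms = ref_rms),
      label = "noStroke", center = NULL, diameter = NULL,
      replicate = r)
  }
  structure(list(samples = samples,
                 config = list(name = name,
                               positions = unname(positions),
                               diameters = as.numeric(diameters),
                               n_nostroke = as.integer(n_nostroke),
                               noise_level = as.numeric(noise_level),
                               ref_rms = ref_rms,
                               seed = as.numeric(seed),
                               ring_z = as.numeric(ring_z),
                               frequency = as.numeric(operator$frequency),
                               channel_order = operator$channel_order),
                 name = name),
            class = "labeled_dataset")
}

#' Fixed-position training dataset (M1 analog)
#'
#' 20 fixed positions x 3 sizes x 2 stroke types = 120 stroke samples
#' plus 40 stroke-free replicates: 160 S-matrices with label counts
#' 60 / 60 / 40.
#'
#' @inheritParams build_dataset
#' @param positions XY positions (default [fixed_positions_m1()]).
#' @return A `labeled_dataset` named `"M1"`.
#' @export
build_m1 <- function(operator, noise_level = 0.01, seed = 1,
                     media = head_media(),
                     background_S = default_background_smatrix(),
                     positions = fixed_positions_m1()) {
  build_dataset(operator, positions, noise_level = noise_level, seed = seed,
                media = media, background_S = background_S, name = "M1")
}

#' Random-position test dataset (M2 analog)
#'
#' 30 positions drawn uniformly over the admissible head region (each
#' reused for all 3 sizes) x 2 stroke types = 180 stroke samples plus 40
#' stroke-free replicates: 220 S-matrices with label counts 90 / 90 / 40.
#'
#' @inheritParams build_dataset
#' @param n_positions Number of random positions (default 30).
#' @return A `labeled_dataset` named `"M2"`.
#' @export
build_m2 <- function(operator, noise_level = 0.01, seed = 2,
                     media = head_media(),
                     background_S = default_background_smatrix(),
                     n_positions = 30) {
  set.seed(seed)
  positions <- sample_positions(n_positions, margin = 20,
                                semi_axes = operator$grid$semi_axes)
  build_dataset(operator, positions, noise_level = noise_level,
                seed = seed + 1L, media = media,
                background_S = background_S, name = "M2")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(dataset_labels(x))
  cat(sprintf("<labeled_dataset %s> %d samples (%s)\n", x$name,
              length(x$samples),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$samples)

#' Labels of a dataset
#' @param dataset A `labeled_dataset`.
#' @return Character vector of per-sample labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$samples, `[[`, character(1), "label")
}

#' Save a labeled dataset to JSON
#'
#' Lossless plain-text serialization: S-matrix entries (split into real
#' and imaginary parts at full double precision), labels, scenario
#' metadata, generation config, and the channel-ordering string.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  obj <- list(
    format = .DATASET_FORMAT,
    channel_order = .CHANNEL_ORDER_STRING,
    name = dataset$name,
    config = dataset$config,
    samples = lapply(dataset$samples, function(s) list(
      label = s$label,
      center = s$center,
      diameter = s$diameter,
      replicate = s$replicate,
      frequency = s$s_matrix$frequency,
      s_re = as.vector(Re(s$s_matrix$entries)),
      s_im = as.vector(Im(s$s_matrix$entries)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a labeled dataset from JSON
#'
#' Validates the format version and the channel-ordering string and fails
#' loudly on mismatch.
#'
#' @param path A `.json` file written by [save_dataset()].
#' @return A `labeled_dataset`.
#' @export
load_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, .DATASET_FORMAT))
    stop("not a ", .DATASET_FORMAT, " file: ", path)
  if (!identical(obj$channel_order, .CHANNEL_ORDER_STRING))
    stop("channel-ordering mismatch: file says '", obj$channel_order, "'")
  samples <- lapply(obj$samples, function(s) list(
    s_matrix = smatrix(matrix(complex(real = as.numeric(s$s_re),
                                      imaginary = as.numeric(s$s_im)),
                              10, 10),
                       frequency = as.numeric(s$frequency)),
    label = s$label,
    center = if (is.null(s$center)) NULL else as.numeric(s$center),
    diameter = if (is.null(s$diameter)) NULL else as.numeric(s$diameter),
    replicate = as.integer(s$replicate)))
  cfg <- obj$config
  if (!is.null(cfg$positions))
    cfg$positions <- do.call(rbind, lapply(cfg$positions, as.numeric))
  for (f in c("diameters", "noise_level", "ref_rms", "seed", "ring_z",
              "frequency"))
    cfg[[f]] <- as.numeric(cfg[[f]])
  cfg$n_nostroke <- as.integer(cfg$n_nostroke)
  structure(list(samples = samples, config = cfg, name = obj$name),
            class = "labeled_dataset")
}

#' Export a dataset as per-sample Touchstone files plus a CSV manifest
#'
#' Writes `sample_<i>.s10p` for every sample and a `manifest.csv` with
#' columns `file, label, x, y, z, diameter, replicate`.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
export_touchstone <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$samples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    f <- sprintf("sample_%03d.s10p", i)
    write_touchstone(s$s_matrix, file.path(dir, f))
    rows[[i]] <- data.frame(
      file = f, label = s$label,
      x = if (is.null(s$center)) NA_real_ else s$center[1],
      y = if (is.null(s$center)) NA_real_ else s$center[2],
      z = if (is.null(s$center)) NA_real_ else s$center[3],
      diameter = if (is.null(s$diameter)) NA_real_ else s$diameter,
      replicate = s$replicate)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
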