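# Stage-seed derivation: each pipeline stage draws from its own seed,
# computed from the master seed by a fixed counter scheme
# (master * 100 + stage offset). Adding a new stage gets a new offset and
# never perturbs the draws of earlier stages.
.STAGE_OFFSETS <- c(m1 = 11L, m2 = 12L, train = 21L)

#' Derive a stage seed from the master seed
#' @param master_seed Integer master seed.
#' @param stage One of `"m1"`, `"m2"`, `"train"`.
#' @return Integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(master_seed) * 100 + off) %%
               (.Machine$integer.max - 1))
}

#' Seeded end-to-end run: simulate, image, train, evaluate
#'
#' Reproduces the full workflow on synthetic data: build the Born
#' operator on a 3D slab grid, generate the fixed-position (M1 analog)
#' and random-position (M2 analog) datasets, cache the operator SVD,
#' reconstruct a set of reference scenes (both stroke types at a shallow
#' and a deep position, 20 and 40 mm, plus one out-of-plane case) to PNG,
#' train the PCA + SVM classifier on the M1 analog and evaluate it on the
#' M2 analog. All randomness derives from the master seed; two runs with
#' the same seed produce identical evaluation JSON.
#'
#' @param out_dir Output directory (created).
#' @param master_seed Integer master seed (default 1000).
#' @param noise_level Relative measurement-noise level (default 0.01).
#' @param spacing Grid pitch in mm (default 5).
#' @param zlim Grid slab z range in mm (default c(40, 160)).
#' @param nT Truncation index for the reference reconstructions
#'   (default 50).
#' @param n_components PCA dimensionality (default 20).
#' @param k CV folds (default 5).
#' @param write_images Emit PNG reconstructions (default TRUE).
#' @param save_datasets Write the M1/M2 JSON datasets (default TRUE).
#' @return Invisibly, a list with the datasets, the classifier, the
#'   [evaluate()] report and the output paths.
#' @export
run_pipeline <- function(out_dir, master_seed = 1000, noise_level = 0.01,
                         spacing = 5, zlim = c(40, 160), nT = 50,
                         n_components = 20, k = 5, write_images = TRUE,
                         save_datasets = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(master_seed = master_seed, noise_level = noise_level,
              spacing = spacing, zlim = zlim, nT = nT,
              n_components = n_components, k = k)
  message("[pipeline] assembling operator")
  grid <- imaging_grid(spacing = spacing, z = zlim)
  op <- assemble_operator(default_array(), grid)

  message("[pipeline] generating datasets")
  m1 <- build_m1(op, noise_level = noise_level,
                 seed = stage_seed(master_seed, "m1"))
  m2 <- build_m2(op, noise_level = noise_level,
                 seed = stage_seed(master_seed, "m2"))
  paths <- list()
  if (save_datasets) {
    paths$m1 <- file.path(out_dir, "m1.json")
    paths$m2 <- file.path(out_dir, "m2.json")
    save_dataset(m1, paths$m1)
    save_dataset(m2, paths$m2)
  }

  if (write_images) {
    message("[pipeline] reference reconstructions")
    sv <- decompose(op)
    scenes <- list(
      list(tag = "iStroke_20mm_shallow", lab = "iStroke", d = 20,
           c = c(20, 30, 100)),
      list(tag = "hStroke_20mm_deep", lab = "hStroke", d = 20,
           c = c(10, 10, 100)),
      list(tag = "iStroke_40mm_shallow", lab = "iStroke", d = 40,
           c = c(20, 30, 100)),
      list(tag = "hStroke_40mm_shallow", lab = "hStroke", d = 40,
           c = c(20, 30, 100)),
      list(tag = "iStroke_40mm_offplane", lab = "iStroke", d = 40,
           c = c(20, 30, 70)))
    for (sc in scenes) {
      scen <- stroke_scenario(sc$lab, center = sc$c, diameter = sc$d)
      dS <- forward_dS(op, true_contrast(scen, grid, op$frequency))
      img <- blur_map(reconstruct(sv, dS, nT = nT))
      png_path <- file.path(out_dir, paste0(sc$tag, ".png"))
      grDevices::png(png_path, width = 700, height = 600)
      plot_slice(img, plane = "xy", at = sc$c[3],
                 main = sprintf("%s %g mm at (%g, %g, %g)",
                                sc$lab, sc$d, sc$c[1], sc$c[2], sc$c[3]))
      grDevices::dev.off()
      if (sc$c[3] != 100) {   # out-of-plane: add the XZ view
        png_path2 <- file.path(out_dir, paste0(sc$tag, "_xz.png"))
        grDevices::png(png_path2, width = 700, height = 600)
        plot_slice(img, plane = "xz", at = sc$c[2],
                   main = sprintf("%s %g mm, XZ view", sc$lab, sc$d))
        grDevices::dev.off()
      }
    }
  }

  message("[pipeline] training classifier")
  model <- fit_classifier(m1, n_components = n_components, k = k,
                          seed = stage_seed(master_seed, "train"))
  report <- evaluate(model, m2)

  paths$report <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(
    list(config = cfg,
         selected = list(kernel_scale = model$svm$kernel_scale,
                         box_constraint = model$svm$cost,
                         cv_accuracy = model$svm$cv_accuracy),
         classes = .CLASSES,
         confusion = lapply(seq_len(nrow(report$confusion)),
                            function(i) unname(report$confusion[i, ])),
         accuracy = report$accuracy,
         recall = as.list(report$recall),
         kappa = report$kappa),
    paths$report, auto_unbox = TRUE, digits = I(17))
  message(sprintf("[pipeline] accuracy %.3f, kappa %.3f",
                  report$accuracy, report$kappa))
  invisible(list(m1 = m1, m2 = m2, model = model, report = report,
                 operator = op, paths = paths, config = cfg))
}
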