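#' Parameters for procedural lung-like image rendering
#'
#' Controls the synthetic grayscale rasters that stand in for chest-image
#' slices: two elliptical "lung fields" on a brighter thoracic background,
#' low-frequency parenchymal texture, additive pixel noise, and bright
#' Gaussian lesion blobs whose count and intensity grow with disease stage.
#' Lesion intensity must be monotone non-decreasing over
#' none < mild < moderate < severe, which is what makes image texture
#' informative about stage.
#'
#' @param height,width Raster size in pixels (minimum 16).
#' @param lesion_count Named integer blob counts per stage.
#' @param lesion_intensity Named peak blob intensities per stage (gray units
#'   on the `[0, 1]` scale); monotone non-decreasing in severity.
#' @param lesion_sigma Blob radius (pixels) as a fraction of image height.
#' @param background Thoracic background brightness in `[0, 1]`.
#' @param texture_scale Amplitude of the smoothed parenchymal texture.
#' @param noise_sd Per-pixel Gaussian noise sd.
#' @return An object of class `image_params`.
#' @export
image_params <- function(height = 64L, width = 64L,
                         lesion_count = c(none = 0L, mild = 2L, moderate = 4L, severe = 7L),
                         lesion_intensity = c(none = 0, mild = 0.18, moderate = 0.30, severe = 0.45),
                         lesion_sigma = 0.06,
                         background = 0.35,
                         texture_scale = 0.06,
                         noise_sd = 0.02) {
  p <- list(height = as.integer(height), width = as.integer(width),
            lesion_count = lesion_count, lesion_intensity = lesion_intensity,
            lesion_sigma = lesion_sigma, background = background,
            texture_scale = texture_scale, noise_sd = noise_sd)
  class(p) <- "image_params"
  validate_image_params(p)
  p
}

validate_image_params <- function(p) {
  if (p$height < 16L || p$width < 16L)
    stop("image size must be at least 16x16", call. = FALSE)
  for (nm in c("lesion_count", "lesion_intensity")) {
    if (!all(stage_levels %in% names(p[[nm]])))
      stop("`", nm, "` must be named over none/mild/moderate/severe",
           call. = FALSE)
  }
  li <- p$lesion_intensity[stage_levels]
  if (any(diff(li) < 0))
    stop("`lesion_intensity` must be monotone non-decreasing in stage severity",
         call. = FALSE)
  if (any(p$lesion_count < 0)) stop("`lesion_count` must be non-negative", call. = FALSE)
  if (p$noise_sd < 0 || p$texture_scale < 0)
    stop("noise_sd and texture_scale must be non-negative", call. = FALSE)
  invisible(p)
}

# 3x3 box blur with edge replication; cheap low-pass for texture synthesis.
box_blur <- function(m, passes = 2L) {
  h <- nrow(m); w <- ncol(m)
  for (k in seq_len(passes)) {
    up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
    dn <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
    m <- (up + m + dn) / 3
    lf <- m[, c(1, seq_len(w - 1)), drop = FALSE]
    rt <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
    m <- (lf + m + rt) / 3
  }
  m
}

#' Render one synthetic lung-like image
#'
#' Deterministically renders the grayscale raster for a patient record. The
#' effective stage used for lesion placement is the record's stage unless its
#' `image_informative` flag is `FALSE`, in which case the image is rendered
#' lesion-free (stage `"none"`), severing the image-label association for
#' that patient.
#'
#' @param record A single cohort row (or any list with `stage` and optionally
#'   `image_informative`).
#' @param params An [image_params()] object.
#' @param seed Integer seed; the same record/params/seed triple renders an
#'   identical pixel array.
#' @return A numeric matrix (rows x columns, origin top-left) with values in
#'   `[0, 1]`.
#' @export
render_image <- function(record, params = image_params(), seed = 1L) {
  validate_image_params(params)
  set.seed(as.integer(seed))
  h <- params$height; w <- params$width

  stage <- as.character(record$stage)
  if (length(stage) != 1L || !stage %in% stage_levels)
    stop("record$stage must be one of ", paste(stage_levels, collapse = "/"),
         call. = FALSE)
  informative <- if (!is.null(record$image_informative)) {
    isTRUE(record$image_informative)
  } else TRUE
  eff_stage <- if (informative) stage else "none"

  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  img <- matrix(params$background, h, w)
  # two elliptical lung fields, darker than the chest wall
  for (cxf in c(0.32, 0.68)) {
    cx <- cxf * w; cy <- 0.52 * h
    ell <- ((xx - cx) / (0.20 * w))^2 + ((yy - cy) / (0.36 * h))^2
    img[ell <= 1] <- img[ell <= 1] - 0.22
  }
  img <- img + params$texture_scale *
    box_blur(matrix(stats::rnorm(h * w), h, w), passes = 3L)

  n_lesion <- params$lesion_count[[eff_stage]]
  amp <- params$lesion_intensity[[eff_stage]]
  if (n_lesion > 0 && amp > 0) {
    sg <- params$lesion_sigma * h
    for (k in seq_len(n_lesion)) {
      side <- if (stats::runif(1) < 0.5) 0.32 else 0.68
      cx <- side * w + stats::rnorm(1, 0, 0.08 * w)
      cy <- 0.52 * h + stats::rnorm(1, 0, 0.22 * h)
      img <- img + amp * exp(-(((xx - cx)^2 + (yy - cy)^2) / (2 * sg^2)))
    }
  }
  img <- img + stats::rnorm(h * w, 0, params$noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Render all cohort images to PNG files
#'
#' Writes one 8-bit grayscale PNG per patient under `dir` and fills the
#' cohort's `image_path` column. Per-patient render seeds are derived from
#' `base_seed` and the patient index, so a cohort re-rendered with the same
#' seed is file-identical.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @param params An [image_params()] object.
#' @param base_seed Integer seed from which per-patient seeds are derived.
#' @return The cohort with `image_path` filled.
#' @export
render_cohort_images <- function(cohort, dir, params = image_params(),
                                 base_seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$id, ".png"))
  for (i in seq_len(nrow(cohort))) {
    img <- render_image(cohort[i, ], params, seed = patient_seed(base_seed, i))
    png::writePNG(img, paths[i])
  }
  cohort$image_path <- paths
  cohort
}

# Per-patient seed derived from a base seed; kept below 2^31.
patient_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 7919 + i * 104729) %% 2147483629)
}

#' Load cohort images as a list of matrices
#'
#' Reads rasters from `image_path` where present (8- or 16-bit grayscale PNG;
#' RGB inputs are averaged to gray) and renders in memory otherwise, using the
#' same per-patient seed derivation as [render_cohort_images()].
#'
#' @inheritParams render_cohort_images
#' @return A list of numeric matrices in `[0, 1]`, one per cohort row.
#' @export
cohort_images <- function(cohort, params = image_params(), base_seed = 1L) {
  lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort$image_path[i]
    if (!is.na(p) && file.exists(p)) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      img
    } else {
      render_image(cohort[i, ], params, seed = patient_seed(base_seed, i))
    }
  })
}
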