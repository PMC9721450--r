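#' Phantom dataset configuration
#'
#' Describes a synthetic mammogram cohort: each patient contributes two views
#' (CC and MLO) of one breast carrying a single elliptical mass. Class signal
#' is injected as extra, zero-mean texture noise whose standard deviation
#' scales with `core_effect` inside the mass and with `rim_effect` in an
#' annulus of width `rim_width_mm` just outside it, so that malignant lesions
#' differ from benign ones in local intensity variance (and hence in
#' GLCM-family texture) rather than only in mean brightness.
#'
#' The injected per-pixel variance margin between classes is
#' `(effect * noise_sd)^2` in the corresponding compartment; see
#' [phantom_variance_margin()].
#'
#' @param n_patients number of patients (2 images each)
#' @param malignant_fraction fraction of patients with a malignant lesion
#' @param image_size side of the square image in pixels
#' @param pixel_spacing_mm physical pixel size, mm/pixel (isotropic)
#' @param mass_radius_range_mm range the mean mass radius is drawn from (mm)
#' @param core_effect dimensionless texture-contrast shift inside the mass
#' @param rim_effect same, applied in the peritumoral annulus
#' @param rim_width_mm width of the annulus carrying `rim_effect` (mm)
#' @param noise_sd base texture noise standard deviation (intensity units)
#' @param pectoral_wedge add a pectoral-muscle wedge to MLO views
#' @param seed integer seed; identical seeds give bit-identical datasets
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(n_patients = 40, malignant_fraction = 0.5,
                           image_size = 192, pixel_spacing_mm = 0.25,
                           mass_radius_range_mm = c(3, 7),
                           core_effect = 0, rim_effect = 0, rim_width_mm = 2,
                           noise_sd = 20, pectoral_wedge = TRUE, seed = 1) {
  stopifnot(n_patients >= 1, image_size >= 32)
  if (malignant_fraction < 0 || malignant_fraction > 1)
    stop("malignant_fraction must be in [0, 1]", call. = FALSE)
  if (any(mass_radius_range_mm <= 0) || diff(range(mass_radius_range_mm)) < 0)
    stop("mass_radius_range_mm must be positive (min, max)", call. = FALSE)
  if (rim_width_mm <= 0) stop("rim_width_mm must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    malignant_fraction = malignant_fraction,
    image_size = as.integer(image_size),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    mass_radius_range_mm = sort(as.numeric(mass_radius_range_mm)),
    core_effect = core_effect, rim_effect = rim_effect,
    rim_width_mm = rim_width_mm, noise_sd = noise_sd,
    pectoral_wedge = isTRUE(pectoral_wedge), seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Injected between-class variance margin
#'
#' The malignant class receives extra independent noise of standard deviation
#' `effect * noise_sd` in the given compartment, so the expected difference in
#' per-pixel intensity variance between malignant and benign lesions is
#' `(effect * noise_sd)^2`.
#'
#' @param config a [phantom_config()]
#' @param where `"core"` or `"rim"`
#' @return variance difference in squared intensity units
#' @export
phantom_variance_margin <- function(config, where = c("rim", "core")) {
  where <- match.arg(where)
  eff <- if (where == "rim") config$rim_effect else config$core_effect
  (eff * config$noise_sd)^2
}

# breast support: half-ellipse anchored at the image's left edge
breast_support <- function(n) {
  r <- matrix(seq_len(n), n, n)
  c_ <- matrix(seq_len(n), n, n, byrow = TRUE)
  cy <- (n + 1) / 2
  ry <- 0.46 * n
  rx <- 0.82 * n
  ((r - cy) / ry)^2 + (c_ / rx)^2 <= 1
}

pectoral_support <- function(n) {
  r <- matrix(seq_len(n), n, n)
  c_ <- matrix(seq_len(n), n, n, byrow = TRUE)
  r / (0.38 * n) + c_ / (0.30 * n) < 1
}

# smooth low-frequency parenchyma field: coarse gaussian grid upsampled
smooth_field <- function(n, coarse = 12, amplitude = 1) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  up <- EBImage::resize(g, w = n, h = n)
  amplitude * as.matrix(up)
}

ellipse_mask <- function(n, center, semi_axes, theta) {
  r <- matrix(seq_len(n), n, n) - center[1]
  c_ <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  u <- cos(theta) * r + sin(theta) * c_
  v <- -sin(theta) * r + cos(theta) * c_
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Generate a synthetic mammogram dataset
#'
#' Produces, for every patient, a CC and an MLO view: a bright breast
#' half-ellipse with smooth parenchyma texture on a near-zero noisy
#' background, a pectoral wedge on MLO views (when configured), and one
#' elliptical mass placed fully inside the breast with its peritumoral
#' annulus. Ground-truth lesion masks are returned alongside the images.
#'
#' @param config a [phantom_config()]
#' @return an object of class `phantom_dataset`: a list with `images` (each a
#'   `mammogram_image` carrying `pixels`, `spacing_mm`, `patient_id`, `view`,
#'   `label`), `masks` (binary matrices aligned to the images), and `meta`
#'   (one data.frame row per image)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  sp <- config$pixel_spacing_mm

  n_mal <- round(config$malignant_fraction * config$n_patients)
  with_seed(config$seed, {
    labels <- sample(rep(c("malignant", "benign"),
                         c(n_mal, config$n_patients - n_mal)))
    breast <- breast_support(n)
    pect <- pectoral_support(n)
    # eligible mass centers must keep mass + margin inside the breast and
    # clear of the pectoral wedge; distance maps give both tests in O(1)
    dist_in <- as.matrix(EBImage::distmap(matrix(as.numeric(breast), n, n)))
    dist_pect <- as.matrix(EBImage::distmap(matrix(as.numeric(!pect), n, n)))
    images <- vector("list", 2L * config$n_patients)
    masks <- vector("list", 2L * config$n_patients)
    meta <- vector("list", 2L * config$n_patients)
    k <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", p)
      label <- labels[p]
      radius_mm <- stats::runif(1, config$mass_radius_range_mm[1],
                                config$mass_radius_range_mm[2])
      for (view in c("CC", "MLO")) {
        wedge <- view == "MLO" && config$pectoral_wedge
        axes_mm <- radius_mm * c(stats::runif(1, 0.8, 1.2),
                                 stats::runif(1, 0.8, 1.2))
        margin_px <- (max(axes_mm) + 6) / sp
        ok <- dist_in > margin_px & dist_pect > margin_px
        if (!any(ok))
          stop(sprintf(
            "cannot place a mass of radius %.1f mm (+ 6 mm margin) inside the breast at image size %d px / %.2f mm per px",
            radius_mm, n, sp), call. = FALSE)
        idx <- which(ok)
        center_i <- idx[sample.int(length(idx), 1)]
        center <- c((center_i - 1) %% n + 1, (center_i - 1) %/% n + 1)
        theta <- stats::runif(1, 0, pi)
        mass <- ellipse_mask(n, center, axes_mm / sp, theta)
        # exact-distance annulus so the injected rim signal occupies precisely
        # the peritumoral band the region module will reconstruct
        rim <- (dilate_mask(mass, config$rim_width_mm, c(sp, sp)) & !mass) & breast

        img <- matrix(pmax(0, stats::rnorm(n * n, 10, config$noise_sd / 4)), n, n)
        body_tex <- smooth_field(n, coarse = 12, amplitude = 40) +
          matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
        img[breast] <- 400 + body_tex[breast]
        if (wedge) img[pect] <- 550 + body_tex[pect]
        img[mass] <- img[mass] + 150
        if (label == "malignant") {
          if (config$core_effect > 0)
            img[mass] <- img[mass] +
              stats::rnorm(sum(mass), 0, config$core_effect * config$noise_sd)
          if (config$rim_effect > 0)
            img[rim] <- img[rim] +
              stats::rnorm(sum(rim), 0, config$rim_effect * config$noise_sd)
        }
        img <- pmax(img, 0)

        k <- k + 1L
        images[[k]] <- structure(list(
          pixels = img, spacing_mm = c(sp, sp),
          patient_id = pid, view = view, label = label
        ), class = "mammogram_image")
        masks[[k]] <- mass
        meta[[k]] <- data.frame(
          patient_id = pid, view = view, label = label,
          spacing_mm = sp, mass_radius_mm = radius_mm,
          mass_size_mm = 2 * radius_mm, stringsAsFactors = FALSE)
      }
    }
    structure(list(images = images, masks = masks,
                   meta = do.call(rbind, meta), config = config),
              class = "phantom_dataset")
  })
}

#' @exportS3Method base::print
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %d patients, %d images (%d malignant patients)\n",
              x$config$n_patients, length(x$images),
              sum(x$meta$label[x$meta$view == "CC"] == "malignant")))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Images are written as 16-bit TIFF, masks as 8-bit PNG (0/255), and the
#' per-image metadata (patient, view, label, spacing, file paths) as CSV.
#'
#' @param dataset a `phantom_dataset`
#' @param dir output directory (created if needed)
#' @return invisibly, the metadata data.frame including file paths
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset$meta
  meta$image_path <- meta$mask_path <- NA_character_
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    stem <- sprintf("%s_%s", im$patient_id, im$view)
    ip <- file.path(dir, paste0(stem, ".tiff"))
    mp <- file.path(dir, paste0(stem, "_mask.png"))
    tiff::writeTIFF(im$pixels / 65535, ip, bits.per.sample = 16L)
    png::writePNG(matrix(as.numeric(dataset$masks[[i]]), nrow(dataset$masks[[i]])), mp)
    meta$image_path[i] <- ip
    meta$mask_path[i] <- mp
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir directory containing `metadata.csv` and the image/mask files
#' @return a `phantom_dataset`-shaped list (without the generating config)
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  images <- vector("list", nrow(meta))
  masks <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    px <- tiff::readTIFF(meta$image_path[i]) * 65535
    images[[i]] <- structure(list(
      pixels = px, spacing_mm = rep(meta$spacing_mm[i], 2),
      patient_id = meta$patient_id[i], view = meta$view[i],
      label = meta$label[i]), class = "mammogram_image")
    masks[[i]] <- png::readPNG(meta$mask_path[i]) > 0.5
  }
  structure(list(images = images, masks = masks, meta = meta, config = NULL),
            class = "phantom_dataset")
}
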