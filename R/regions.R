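#' Body mask by Otsu thresholding
#'
#' Separates the imaged body (breast plus pectoral muscle) from the dark air
#' background: pixels above the Otsu threshold are kept, connected components
#' smaller than `min_area_fraction` of the image are discarded as specks, and
#' holes are filled. The pectoral muscle is deliberately retained; only
#' air/background is removed.
#'
#' @param image a `mammogram_image` or a numeric matrix
#' @param min_area_fraction components smaller than this fraction of the
#'   image area are dropped (default 0.5\%)
#' @return a logical matrix marking the body support
#' @export
compute_body_mask <- function(image, min_area_fraction = 0.005) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  stopifnot(is.matrix(px))
  rng <- range(px)
  if (diff(rng) == 0)
    stop("Otsu thresholding failed: image is constant (needs >= 2 distinct intensities)",
         call. = FALSE)
  norm <- (px - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  mask <- norm > th
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(px)))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_area_fraction * length(px))
  mask <- matrix(as.integer(lab) %in% keep & as.integer(lab) > 0, nrow(px))
  mask <- as.matrix(EBImage::fillHull(matrix(as.numeric(mask), nrow(px)))) > 0
  mask
}

#' Dilate a mask by a physical distance
#'
#' Returns every pixel whose Euclidean distance (in mm, honouring possibly
#' anisotropic pixel spacing) to the input mask is at most `distance_mm`.
#' Implemented as morphological dilation with an elliptical structuring
#' element whose support is exactly the set of pixel offsets within
#' `distance_mm`, which is equivalent to thresholding the Euclidean distance
#' transform. `distance_mm = 0` returns the input unchanged.
#'
#' @param mask logical matrix
#' @param distance_mm dilation distance in mm (>= 0)
#' @param spacing_mm pixel spacing, one value or (row, col), mm/pixel
#' @return logical matrix of the same shape
#' @export
dilate_mask <- function(mask, distance_mm, spacing_mm) {
  mask <- as_binary_matrix(mask)
  if (!is.numeric(distance_mm) || length(distance_mm) != 1 || distance_mm < 0)
    stop("distance_mm must be a single value >= 0", call. = FALSE)
  spacing_mm <- check_spacing(spacing_mm)
  if (distance_mm == 0 || !any(mask)) return(mask)
  kr <- floor(distance_mm / spacing_mm[1])
  kc <- floor(distance_mm / spacing_mm[2])
  dr <- ((-kr):kr) * spacing_mm[1]
  dc <- ((-kc):kc) * spacing_mm[2]
  kern <- outer(dr^2, dc^2, `+`) <= distance_mm^2 + 1e-9
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), kern * 1)
  as.matrix(out) > 0
}

#' Build tumoral, peritumoral-ring and combined regions
#'
#' For each physical distance d the ring is the tumor dilated by d, minus the
#' tumor, intersected with the body mask (peritumoral pixels falling on air
#' background are removed); the combined region is the body-clipped dilation
#' united with the tumor, so radiologist-drawn tumor pixels are always kept
#' even where the automatic body mask disagrees.
#'
#' @param image a `mammogram_image` (used for the body mask and spacing)
#' @param tumor logical lesion mask aligned to the image
#' @param distances_mm vector of ring distances in mm (default 1:5)
#' @param body optional precomputed body mask
#' @return an object of class `region_set` with elements `tumor`, `body`,
#'   `distances_mm`, `rings`, `combineds` (named lists, one mask per
#'   distance) and `empty` (logical: rings that vanished after body clipping)
#' @export
build_region_set <- function(image, tumor, distances_mm = 1:5, body = NULL) {
  stopifnot(inherits(image, "mammogram_image"))
  tumor <- as_binary_matrix(tumor, "tumor mask")
  if (!any(tumor)) stop("tumor mask is empty", call. = FALSE)
  if (!all(dim(tumor) == dim(image$pixels)))
    stop("tumor mask and image have different shapes", call. = FALSE)
  if (is.null(body)) body <- compute_body_mask(image)
  spacing <- check_spacing(image$spacing_mm)
  dn <- as.character(distances_mm)
  rings <- combineds <- stats::setNames(vector("list", length(distances_mm)), dn)
  empty <- stats::setNames(logical(length(distances_mm)), dn)
  for (i in seq_along(distances_mm)) {
    d <- distances_mm[i]
    dil <- dilate_mask(tumor, d, spacing)
    ring <- (dil & !tumor) & body
    combined <- (dil & body) | tumor
    if (!any(ring)) {
      warning(sprintf("peritumoral ring at %g mm is empty after body clipping", d),
              call. = FALSE)
      empty[i] <- TRUE
    }
    rings[[i]] <- ring
    combineds[[i]] <- combined
  }
  structure(list(tumor = tumor, body = body,
                 distances_mm = as.numeric(distances_mm),
                 rings = rings, combineds = combineds, empty = empty),
            class = "region_set")
}

#' @exportS3Method base::print
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: tumor %d px, body %d px, distances %s mm\n",
              sum(x$tumor), sum(x$body),
              paste(x$distances_mm, collapse = ", ")))
  invisible(x)
}

#' Write a region set to disk
#'
#' One 8-bit PNG (0/255) per (region kind, distance) plus the tumor and body
#' masks, with a manifest CSV naming each file.
#'
#' @param regions a `region_set`
#' @param dir output directory
#' @param lesion_id identifier used in file names and the manifest
#' @return invisibly, the manifest data.frame
#' @export
write_region_set <- function(regions, dir, lesion_id = "lesion") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  put <- function(mask, kind, distance) {
    fn <- file.path(dir, sprintf("%s_%s%s.png", lesion_id, kind,
                                 if (is.na(distance)) "" else paste0("_", distance, "mm")))
    png::writePNG(matrix(as.numeric(mask), nrow(mask)), fn)
    rows[[length(rows) + 1L]] <<- data.frame(
      lesion_id = lesion_id, region = kind, distance_mm = distance,
      path = fn, stringsAsFactors = FALSE)
  }
  put(regions$tumor, "tumoral", NA)
  put(regions$body, "body", NA)
  for (i in seq_along(regions$distances_mm)) {
    put(regions$rings[[i]], "peritumoral", regions$distances_mm[i])
    put(regions$combineds[[i]], "combined", regions$distances_mm[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, paste0(lesion_id, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
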