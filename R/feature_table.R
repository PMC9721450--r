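#' Extract the full feature table of a dataset
#'
#' Builds the region set of every image and extracts the complete radiomics
#' vector for the tumoral region and for the peritumoral ring and combined
#' region at every distance. One row per (lesion, view, region, distance);
#' rings that are empty after body clipping are skipped with their `empty`
#' flag respected.
#'
#' @param dataset a `phantom_dataset` (or compatible list of images/masks/meta)
#' @param distances_mm ring distances in mm (default 1:5)
#' @param config a [feature_config()]
#' @param region_sets optional precomputed list of `region_set`s (one per image)
#' @return a data.frame: metadata columns (`patient_id`, `view`, `label`,
#'   `region`, `distance_mm`) followed by feature columns
#' @export
extract_feature_table <- function(dataset, distances_mm = 1:5,
                                  config = feature_config(),
                                  region_sets = NULL) {
  if (is.null(region_sets)) {
    region_sets <- lapply(seq_along(dataset$images), function(i)
      build_region_set(dataset$images[[i]], dataset$masks[[i]], distances_mm))
  }
  rows <- list()
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    rs <- region_sets[[i]]
    add <- function(mask, region, distance) {
      fv <- extract_all(im, mask, config)
      rows[[length(rows) + 1L]] <<- cbind(
        data.frame(patient_id = im$patient_id, view = im$view,
                   label = im$label, region = region, distance_mm = distance,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(fv), check.names = FALSE))
    }
    add(rs$tumor, "tumoral", NA_real_)
    for (d in seq_along(rs$distances_mm)) {
      if (!rs$empty[d]) add(rs$rings[[d]], "peritumoral", rs$distances_mm[d])
      add(rs$combineds[[d]], "combined", rs$distances_mm[d])
    }
  }
  do.call(rbind, rows)
}

feature_columns <- function(table) {
  setdiff(colnames(table),
          c("patient_id", "view", "label", "region", "distance_mm"))
}

#' Write a feature table with a JSON metadata sidecar
#'
#' @param table data.frame from [extract_feature_table()]
#' @param path CSV output path
#' @param meta optional named list recorded in `<path>.json` (seed, config
#'   hash, provenance)
#' @return the path, invisibly
#' @export
write_feature_table <- function(table, path, meta = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
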