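#' Study configuration
#'
#' Bundles all stage configurations with an output directory and a global
#' seed. The configuration round-trips through YAML
#' ([save_study_config()] / [load_study_config()]) and its [config_hash()]
#' is stamped into every stage output so downstream stages can verify
#' lineage.
#'
#' @param phantom a [phantom_config()]
#' @param features a [feature_config()]
#' @param selection a [selection_config()]
#' @param cnn a [cnn_config()]
#' @param penalty_grid lasso penalties searched on validation folds
#' @param distances_mm ring distances of the region models
#' @param k cross-validation folds
#' @param aggregate patient-level aggregation rule
#' @param outdir output directory for all stages
#' @param seed global seed (propagated to phantom/CV/CNN unless they differ)
#' @param log_level `"info"` or `"quiet"`
#' @return an object of class `study_config`
#' @export
study_config <- function(phantom = phantom_config(), features = feature_config(),
                         selection = selection_config(), cnn = tiny_cnn_config(),
                         penalty_grid = c(0.01, 0.1, 1, 10),
                         distances_mm = 1:5, k = 5, aggregate = "max",
                         outdir = "perirad_out", seed = 1,
                         log_level = "info") {
  phantom$seed <- phantom$seed %||% seed
  structure(list(phantom = phantom, features = features,
                 selection = selection, cnn = cnn,
                 penalty_grid = penalty_grid,
                 distances_mm = as.numeric(distances_mm),
                 k = as.integer(k), aggregate = aggregate,
                 outdir = outdir, seed = as.integer(seed),
                 log_level = log_level),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`
#' @param path YAML file path
#' @export
save_study_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"), path)
  invisible(path)
}

#' @rdname study_config
#' @export
load_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vec <- function(x) if (is.list(x)) unlist(x) else x
  study_config(
    phantom = do.call(phantom_config, lapply(raw$phantom, vec)),
    features = do.call(feature_config, lapply(raw$features, vec)),
    selection = do.call(selection_config, lapply(raw$selection, vec)),
    cnn = do.call(cnn_config, lapply(raw$cnn, vec)),
    penalty_grid = vec(raw$penalty_grid),
    distances_mm = vec(raw$distances_mm),
    k = raw$k, aggregate = raw$aggregate, outdir = raw$outdir,
    seed = raw$seed, log_level = raw$log_level %||% "info")
}

study_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[perirad %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

provenance_path <- function(config, stage)
  file.path(config$outdir, sprintf("%s.provenance.json", stage))

write_provenance <- function(config, stage, extra = list()) {
  obj <- c(list(stage = stage, config_hash = config_hash(unclass(config)),
                seed = config$seed, created = format(Sys.time())), extra)
  jsonlite::write_json(obj, provenance_path(config, stage),
                       auto_unbox = TRUE, digits = NA)
}

require_stage <- function(config, stage) {
  p <- provenance_path(config, stage)
  if (!file.exists(p))
    stop(sprintf("stage '%s' has not been run in %s; run it first",
                 stage, config$outdir), call. = FALSE)
  prov <- jsonlite::read_json(p)
  if (!identical(prov$config_hash, config_hash(unclass(config))))
    stop(sprintf("stage '%s' was produced under a different configuration (hash %s != %s)",
                 stage, prov$config_hash, config_hash(unclass(config))),
         call. = FALSE)
  invisible(prov)
}

#' Run the study stages
#'
#' File-based pipeline stages over a `study_config`: each writes its outputs
#' plus a provenance JSON (stage, config hash, seed) under `config$outdir`,
#' and each later stage refuses to run if its prerequisite is missing or was
#' produced under a different configuration.
#'
#' @param config a [study_config()]
#' @return the stage's principal object, invisibly where large
#' @export
study_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  ds <- generate_dataset(config$phantom)
  write_dataset(ds, file.path(config$outdir, "dataset"))
  write_provenance(config, "simulate",
                   list(n_images = length(ds$images),
                        elapsed_s = as.numeric(Sys.time() - t0, units = "secs")))
  study_log(config, "simulate: %d images written", length(ds$images))
  invisible(ds)
}

#' @rdname study_simulate
#' @export
study_extract <- function(config) {
  require_stage(config, "simulate")
  t0 <- Sys.time()
  ds <- read_dataset(file.path(config$outdir, "dataset"))
  ft <- extract_feature_table(ds, config$distances_mm, config$features)
  write_feature_table(ft, file.path(config$outdir, "features.csv"),
                      meta = list(config_hash = config_hash(unclass(config)),
                                  seed = config$seed, rows = nrow(ft)))
  write_provenance(config, "extract",
                   list(rows = nrow(ft),
                        features = length(feature_columns(ft)),
                        elapsed_s = as.numeric(Sys.time() - t0, units = "secs")))
  study_log(config, "extract: %d rows x %d features", nrow(ft),
            length(feature_columns(ft)))
  invisible(ft)
}

#' @rdname study_simulate
#' @export
study_evaluate <- function(config) {
  require_stage(config, "extract")
  t0 <- Sys.time()
  ft <- utils::read.csv(file.path(config$outdir, "features.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  res <- run_study(NULL, distances_mm = config$distances_mm,
                   feature_config = config$features,
                   selection_config = config$selection,
                   penalty_grid = config$penalty_grid,
                   k = config$k, seed = config$seed,
                   aggregate = config$aggregate, feature_table = ft)
  for (level in c("roi", "patient")) {
    out <- file.path(config$outdir, sprintf("results_%s.csv", level))
    utils::write.csv(res[[level]], out, row.names = FALSE)
    jsonlite::write_json(list(config_hash = config_hash(unclass(config)),
                              seed = config$seed, level = level),
                         paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  saveRDS_safe <- function() {
    sc <- do.call(rbind, lapply(names(res$scores), function(k)
      cbind(model = k, res$scores[[k]]$roi)))
    utils::write.csv(sc, file.path(config$outdir, "scores_roi.csv"),
                     row.names = FALSE)
  }
  saveRDS_safe()
  write_provenance(config, "evaluate",
                   list(models = nrow(res$patient),
                        elapsed_s = as.numeric(Sys.time() - t0, units = "secs")))
  study_log(config, "evaluate: %d region models at 2 levels", nrow(res$patient))
  invisible(res)
}

#' @rdname study_simulate
#' @export
study_compare <- function(config) {
  require_stage(config, "evaluate")
  sc <- utils::read.csv(file.path(config$outdir, "scores_roi.csv"),
                        stringsAsFactors = FALSE)
  models <- unique(sc$model)
  P <- matrix(NA_real_, length(models), length(models),
              dimnames = list(models, models))
  for (a in models) for (b in models) {
    if (a == b) next
    sa <- sc[sc$model == a, ]
    sb <- sc[sc$model == b, ]
    mg <- merge(sa, sb, by = c("patient_id", "view"))
    P[a, b] <- delong_test(mg$score.x, mg$score.y, mg$label.x)$p
  }
  utils::write.csv(as.data.frame(P), file.path(config$outdir, "delong_matrix.csv"))
  write_provenance(config, "compare", list(models = length(models)))
  invisible(P)
}

#' @rdname study_simulate
#' @param counts named list of contingency matrices (default: the packaged
#'   published clinical table)
#' @export
study_clinstats <- function(config, counts = clinical_table1_counts()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(counts, function(m) {
    r <- chi_square(m)
    list(chi2 = r$chi2, df = r$df, p = r$p, corrected = r$corrected)
  })
  jsonlite::write_json(res, file.path(config$outdir, "clinstats.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(config, "clinstats", list(tables = length(res)))
  res
}

#' @rdname study_simulate
#' @export
study_report <- function(config) {
  require_stage(config, "evaluate")
  sc <- utils::read.csv(file.path(config$outdir, "scores_roi.csv"),
                        stringsAsFactors = FALSE)
  pat <- utils::read.csv(file.path(config$outdir, "results_patient.csv"),
                         stringsAsFactors = FALSE)
  fig <- file.path(config$outdir, "roc_curves.png")
  grDevices::png(fig, width = 700, height = 700)
  models <- intersect(c("tumoral", "peritumoral_2mm", "combined_2mm"),
                      unique(sc$model))
  cols <- c("black", "steelblue", "firebrick")
  plot(c(0, 1), c(0, 1), type = "l", lty = 3, xlab = "1 - specificity",
       ylab = "sensitivity", main = "ROI-level ROC")
  for (i in seq_along(models)) {
    s <- sc[sc$model == models[i], ]
    y <- label_to_binary(s$label)
    th <- sort(unique(s$score), decreasing = TRUE)
    sens <- vapply(th, function(t) mean(s$score[y == 1] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(s$score[y == 0] >= t), numeric(1))
    graphics::lines(c(0, fpr, 1), c(0, sens, 1), col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = models, col = cols[seq_along(models)],
                   lwd = 2, bty = "n")
  grDevices::dev.off()
  fig2 <- file.path(config$outdir, "auc_forest.png")
  grDevices::png(fig2, width = 700, height = 400)
  lab <- ifelse(is.na(pat$distance_mm), pat$region,
                sprintf("%s %gmm", pat$region, pat$distance_mm))
  o <- seq_len(nrow(pat))
  plot(pat$auc, rev(o), xlim = c(0, 1), pch = 19, yaxt = "n",
       xlab = "patient-level AUC (95% CI)", ylab = "",
       main = "Region models")
  graphics::segments(pat$ci_lo, rev(o), pat$ci_hi, rev(o))
  graphics::axis(2, at = rev(o), labels = lab, las = 2, cex.axis = 0.7)
  graphics::abline(v = 0.5, lty = 3)
  grDevices::dev.off()
  write_provenance(config, "report", list(figures = 2))
  invisible(c(fig, fig2))
}
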