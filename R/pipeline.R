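# End-to-end pipeline: CSV inputs -> normalize -> fit -> DSS -> (selective
# DSS, TAS, synergy, cohort statistics) -> CSV outputs + run manifest.
# Every stage is a pure function of the inputs, the configuration and the
# seed; the manifest records content digests so reruns can be compared
# byte for byte.

#' Pipeline configuration
#'
#' @param input_dir directory with `wells.csv`, `library.csv`,
#'   `samples.csv` and optionally `targets.csv`, `controls.csv`, plus any
#'   combination matrices listed in `combo_files`.
#' @param out_dir output directory (created).
#' @param dss a [dss_config()].
#' @param tas list of TAS settings (`potency_cutoff_nM`,
#'   `min_drugs_per_target`, `n_perm`, `kinase_only`) or `NULL` to skip
#'   TAS.
#' @param cohort list of cohort settings: `threshold`, `groupA_subtype`,
#'   `groupB_subtype` (subtype labels for the differential comparison),
#'   `method` (`"moderated"`/`"welch"`).
#' @param combo_files CSV files (columns `drugA_conc`, `drugB_conc`,
#'   `inhibition`), relative to `input_dir`, scored with the HSA model.
#' @param seed integer seed for all pipeline randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            dss = dss_config(),
                            tas = list(potency_cutoff_nM = 1000,
                                       min_drugs_per_target = 2L,
                                       n_perm = 1000L,
                                       kinase_only = FALSE),
                            cohort = list(threshold = 10,
                                          groupA_subtype = "LGSOC",
                                          groupB_subtype = c("HGSOC",
                                                             "MUCOC"),
                                          method = "moderated"),
                            combo_files = character(0),
                            seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir, dss = dss,
                 tas = tas, cohort = cohort, combo_files = combo_files,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.read_input <- function(dir, file, required = TRUE) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    if (required) stop("missing required input file: ", path)
    return(NULL)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full DSRT analysis pipeline
#'
#' Stages in dependency order: plate normalization -> series assembly ->
#' 4PL fitting -> DSS scoring -> screen matrix -> selective DSS (if a
#' control panel is present) -> TAS (if a target map is present and TAS is
#' enabled) -> cohort statistics -> HSA synergy (for any combination
#' matrices).  All stage artifacts are written as CSV under
#' `config$out_dir`; `manifest.txt` records the package version, seed,
#' configuration digest, per-stage row counts and the MD5 digest of every
#' output file (no timestamps, so identical runs produce identical
#' manifests).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest (named character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(package = "dsrtools",
                version = as.character(utils::packageVersion("dsrtools")),
                seed = as.character(config$seed))
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(config[setdiff(names(config), c("input_dir",
                                                       "out_dir"))],
                       cfg_json, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  manifest["config_md5"] <- unname(tools::md5sum(cfg_json))
  unlink(cfg_json)

  emit <- function(df, file) {
    utils::write.csv(df, file.path(config$out_dir, file),
                     row.names = FALSE)
  }

  wells <- .stage("read_inputs",
                  .read_input(config$input_dir, "wells.csv"))
  library <- .stage("read_inputs",
                    .read_input(config$input_dir, "library.csv"))
  samples <- .stage("read_inputs",
                    .read_input(config$input_dir, "samples.csv"))
  targets <- .read_input(config$input_dir, "targets.csv", required = FALSE)
  controls <- .read_input(config$input_dir, "controls.csv",
                          required = FALSE)
  if (!is.null(config$tas) && is.null(targets))
    stop("pipeline stage [read_inputs] failed: TAS is enabled but ",
         file.path(config$input_dir, "targets.csv"), " is missing",
         call. = FALSE)

  norm <- .stage("normalize", normalize_plates(wells))
  emit(norm$qc, "qc.csv")
  series <- .stage("assemble", assemble_series(norm$wells))
  emit(series, "series.csv")
  manifest["n_series_rows"] <- as.character(nrow(series))

  fits <- .stage("fit", fit_screen(series))
  emit(fits, "fits.csv")
  manifest["n_fits"] <- as.character(nrow(fits))

  dss <- .stage("dss", dss_screen(fits, config$dss))
  emit(dss, "dss.csv")
  mat <- .stage("matrix",
                screen_matrix(dss, sample_anno = samples,
                              drug_anno = library))
  emit(data.frame(sample_id = rownames(mat), unclass(mat),
                  check.names = FALSE), "matrix_wide.csv")

  results <- list(qc = norm$qc, series = series, fits = fits, dss = dss,
                  matrix = mat)

  if (!is.null(controls)) {
    sdss <- .stage("sdss", selective_dss(dss, controls))
    emit(sdss, "sdss.csv")
    results$sdss <- sdss
  }

  if (!is.null(config$tas)) {
    tas <- .stage("tas", {
      mem <- build_membership(
        targets, potency_cutoff_nM = config$tas$potency_cutoff_nM,
        min_drugs_per_target = config$tas$min_drugs_per_target,
        kinase_only = isTRUE(config$tas$kinase_only))
      tas_screen(dss, mem, n_perm = config$tas$n_perm,
                 seed = config$seed)
    })
    emit(tas, "tas.csv")
    manifest["n_tas_rows"] <- as.character(nrow(tas))
    results$tas <- tas
  }

  co <- config$cohort
  eff <- .stage("cohort", effectiveness_calls(mat,
                                              threshold = co$threshold))
  emit(eff$fractions, "effectiveness.csv")
  gs <- .stage("cohort", subtype_group_stats(mat, level = "class",
                                             threshold = co$threshold))
  emit(gs$summary, "group_stats.csv")
  emit(gs$pairwise, "group_tests.csv")
  corr <- .stage("cohort", pairwise_subtype_correlation(mat))
  emit(corr, "correlations.csv")
  pca <- .stage("cohort", pca_projection(mat))
  emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                  check.names = FALSE), "pca_scores.csv")
  hc <- .stage("cohort", cluster_samples(mat))
  emit(data.frame(order = seq_along(hc$order),
                  sample_id = hc$labels[hc$order]), "cluster_order.csv")
  anno <- attr(mat, "sample_anno")
  gA <- anno$sample_id[anno$subtype %in% co$groupA_subtype]
  gB <- anno$sample_id[anno$subtype %in% co$groupB_subtype]
  volcano <- .stage("cohort",
                    differential_sensitivity(mat, gA, gB,
                                             include_threshold =
                                               co$threshold,
                                             method = co$method))
  emit(volcano, "volcano.csv")
  results <- c(results, list(effectiveness = eff, group_stats = gs,
                             correlations = corr, pca = pca, hclust = hc,
                             volcano = volcano))

  if (length(config$combo_files)) {
    syn <- .stage("synergy", {
      rows <- lapply(config$combo_files, function(f) {
        cmdf <- utils::read.csv(file.path(config$input_dir, f),
                                stringsAsFactors = FALSE)
        cA <- sort(unique(cmdf$drugA_conc))
        cB <- sort(unique(cmdf$drugB_conc))
        inh <- matrix(NA_real_, length(cA), length(cB))
        inh[cbind(match(cmdf$drugA_conc, cA),
                  match(cmdf$drugB_conc, cB))] <- cmdf$inhibition
        res <- hsa_excess(combination_matrix(cA, cB, inh,
                                             drugA_id = f,
                                             drugB_id = f))
        data.frame(combo = f, summary_score = res$summary_score,
                   max_window_score = res$max_window_score,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    emit(syn, "synergy_summary.csv")
    results$synergy <- syn
  }

  files <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  md5 <- tools::md5sum(file.path(config$out_dir, files))
  names(md5) <- paste0("md5_", files)
  manifest <- c(manifest, md5)
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(config$out_dir, "manifest.txt"))
  results$manifest <- manifest
  invisible(results)
}
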