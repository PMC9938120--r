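# Control-based plate normalization: raw luminescence to % inhibition.
#
# Each plate carries DMSO negative controls (full viability, 0% inhibition)
# and benzethonium chloride positive controls (full kill, 100%).  Controls
# are pooled per plate; no within-plate spatial correction is attempted.

#' Normalize raw plate signals to percent inhibition
#'
#' `inhibition = 100 * (mu_neg - signal) / (mu_neg - mu_pos)` with control
#' means pooled per plate.  Values outside \[0, 100\] are preserved so the
#' fitting layer sees raw behaviour.  Per-plate QC includes the Z'-factor
#' `1 - 3 (sd_neg + sd_pos) / (mu_neg - mu_pos)`.
#'
#' @param wells data frame with columns `plate_id`, `well`, `sample_id`,
#'   `drug_id`, `conc_nM`, `signal`, `role` (one of `sample`, `neg_ctrl`,
#'   `pos_ctrl`).
#' @return list with `wells` (sample wells plus an `inhibition` column) and
#'   `qc` (per plate: control means/sds, `z_prime`).
#' @export
normalize_plates <- function(wells) {
  need <- c("plate_id", "well", "sample_id", "drug_id", "conc_nM",
            "signal", "role")
  if (!all(need %in% names(wells)))
    stop("wells must contain columns: ", paste(need, collapse = ", "))
  if (!all(wells$role %in% c("sample", "neg_ctrl", "pos_ctrl")))
    stop("unknown well role(s)")
  plates <- unique(wells$plate_id)
  qc <- vector("list", length(plates))
  out <- vector("list", length(plates))
  for (k in seq_along(plates)) {
    p <- plates[k]
    w <- wells[wells$plate_id == p, , drop = FALSE]
    neg <- w$signal[w$role == "neg_ctrl"]
    pos <- w$signal[w$role == "pos_ctrl"]
    if (length(neg) < 2L || length(pos) < 2L)
      stop("plate ", p, ": need >= 2 wells of each control class")
    mu_neg <- mean(neg); mu_pos <- mean(pos)
    if (mu_neg <= mu_pos)
      stop("plate ", p, ": control inversion (mean DMSO signal <= ",
           "mean positive-control signal)")
    sd_neg <- stats::sd(neg); sd_pos <- stats::sd(pos)
    qc[[k]] <- data.frame(
      plate_id = p, n_neg = length(neg), n_pos = length(pos),
      mu_neg = mu_neg, sd_neg = sd_neg, mu_pos = mu_pos, sd_pos = sd_pos,
      z_prime = 1 - 3 * (sd_neg + sd_pos) / (mu_neg - mu_pos),
      stringsAsFactors = FALSE)
    sw <- w[w$role == "sample", , drop = FALSE]
    sw$inhibition <- 100 * (mu_neg - sw$signal) / (mu_neg - mu_pos)
    out[[k]] <- sw
  }
  wells_out <- do.call(rbind, out)
  rownames(wells_out) <- NULL
  qc <- do.call(rbind, qc)
  rownames(qc) <- NULL
  list(wells = wells_out, qc = qc)
}

#' Assemble per-(sample, drug) dose-response series
#'
#' Replicate wells at the same concentration are averaged (arithmetic mean);
#' series are sorted by concentration.  Series with fewer than `min_doses`
#' distinct concentrations are excluded and reported, not fitted.
#'
#' @param norm_wells normalized sample wells from [normalize_plates()]
#'   (columns `sample_id`, `drug_id`, `conc_nM`, `inhibition`).
#' @param min_doses minimum distinct concentrations per series (default 4).
#' @return long data frame `sample_id`, `drug_id`, `conc_nM`, `inhibition`
#'   sorted within series; attribute `excluded` is a data frame of dropped
#'   (sample, drug) pairs with their dose counts.
#' @export
assemble_series <- function(norm_wells, min_doses = 4L) {
  need <- c("sample_id", "drug_id", "conc_nM", "inhibition")
  if (!all(need %in% names(norm_wells)))
    stop("norm_wells must contain columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(
    inhibition ~ sample_id + drug_id + conc_nM, data = norm_wells,
    FUN = mean)
  agg <- agg[order(agg$sample_id, agg$drug_id, agg$conc_nM), , drop = FALSE]
  key <- paste(agg$sample_id, agg$drug_id, sep = "\r")
  n_doses <- table(key)
  bad <- names(n_doses)[n_doses < min_doses]
  excluded <- data.frame(sample_id = character(0), drug_id = character(0),
                         n_doses = integer(0), stringsAsFactors = FALSE)
  if (length(bad)) {
    parts <- strsplit(bad, "\r", fixed = TRUE)
    excluded <- data.frame(
      sample_id = vapply(parts, `[`, "", 1L),
      drug_id = vapply(parts, `[`, "", 2L),
      n_doses = as.integer(n_doses[bad]), stringsAsFactors = FALSE)
    message(length(bad), " series excluded with < ", min_doses, " doses")
    agg <- agg[!key %in% bad, , drop = FALSE]
  }
  agg <- agg[, need]
  rownames(agg) <- NULL
  attr(agg, "excluded") <- excluded
  agg
}
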