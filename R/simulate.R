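# Synthetic DSRT screen generator.
#
# Emulates a 16-sample / 13-patient epithelial ovarian cancer cohort
# (HGSOC, LGSOC, MUCOC) screened against an oncology library of 526 drugs
# at 5 concentrations spanning a 10,000-fold range on 384-well plates, with
# DMSO negative and benzethonium positive control wells.  Ground truth
# (per-series 4PL parameters, planted subtype effects, planted synergy) is
# recorded in a sidecar table that the analysis pipeline never reads.

.TARGETED_TAGS <- c("MDM2", "ERBB", "MEK", "ERK", "CHK1", "WEE1", "SMAC",
                    "PI3K", "MTOR", "CDK", "BCL2", "PARP", "HDAC", "JAK",
                    "SRC", "ALK", "FGFR", "VEGFR", "BRAF", "AURK")
.CHEMO_TAGS <- c("TOPO", "ANTIMETABOLITE", "ALKYLATOR", "TAXANE",
                 "PLATINUM", "VINCA", "ANTHRACYCLINE")
.KINASE_TAGS <- c("ERBB", "MEK", "ERK", "CHK1", "WEE1", "PI3K", "MTOR",
                  "CDK", "JAK", "SRC", "ALK", "FGFR", "VEGFR", "BRAF",
                  "AURK")

#' Default planted subtype drug-sensitivity effects
#'
#' LGSOC analogues gain sensitivity to MDM2, ERBB and MEK/ERK inhibitors,
#' MUCOC to MEK/ERK, HGSOC to CHK1, Wee1 and SMAC-mimetic drugs.  Shifts
#' are `+45` percentage points on the top asymptote and `-1.5` log10 units
#' on the EC50 of drugs carrying the tag: a planted sensitive mechanism
#' confers a strong maximal response at potent concentrations, giving the
#' affected drugs DSS values in the 15-30 range typical of clear subtype
#' hits rather than marginal shifts.
#'
#' @return data frame with columns `subtype`, `tag`, `d_top`, `d_logec50`.
#' @export
default_subtype_effects <- function() {
  rbind(
    data.frame(subtype = "LGSOC", tag = c("MDM2", "ERBB", "MEK", "ERK"),
               d_top = 45, d_logec50 = -1.5, stringsAsFactors = FALSE),
    data.frame(subtype = "MUCOC", tag = c("MEK", "ERK"),
               d_top = 45, d_logec50 = -1.5, stringsAsFactors = FALSE),
    data.frame(subtype = "HGSOC", tag = c("CHK1", "WEE1", "SMAC"),
               d_top = 45, d_logec50 = -1.5, stringsAsFactors = FALSE))
}

#' Simulation configuration for a synthetic DSRT screen
#'
#' Defaults state the emulated cohort: 5 HGSOC, 5 LGSOC and 3 MUCOC
#' patients (two LGSOC patients contribute 3 and 2 serial samples, giving
#' 16 samples in total), 526 drugs at 5 concentrations covering a
#' 10,000-fold range (1 to 10,000 nM), raw-signal coefficient of variation
#' 0.1, and the planted subtype effects of [default_subtype_effects()].
#'
#' @param n_samples_per_subtype named integer vector of patient counts for
#'   HGSOC/LGSOC/MUCOC.
#' @param serial_counts named list: per subtype, samples per patient
#'   (recycled); default gives the first two LGSOC patients 3 and 2 serial
#'   samples.
#' @param n_drugs library size.
#' @param n_doses doses per single-agent series (5; use 9 for 3D-style
#'   series).
#' @param dose_range_fold fold range between lowest and highest dose.
#' @param min_conc_nM lowest tested concentration.
#' @param control_wells_per_plate DMSO and positive-control wells per plate
#'   (each).
#' @param noise_cv coefficient of variation of the raw luminescence signal.
#' @param mu_neg,mu_pos expected raw signal of negative/positive control
#'   wells.
#' @param inactive_prob probability a library drug is inactive (top
#'   asymptote near 0) in an unshifted sample.
#' @param chemo_prob probability a drug is a chemotherapeutic.
#' @param sd_top,sd_logec50 between-patient SD of the top asymptote
#'   (percent) and log10-EC50.
#' @param subtype_effect_map data frame as [default_subtype_effects()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples_per_subtype = c(HGSOC = 5L, LGSOC = 5L,
                                                 MUCOC = 3L),
                       serial_counts = list(LGSOC = c(3L, 2L, 1L, 1L, 1L)),
                       n_drugs = 526L, n_doses = 5L,
                       dose_range_fold = 1e4, min_conc_nM = 1,
                       control_wells_per_plate = 16L,
                       noise_cv = 0.1, mu_neg = 1e5, mu_pos = 2e3,
                       inactive_prob = 0.6, chemo_prob = 0.2,
                       sd_top = 5, sd_logec50 = 0.15,
                       subtype_effect_map = default_subtype_effects(),
                       seed = 1L) {
  stopifnot(all(n_samples_per_subtype >= 1L), n_drugs >= 1L, n_doses >= 2L,
            dose_range_fold > 1, noise_cv >= 0,
            control_wells_per_plate >= 2L)
  if (mu_neg <= mu_pos)
    stop("control separation must be positive (mu_neg > mu_pos)")
  structure(list(n_samples_per_subtype = n_samples_per_subtype,
                 serial_counts = serial_counts, n_drugs = n_drugs,
                 n_doses = n_doses, dose_range_fold = dose_range_fold,
                 min_conc_nM = min_conc_nM,
                 control_wells_per_plate = control_wells_per_plate,
                 noise_cv = noise_cv, mu_neg = mu_neg, mu_pos = mu_pos,
                 inactive_prob = inactive_prob, chemo_prob = chemo_prob,
                 sd_top = sd_top, sd_logec50 = sd_logec50,
                 subtype_effect_map = subtype_effect_map, seed = seed),
            class = "sim_config")
}

# Sample table: patients and (possibly serial) samples per subtype.
.sim_samples <- function(config) {
  rows <- list(); pid <- 0L
  for (st in names(config$n_samples_per_subtype)) {
    n_pat <- config$n_samples_per_subtype[[st]]
    per_pat <- config$serial_counts[[st]]
    if (is.null(per_pat)) per_pat <- 1L
    per_pat <- rep_len(per_pat, n_pat)
    for (j in seq_len(n_pat)) {
      pid <- pid + 1L
      patient <- sprintf("P%02d", pid)
      for (k in seq_len(per_pat[j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = if (per_pat[j] > 1L) sprintf("%s_%d", patient, k)
                      else patient,
          patient_id = patient, subtype = st, serial_index = k,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Drug library with mechanism tags and per-drug base 4PL parameters.
.sim_library <- function(config, x_min, x_max) {
  n <- config$n_drugs
  drug_id <- sprintf("D%04d", seq_len(n))
  is_chemo <- stats::runif(n) < config$chemo_prob
  tag <- ifelse(is_chemo,
                sample(.CHEMO_TAGS, n, replace = TRUE),
                sample(.TARGETED_TAGS, n, replace = TRUE))
  # long-tailed activity: most drugs inactive, actives with high asymptote.
  # Cytotoxic chemotherapy is more broadly active than targeted agents
  # (class-conditional inactivity 2/3 vs >1 of the marginal), with the
  # marginal inactive mass kept at the configured value.
  p <- config$inactive_prob; pc <- config$chemo_prob
  p_chemo <- min(1, p * 2 / 3)
  p_targ <- if (pc < 1) min(1, (p - pc * p_chemo) / (1 - pc)) else p_chemo
  inactive <- stats::runif(n) < ifelse(is_chemo, p_chemo, p_targ)
  a0 <- ifelse(inactive, stats::runif(n, 0, 10), stats::runif(n, 40, 100))
  m0 <- stats::runif(n, x_min + 0.5, x_max + 1)
  s0 <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
  data.frame(drug_id = drug_id,
             name = paste0("drug-", tolower(tag), "-", seq_len(n)),
             class = ifelse(is_chemo, "chemotherapy", "targeted"),
             mechanism_tags = tag,
             base_a = a0, base_m = m0, base_s = pmin(pmax(s0, 0.3), 4),
             stringsAsFactors = FALSE)
}

# Drug-target bioactivity table (Kd/Ki/IC50 potencies in nM) emulating a
# curated polypharmacology extract; targeted drugs hit their mechanism
# target potently plus a few off-targets.
.sim_targets <- function(library) {
  targeted <- library[library$class == "targeted", , drop = FALSE]
  rows <- list()
  eps <- c("Kd", "Ki", "IC50")
  for (i in seq_len(nrow(targeted))) {
    prim <- targeted$mechanism_tags[i]
    n_off <- stats::rpois(1, 1.5)
    offs <- setdiff(sample(.TARGETED_TAGS, n_off, replace = TRUE), prim)
    tg <- c(prim, offs)
    pot <- c(10^stats::runif(1, 0.5, 2),
             10^stats::runif(length(offs), 2, 3.7))
    rows[[i]] <- data.frame(
      drug_id = targeted$drug_id[i], target_id = tg,
      endpoint = sample(eps, length(tg), replace = TRUE),
      potency_nM = pot, is_kinase = tg %in% .KINASE_TAGS,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Planted per-(subtype, tag) shifts for a drug, from the effect map.
.subtype_shift <- function(tag, subtype, map) {
  hit <- map$subtype == subtype & map$tag == tag
  if (!any(hit)) return(c(d_top = 0, d_logec50 = 0))
  c(d_top = max(map$d_top[hit]), d_logec50 = min(map$d_logec50[hit]))
}

#' Simulate a raw plate-format drug screen with ground truth
#'
#' True percent inhibition for each (sample, drug, dose) is generated from
#' a 4PL surface whose per-drug base parameters are shifted per subtype via
#' the planted effect map and jittered per patient; serial samples of the
#' same patient share identical true parameters, so their profiles differ
#' only by plate noise.  Raw signal is
#' `mu_neg - inhibition/100 * (mu_neg - mu_pos)` plus Gaussian noise with
#' the configured CV (applied on the raw-signal scale, so control-based
#' normalization is genuinely exercised).  Wells are laid out on 384-well
#' plates with the configured number of DMSO and positive-control wells.
#'
#' @param config a [sim_config()].
#' @return list of data frames: `wells` (plate_id, well, sample_id,
#'   drug_id, conc_nM, signal, role), `library`, `targets`, `samples`, and
#'   the sidecar `truth` (per sample x drug: true `b`, `a`, `m`, `s` and
#'   the planted shift), plus `doses` (the tested concentrations).
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  doses <- config$min_conc_nM *
    config$dose_range_fold^(seq(0, 1, length.out = config$n_doses))
  x_min <- log10(doses[1L]); x_max <- log10(doses[length(doses)])

  samples <- .sim_samples(config)
  library <- .sim_library(config, x_min, x_max)
  targets <- .sim_targets(library)

  # patient-level true parameters (shared across serial samples)
  patients <- unique(samples[, c("patient_id", "subtype")])
  truth <- list()
  for (i in seq_len(nrow(patients))) {
    sh <- t(vapply(library$mechanism_tags, .subtype_shift, numeric(2),
                   subtype = patients$subtype[i],
                   map = config$subtype_effect_map))
    a <- pmin(pmax(library$base_a + sh[, "d_top"] +
                     stats::rnorm(nrow(library), 0, config$sd_top), 0), 100)
    m <- library$base_m + sh[, "d_logec50"] +
      stats::rnorm(nrow(library), 0, config$sd_logec50)
    truth[[i]] <- data.frame(
      patient_id = patients$patient_id[i], drug_id = library$drug_id,
      b = 0, a = a, m = m, s = library$base_s,
      planted_d_top = sh[, "d_top"],
      planted_d_logec50 = sh[, "d_logec50"], stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth <- merge(samples[, c("sample_id", "patient_id", "subtype")], truth,
                 by = "patient_id", sort = FALSE)
  truth <- truth[order(truth$sample_id, truth$drug_id), , drop = FALSE]
  rownames(truth) <- NULL

  # plate layout: per sample, drug x dose wells chunked onto 384-well
  # plates leaving room for the control wells
  n_ctrl <- config$control_wells_per_plate
  capacity <- 384L - 2L * n_ctrl
  if (capacity < 1L) stop("control wells exceed plate capacity")
  wells <- list()
  for (sid in samples$sample_id) {
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    grid <- expand.grid(di = seq_len(nrow(library)),
                        ci = seq_along(doses))
    inh <- fourpl(log10(doses[grid$ci]), 0, tr$a[grid$di], tr$m[grid$di],
                  tr$s[grid$di])
    sig_true <- config$mu_neg -
      inh / 100 * (config$mu_neg - config$mu_pos)
    plate_no <- (seq_len(nrow(grid)) - 1L) %/% capacity + 1L
    sw <- data.frame(
      plate_id = sprintf("%s_PL%02d", sid, plate_no),
      well = sprintf("W%03d", (seq_len(nrow(grid)) - 1L) %% capacity + 1L),
      sample_id = sid, drug_id = library$drug_id[grid$di],
      conc_nM = doses[grid$ci],
      signal = sig_true +
        stats::rnorm(nrow(grid), 0, config$noise_cv * sig_true),
      role = "sample", stringsAsFactors = FALSE)
    for (p in unique(sw$plate_id)) {
      neg <- config$mu_neg +
        stats::rnorm(n_ctrl, 0, config$noise_cv * config$mu_neg)
      pos <- config$mu_pos +
        stats::rnorm(n_ctrl, 0, config$noise_cv * config$mu_pos)
      wells[[length(wells) + 1L]] <- data.frame(
        plate_id = p,
        well = sprintf("C%03d", seq_len(2L * n_ctrl)),
        sample_id = sid, drug_id = NA_character_, conc_nM = NA_real_,
        signal = c(neg, pos),
        role = rep(c("neg_ctrl", "pos_ctrl"), each = n_ctrl),
        stringsAsFactors = FALSE)
    }
    wells[[length(wells) + 1L]] <- sw
  }
  wells <- do.call(rbind, wells)
  rownames(wells) <- NULL

  list(wells = wells,
       library = library[, c("drug_id", "name", "class", "mechanism_tags")],
       targets = targets, samples = samples, truth = truth, doses = doses,
       config = config)
}

#' Simulate DSS profiles of healthy-control donors
#'
#' Healthy bone-marrow-derived mononuclear cell analogues: targeted drugs
#' draw low scores (half-normal, mean < 5), cytotoxic chemotherapy draws
#' moderate scores, so chemotherapy-class means exceed targeted-class means.
#'
#' @param library drug library data frame (needs `drug_id`, `class`).
#' @param config a [sim_config()] (only the seed is used).
#' @param n_donors number of donors (default 2).
#' @return data frame `donor_id`, `drug_id`, `dss`.
#' @export
simulate_healthy_controls <- function(library, config = sim_config(),
                                      n_donors = 2L) {
  stopifnot(n_donors >= 2L)
  set.seed(config$seed + 104729L)
  rows <- list()
  for (d in seq_len(n_donors)) {
    dss <- ifelse(library$class == "chemotherapy",
                  stats::rgamma(nrow(library), shape = 2.56,
                                scale = 3.125),       # mean 8, sd 5
                  abs(stats::rnorm(nrow(library), 0, 2.2)))  # mean ~1.8
    rows[[d]] <- data.frame(donor_id = sprintf("HC%02d", d),
                            drug_id = library$drug_id, dss = dss,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a 7x7 drug-combination inhibition matrix
#'
#' Single-agent responses come from the two drugs' 4PL curves (row and
#' column 0, i.e. concentration 0); interior cells follow the highest
#' single agent surface plus a planted excess:
#' `inhibition(i, j) = min(100, max(monoA_i, monoB_j) + excess)`.
#' Observed inhibition is obtained by converting to raw signal, adding
#' Gaussian noise at the configured CV, and re-normalizing with simulated
#' DMSO/positive control wells, mirroring the single-agent plates.
#'
#' @param drugA,drugB lists with 4PL parameters `a`, `m`, `s` (and
#'   optionally `b`, `drug_id`).
#' @param synergy_excess planted interior excess in percentage points
#'   (>= 0).
#' @param config a [sim_config()]; supplies noise, control levels, seed.
#' @param concs_nM the six non-zero concentrations per drug (shared).
#' @return a `combination_matrix` object (see [combination_matrix()]) with
#'   attribute `truth_excess`, the planted (post-ceiling) excess surface.
#' @export
simulate_combination_matrix <- function(drugA, drugB, synergy_excess = 0,
                                        config = sim_config(),
                                        concs_nM = 10^seq(0, 4,
                                                          length.out = 6)) {
  stopifnot(synergy_excess >= 0, length(concs_nM) == 6L)
  set.seed(config$seed + 7919L)
  bA <- if (is.null(drugA$b)) 0 else drugA$b
  bB <- if (is.null(drugB$b)) 0 else drugB$b
  concs <- c(0, sort(concs_nM))
  monoA <- c(bA, fourpl(log10(concs[-1L]), bA, drugA$a, drugA$m, drugA$s))
  monoB <- c(bB, fourpl(log10(concs[-1L]), bB, drugB$a, drugB$m, drugB$s))
  true_inh <- outer(monoA, monoB, pmax)
  interior <- outer(seq_along(concs) > 1L, seq_along(concs) > 1L, `&`)
  true_inh[interior] <- pmin(100, true_inh[interior] + synergy_excess)
  true_inh[1L, ] <- monoB
  true_inh[, 1L] <- monoA
  truth_excess <- true_inh - outer(monoA, monoB, pmax)

  sig_true <- config$mu_neg - true_inh / 100 *
    (config$mu_neg - config$mu_pos)
  sig <- sig_true + stats::rnorm(length(sig_true),
                                 0, config$noise_cv * sig_true)
  n_ctrl <- config$control_wells_per_plate
  mu_neg_hat <- mean(config$mu_neg +
                       stats::rnorm(n_ctrl, 0,
                                    config$noise_cv * config$mu_neg))
  mu_pos_hat <- mean(config$mu_pos +
                       stats::rnorm(n_ctrl, 0,
                                    config$noise_cv * config$mu_pos))
  inh_obs <- matrix(100 * (mu_neg_hat - sig) / (mu_neg_hat - mu_pos_hat),
                    nrow = length(concs))
  cm <- combination_matrix(
    concsA = concs, concsB = concs, inhibition = inh_obs,
    drugA_id = if (is.null(drugA$drug_id)) "drugA" else drugA$drug_id,
    drugB_id = if (is.null(drugB$drug_id)) "drugB" else drugB$drug_id)
  attr(cm, "truth_excess") <- truth_excess
  cm
}

#' Write a simulated screen to CSV files
#'
#' Emits `wells.csv`, `library.csv`, `targets.csv`, `samples.csv` and the
#' sidecar `truth.csv` (never read by the pipeline), plus `controls.csv`
#' when a healthy panel is supplied.
#'
#' @param sim output of [simulate_screen()].
#' @param dir output directory (created if needed).
#' @param controls optional healthy panel from
#'   [simulate_healthy_controls()].
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sim, dir, controls = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$wells, file.path(dir, "wells.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$library, file.path(dir, "library.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$targets, file.path(dir, "targets.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(controls))
    utils::write.csv(controls, file.path(dir, "controls.csv"),
                     row.names = FALSE)
  invisible(dir)
}
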