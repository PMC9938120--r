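# Target addiction scoring (TAS): drug polypharmacology maps a per-sample
# DSS profile from compound space into target space.  For target t with
# n_t potent inhibitors, TAS_t = sum_i DSS_i / n_t; significance by
# permuting the DSS-to-drug assignment.

#' Build potency-filtered target membership sets
#'
#' Bioactivity records (Kd/Ki/IC50 potencies in nM) are deduplicated per
#' (drug, target) keeping the most potent record, filtered at the potency
#' cutoff (`<=` convention), and targets with too few member drugs are
#' dropped.
#'
#' @param targets data frame with `drug_id`, `target_id`, `endpoint`,
#'   `potency_nM` (optionally `is_kinase`).
#' @param potency_cutoff_nM potency cutoff defining a "potent" interaction
#'   (default 1000 nM).
#' @param min_drugs_per_target minimum member drugs to score a target
#'   (default 2).
#' @param kinase_only restrict to records with `is_kinase == TRUE`
#'   (requires the column).
#' @return named list: target id -> character vector of member drug ids;
#'   attribute `n_dropped` counts targets removed by the size filter.
#' @export
build_membership <- function(targets, potency_cutoff_nM = 1000,
                             min_drugs_per_target = 2L,
                             kinase_only = FALSE) {
  need <- c("drug_id", "target_id", "potency_nM")
  if (!all(need %in% names(targets)))
    stop("targets must contain columns: ", paste(need, collapse = ", "))
  if (nrow(targets) == 0L) stop("empty drug-target map")
  stopifnot(potency_cutoff_nM > 0, min_drugs_per_target >= 1L,
            all(targets$potency_nM > 0))
  if (kinase_only) {
    if (is.null(targets$is_kinase))
      stop("kinase_only requires an is_kinase column")
    targets <- targets[targets$is_kinase, , drop = FALSE]
  }
  # deduplicate (drug, target) keeping the most potent endpoint
  ord <- order(targets$drug_id, targets$target_id, targets$potency_nM)
  targets <- targets[ord, , drop = FALSE]
  targets <- targets[!duplicated(targets[, c("drug_id", "target_id")]), ,
                     drop = FALSE]
  targets <- targets[targets$potency_nM <= potency_cutoff_nM, , drop = FALSE]
  membership <- lapply(split(targets$drug_id, targets$target_id), unique)
  keep <- vapply(membership, length, 0L) >= min_drugs_per_target
  out <- membership[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Compute target addiction scores for one DSS profile
#'
#' `tas_t` is the arithmetic mean of the sample's DSS over the target's
#' member drugs.  Member drugs without a DSS value are excluded from that
#' target's mean (`n_t` adjusted); targets with no scored member are
#' omitted and counted in the `n_omitted` attribute.
#'
#' @param dss named numeric vector of DSS values, names are drug ids.
#' @param membership list from [build_membership()].
#' @return data frame `target_id`, `tas`, `n_t`; attribute `n_omitted`.
#' @export
compute_tas <- function(dss, membership) {
  stopifnot(!is.null(names(dss)), length(membership) > 0L)
  rows <- lapply(names(membership), function(t) {
    v <- dss[intersect(membership[[t]], names(dss))]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    data.frame(target_id = t, tas = sum(v) / length(v),
               n_t = length(v), stringsAsFactors = FALSE)
  })
  omitted <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_omitted") <- omitted
  out
}

#' Permutation significance of target addiction scores
#'
#' The DSS vector is permuted across drug ids `n_perm` times with the
#' membership structure held fixed (preserving target sizes); the
#' one-sided p-value with add-one correction is
#' `p_t = (1 + #\{perm: tas_t^perm >= tas_t^obs\}) / (n_perm + 1)`, so it
#' can never be 0 and a target containing every screened drug gets p = 1.
#'
#' @param dss named numeric vector of DSS values.
#' @param membership list from [build_membership()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return data frame `target_id`, `tas`, `n_t`, `p_perm`.
#' @export
tas_permutation <- function(dss, membership, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  obs <- compute_tas(dss, membership)
  # indicator matrix restricted to drugs with a DSS value
  dss <- dss[!is.na(dss)]
  drugs <- names(dss)
  M <- matrix(0, nrow(obs), length(drugs),
              dimnames = list(obs$target_id, drugs))
  for (i in seq_len(nrow(obs))) {
    mem <- intersect(membership[[obs$target_id[i]]], drugs)
    M[i, mem] <- 1 / length(mem)
  }
  set.seed(seed)
  ge <- rep(0L, nrow(obs))
  v <- as.numeric(dss)
  for (k in seq_len(n_perm)) {
    tas_perm <- as.numeric(M %*% v[sample.int(length(v))])
    ge <- ge + (tas_perm >= obs$tas - 1e-12)
  }
  obs$p_perm <- (1 + ge) / (n_perm + 1)
  obs
}

#' Per-sample target addiction profiles for a screen
#'
#' @param dss data frame with `sample_id`, `drug_id`, `dss`.
#' @param membership list from [build_membership()].
#' @param n_perm permutations per sample (`0` skips significance).
#' @param seed integer seed (incremented per sample).
#' @return data frame `sample_id`, `target_id`, `tas`, `n_t` (and
#'   `p_perm` when `n_perm > 0`), ranked by `tas` within sample.
#' @export
tas_screen <- function(dss, membership, n_perm = 1000L, seed = 1L) {
  out <- list()
  for (sid in sort(unique(dss$sample_id))) {
    v <- dss$dss[dss$sample_id == sid]
    names(v) <- dss$drug_id[dss$sample_id == sid]
    tp <- if (n_perm > 0L) {
      tas_permutation(v, membership, n_perm = n_perm,
                      seed = seed + match(sid, sort(unique(dss$sample_id))))
    } else compute_tas(v, membership)
    tp <- tp[order(-tp$tas, tp$target_id), , drop = FALSE]
    tp <- cbind(sample_id = sid, tp, stringsAsFactors = FALSE)
    out[[sid]] <- tp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
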