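# Highest single agent (HSA) synergy scoring of dose-combination matrices.

#' Construct a drug-combination inhibition matrix
#'
#' Row `i = 0` and column `j = 0` (concentration 0) hold the single-agent
#' responses of drug B and drug A respectively; the standard layout is a
#' 7x7 matrix (0 plus six doses per drug).
#'
#' @param concsA,concsB concentrations in nM, non-decreasing, first entry 0.
#' @param inhibition numeric matrix (`length(concsA)` x `length(concsB)`)
#'   of percent inhibition, rows indexed by drug A dose.
#' @param drugA_id,drugB_id drug identifiers.
#' @return a `combination_matrix` object.
#' @export
combination_matrix <- function(concsA, concsB, inhibition,
                               drugA_id = "drugA", drugB_id = "drugB") {
  stopifnot(is.matrix(inhibition),
            nrow(inhibition) == length(concsA),
            ncol(inhibition) == length(concsB))
  if (concsA[1L] != 0 || concsB[1L] != 0)
    stop("first concentration of each drug must be 0 (single-agent axis)")
  if (is.unsorted(concsA) || is.unsorted(concsB))
    stop("concentrations must be non-decreasing")
  dimnames(inhibition) <- list(format(concsA, trim = TRUE),
                               format(concsB, trim = TRUE))
  structure(list(drugA_id = drugA_id, drugB_id = drugB_id,
                 concsA = concsA, concsB = concsB,
                 inhibition = inhibition),
            class = "combination_matrix")
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("%dx%d combination matrix: %s (rows) x %s (cols)\n",
              nrow(x$inhibition), ncol(x$inhibition),
              x$drugA_id, x$drugB_id))
  print(round(x$inhibition, 1))
  invisible(x)
}

#' HSA excess synergy scoring
#'
#' Per-cell excess over the highest single agent:
#' `excess(i, j) = inhibition(i, j) - max(inhibition(i, 0),
#' inhibition(0, j))` for `i, j >= 1`, zero on the single-agent margins.
#' The summary score is the mean excess over the interior cells; the
#' highest mean over any contiguous 3x3 interior window is reported
#' alongside.
#'
#' @param cm a [combination_matrix()].
#' @return a `synergy_result` list: `excess` matrix, `summary_score`,
#'   `max_window_score`, drug ids.
#' @export
hsa_excess <- function(cm) {
  stopifnot(inherits(cm, "combination_matrix"))
  inh <- cm$inhibition
  if (anyNA(inh)) {
    bad <- which(is.na(inh), arr.ind = TRUE)
    stop("missing cells at (row, col): ",
         paste(sprintf("(%d,%d)", bad[, 1L], bad[, 2L]), collapse = " "))
  }
  hsa_ref <- outer(inh[, 1L], inh[1L, ], pmax)
  excess <- inh - hsa_ref
  excess[1L, ] <- 0
  excess[, 1L] <- 0
  nr <- nrow(inh); nc <- ncol(inh)
  interior <- excess[2:nr, 2:nc, drop = FALSE]
  win <- -Inf
  if (nrow(interior) >= 3L && ncol(interior) >= 3L) {
    for (i in seq_len(nrow(interior) - 2L)) {
      for (j in seq_len(ncol(interior) - 2L)) {
        win <- max(win, mean(interior[i:(i + 2L), j:(j + 2L)]))
      }
    }
  } else {
    win <- mean(interior)
  }
  structure(list(drugA_id = cm$drugA_id, drugB_id = cm$drugB_id,
                 excess = excess, summary_score = mean(interior),
                 max_window_score = win),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("HSA synergy %s + %s: mean interior excess %.2f, ",
              x$drugA_id, x$drugB_id, x$summary_score),
      sprintf("max 3x3 window %.2f\n", x$max_window_score))
  invisible(x)
}

#' Dose-response slices of a combination matrix
#'
#' One dose-response curve of drug A per requested fixed dose of drug B
#' (fixed dose 0 returns the drug A monotherapy row).
#'
#' @param cm a [combination_matrix()].
#' @param fixed_doses_B fixed drug B concentrations; default all non-zero
#'   doses.
#' @return named list of data frames (`conc_nM`, `inhibition`), one per
#'   fixed dose, over the non-zero drug A concentrations.
#' @export
dose_response_slices <- function(cm, fixed_doses_B = NULL) {
  stopifnot(inherits(cm, "combination_matrix"))
  if (is.null(fixed_doses_B)) fixed_doses_B <- cm$concsB[-1L]
  out <- list()
  for (d in fixed_doses_B) {
    j <- which(cm$concsB == d)
    if (length(j) != 1L)
      stop("fixed dose ", d, " nM not among drug B concentrations")
    out[[format(d, trim = TRUE)]] <- data.frame(
      conc_nM = cm$concsA[-1L],
      inhibition = cm$inhibition[-1L, j])
  }
  out
}
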