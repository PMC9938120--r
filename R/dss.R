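# Drug sensitivity score (DSS): normalized partial AUC of the fitted
# dose-response curve above an activity threshold, over the tested dose
# window.  DSS1 normalizes by the full activity x dose window; DSS3
# additionally multiplies by the realized dose-window fraction and divides
# by log10 of the top asymptote, penalizing shallow responses.

#' DSS configuration
#'
#' @param activity_threshold lower bound of the activity window, percent
#'   inhibition (default 10).
#' @param response_ceiling upper bound of the activity window (default 100).
#' @param metric `"DSS3"` (default) or `"DSS1"`.
#' @param x_min,x_max log10-nM bounds of the tested dose range; `NULL`
#'   (default) takes each fit's own tested range.
#' @return a `dss_config` list.
#' @export
dss_config <- function(activity_threshold = 10, response_ceiling = 100,
                       metric = c("DSS3", "DSS1"),
                       x_min = NULL, x_max = NULL) {
  metric <- match.arg(metric)
  if (activity_threshold <= 0 || activity_threshold >= response_ceiling)
    stop("need 0 < activity_threshold < response_ceiling")
  if (!is.null(x_min) && !is.null(x_max) && x_min >= x_max)
    stop("x_min must be below x_max")
  structure(list(activity_threshold = activity_threshold,
                 response_ceiling = response_ceiling,
                 metric = metric, x_min = x_min, x_max = x_max),
            class = "dss_config")
}

# log(1 + 10^z), numerically stable for large z
.log1p10 <- function(z) {
  ifelse(z > 25, z * log(10) + log1p(10^(-z)), log1p(10^z))
}

# Antiderivative of the 4PL curve: int y dx = b x + (a-b)/(s ln 10) *
# ln(1 + 10^{s (x - m)})
.fourpl_antideriv <- function(x, b, a, m, s) {
  b * x + (a - b) / (s * log(10)) * .log1p10(s * (x - m))
}

# Closed-form integral of (min(y, ceiling) - t) over [x1, x2] for an
# increasing 4PL curve y.
.pauc_4pl <- function(b, a, m, s, t, ceiling, x1, x2) {
  if (x2 <= x1) return(0)
  plain <- function(lo, hi) {
    .fourpl_antideriv(hi, b, a, m, s) - .fourpl_antideriv(lo, b, a, m, s) -
      t * (hi - lo)
  }
  if (a <= ceiling) return(plain(x1, x2))
  # curve exceeds the ceiling beyond xc; clip
  xc <- m - (1 / s) * log10((a - b) / (ceiling - b) - 1)
  if (xc <= x1) return((ceiling - t) * (x2 - x1))
  if (xc >= x2) return(plain(x1, x2))
  plain(x1, xc) + (ceiling - t) * (x2 - xc)
}

#' Compute the drug sensitivity score of a fitted curve
#'
#' The dose window runs from the larger of the minimum tested concentration
#' and the concentration where the curve reaches the activity threshold, to
#' the maximum tested concentration.  The partial AUC
#' `I = int_{x1}^{x2} (min(y(x), ceiling) - t) dx` has a closed form from
#' the logistic antiderivative.  With activity window `(t, ceiling)` and
#' tested range `(x_min, x_max)`:
#' \deqn{DSS1 = 100 I / ((ceiling - t)(x_{max} - x_{min}))}
#' \deqn{DSS3 = DSS1 \cdot \frac{x_2 - x_1}{x_{max} - x_{min}} / \log_{10} a}
#' with `a` clipped to `(t, ceiling]` inside the logarithm.  Curves whose
#' top asymptote does not exceed the threshold, and non-converged fits,
#' score 0 with an empty window.
#'
#' @param fit a `fourpl_fit` object.
#' @param config a [dss_config()].
#' @return data frame row: `dss` (selected metric), `dss1`, `dss3`,
#'   `x1`, `x2`, `pauc`, `metric`.
#' @export
compute_dss <- function(fit, config = dss_config()) {
  stopifnot(inherits(fit, "fourpl_fit"))
  x_min <- if (is.null(config$x_min)) fit$x_min else config$x_min
  x_max <- if (is.null(config$x_max)) fit$x_max else config$x_max
  t <- config$activity_threshold
  ceil <- config$response_ceiling
  zero <- data.frame(dss = 0, dss1 = 0, dss3 = 0,
                     x1 = x_max, x2 = x_max, pauc = 0,
                     metric = config$metric, stringsAsFactors = FALSE)
  if (!isTRUE(fit$converged)) return(zero)
  if (fit$a <= max(t, 1)) return(zero)
  xt <- dose_at_inhibition(fit, t)
  x1 <- if (is.na(xt)) x_min else max(x_min, xt)
  x2 <- x_max
  if (x1 >= x2) return(zero)
  I <- .pauc_4pl(fit$b, fit$a, fit$m, fit$s, t, ceil, x1, x2)
  dss1 <- 100 * I / ((ceil - t) * (x_max - x_min))
  a_clip <- min(max(fit$a, t + 1e-9), ceil)
  dss3 <- dss1 * ((x2 - x1) / (x_max - x_min)) / log10(a_clip)
  data.frame(dss = if (config$metric == "DSS3") dss3 else dss1,
             dss1 = dss1, dss3 = dss3, x1 = x1, x2 = x2, pauc = I,
             metric = config$metric, stringsAsFactors = FALSE)
}

#' DSS directly from 4PL parameters
#'
#' Convenience wrapper used for ground-truth calculations: builds converged
#' `fourpl_fit` objects from parameter vectors and scores them.
#'
#' @param a,m,s 4PL parameter vectors (recycled to a common length).
#' @param b bottom asymptote (scalar, default 0).
#' @param x_min,x_max tested log10-nM range.
#' @param config a [dss_config()]; its `x_min`/`x_max` are overridden.
#' @return numeric vector of DSS values (metric per `config`).
#' @export
dss_from_params <- function(a, m, s, b = 0, x_min, x_max,
                            config = dss_config()) {
  n <- max(length(a), length(m), length(s))
  a <- rep_len(a, n); m <- rep_len(m, n); s <- rep_len(s, n)
  cfg <- config; cfg$x_min <- x_min; cfg$x_max <- x_max
  vapply(seq_len(n), function(i) {
    f <- .new_fourpl_fit(b, a[i], m[i], s[i], 0, TRUE, NA_integer_,
                         x_min, x_max)
    compute_dss(f, cfg)$dss
  }, numeric(1))
}

#' Score every fitted series of a screen
#'
#' @param fits data frame from [fit_screen()].
#' @param config a [dss_config()].
#' @return data frame: `sample_id`, `drug_id`, `dss`, `dss1`, `dss3`,
#'   `x1`, `x2`.
#' @export
dss_screen <- function(fits, config = dss_config()) {
  out <- vector("list", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    f <- .new_fourpl_fit(fits$b[i], fits$a[i], fits$m[i], fits$s[i],
                         fits$rss[i], fits$converged[i], fits$n_points[i],
                         fits$x_min[i], fits$x_max[i])
    d <- compute_dss(f, config)
    out[[i]] <- data.frame(sample_id = fits$sample_id[i],
                           drug_id = fits$drug_id[i],
                           dss = d$dss, dss1 = d$dss1, dss3 = d$dss3,
                           x1 = d$x1, x2 = d$x2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Selective DSS against a healthy-control panel
#'
#' `sDSS = DSS(sample) - mean(DSS over control donors)`, used to discount
#' drugs that are generally cytotoxic in healthy cells.  Drugs absent from
#' every control donor get `NA` and are listed in the `missing_controls`
#' attribute, never silently zeroed.
#'
#' @param dss data frame with `sample_id`, `drug_id`, `dss`.
#' @param controls data frame with `donor_id`, `drug_id`, `dss`.
#' @return `dss` with an added `sdss` column; attribute `missing_controls`
#'   holds drug ids with no control coverage.
#' @export
selective_dss <- function(dss, controls) {
  stopifnot(all(c("drug_id", "dss") %in% names(dss)),
            all(c("donor_id", "drug_id", "dss") %in% names(controls)))
  if (nrow(controls) == 0L) stop("empty control panel")
  ctrl_mean <- tapply(controls$dss, controls$drug_id, mean)
  mu <- ctrl_mean[match(dss$drug_id, names(ctrl_mean))]
  out <- dss
  out$sdss <- out$dss - as.numeric(mu)
  missing <- unique(out$drug_id[is.na(mu)])
  attr(out, "missing_controls") <- missing
  out
}

#' Assemble a samples-by-drugs DSS matrix
#'
#' @param dss data frame with `sample_id`, `drug_id`, `dss`.
#' @param sample_anno data frame with `sample_id`, `patient_id`, `subtype`,
#'   `serial_index`.
#' @param drug_anno data frame with `drug_id`, `class`, `mechanism_tags`.
#' @return numeric matrix (samples x drugs) of class `screen_matrix` with
#'   `sample_anno`/`drug_anno` attributes; missing (sample, drug) pairs
#'   are `NA`.
#' @export
screen_matrix <- function(dss, sample_anno, drug_anno) {
  samples <- sort(unique(dss$sample_id))
  drugs <- sort(unique(dss$drug_id))
  mat <- matrix(NA_real_, length(samples), length(drugs),
                dimnames = list(samples, drugs))
  mat[cbind(match(dss$sample_id, samples), match(dss$drug_id, drugs))] <-
    dss$dss
  if (anyDuplicated(paste(dss$sample_id, dss$drug_id)))
    stop("duplicate (sample, drug) scores")
  sample_anno <- sample_anno[match(samples, sample_anno$sample_id), ,
                             drop = FALSE]
  drug_anno <- drug_anno[match(drugs, drug_anno$drug_id), , drop = FALSE]
  structure(mat, sample_anno = sample_anno, drug_anno = drug_anno,
            class = c("screen_matrix", "matrix", "array"))
}

#' Effectiveness calls and per-class effective-drug fractions
#'
#' A drug is called moderately-to-strongly effective in a sample when its
#' DSS meets the fixed threshold (default 10, the cohort's 85% quantile
#' convention).  The empirical 85th percentile of the pooled score
#' distribution (linear interpolation between order statistics) is reported
#' alongside for comparison; the fixed threshold governs the calls.
#'
#' @param mat a [screen_matrix()] (complete, no `NA`).
#' @param threshold effectiveness threshold on DSS (default 10).
#' @return list with `calls` (boolean matrix), `fractions` (data frame:
#'   `sample_id`, `subtype`, `class` in all/chemotherapy/targeted,
#'   `n_drugs`, `n_effective`, `fraction`), and `pooled_q85`.
#' @export
effectiveness_calls <- function(mat, threshold = 10) {
  stopifnot(inherits(mat, "screen_matrix"))
  if (anyNA(mat)) stop("screen matrix has missing cells")
  drug_anno <- attr(mat, "drug_anno")
  cls <- drug_anno$class
  if (is.null(cls) || anyNA(cls) ||
      !all(cls %in% c("chemotherapy", "targeted")))
    stop("unknown drug class annotation; expected chemotherapy/targeted")
  sample_anno <- attr(mat, "sample_anno")
  calls <- mat >= threshold
  groups <- list(all = rep(TRUE, ncol(mat)),
                 chemotherapy = cls == "chemotherapy",
                 targeted = cls == "targeted")
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) next
    n_eff <- rowSums(calls[, sel, drop = FALSE])
    rows[[g]] <- data.frame(
      sample_id = rownames(mat),
      subtype = sample_anno$subtype,
      class = g, n_drugs = sum(sel), n_effective = as.integer(n_eff),
      fraction = n_eff / sum(sel), stringsAsFactors = FALSE)
  }
  fractions <- do.call(rbind, rows)
  rownames(fractions) <- NULL
  list(calls = calls, fractions = fractions,
       pooled_q85 = unname(stats::quantile(as.numeric(mat), 0.85, type = 7)))
}
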