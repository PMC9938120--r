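# Four-parameter logistic dose-response model and constrained fitting.
#
# Model: y(x) = b + (a - b) / (1 + 10^(s * (m - x))),  x = log10(conc in nM)
# with bottom b, top asymptote a (% inhibition), m = log10(EC50), slope s > 0.

#' Evaluate a four-parameter logistic curve
#'
#' @param x log10 concentration (nM); may be a vector.
#' @param b bottom asymptote (percent inhibition).
#' @param a top asymptote (percent inhibition).
#' @param m log10 of the EC50 in nM.
#' @param s Hill slope (dimensionless, positive for an inhibitor).
#' @return Percent inhibition at `x`; monotone non-decreasing in `x` when
#'   `s > 0`, with limits `b` as `x -> -Inf` and `a` as `x -> +Inf`.
#' @examples
#' fourpl(1, b = 0, a = 100, m = 0, s = 1)  # ~90.9
#' @export
fourpl <- function(x, b, a, m, s) {
  b + (a - b) / (1 + 10^(s * (m - x)))
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit a `fourpl_fit` object from [fit_4pl()].
#' @param x log10 concentration(s) in nM.
#' @return percent inhibition at `x`.
#' @export
inhibition_at <- function(fit, x) {
  stopifnot(inherits(fit, "fourpl_fit"), all(is.finite(x)))
  fourpl(x, fit$b, fit$a, fit$m, fit$s)
}

#' Invert a fitted dose-response curve at a given inhibition level
#'
#' Closed-form inverse `x = m - (1/s) * log10((a - b)/(y - b) - 1)`.
#' Returns `NA` when the level `y` is outside the open interval `(b, a)`,
#' i.e. the curve never reaches it.
#'
#' @param fit a `fourpl_fit` object.
#' @param y percent inhibition level.
#' @return log10 concentration (nM) at which the curve attains `y`, or `NA`.
#' @export
dose_at_inhibition <- function(fit, y) {
  stopifnot(inherits(fit, "fourpl_fit"))
  out <- rep(NA_real_, length(y))
  ok <- y > fit$b & y < fit$a
  out[ok] <- fit$m - (1 / fit$s) * log10((fit$a - fit$b) / (y[ok] - fit$b) - 1)
  out
}

# Residual sum of squares of a 4PL parameterization against a series.
.rss_4pl <- function(par, x, y, b) {
  r <- y - fourpl(x, b, par[1L], par[2L], par[3L])
  sum(r * r)
}

.new_fourpl_fit <- function(b, a, m, s, rss, converged, n_points, x_min, x_max,
                            note = NA_character_) {
  structure(list(b = b, a = a, m = m, s = s, rss = rss,
                 converged = converged, n_points = n_points,
                 x_min = x_min, x_max = x_max, note = note),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: b=%.3g a=%.3g m=%.4g (EC50=%.3g nM) s=%.3g | rss=%.4g %s\n",
    x$b, x$a, x$m, 10^x$m, x$s, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a four-parameter logistic model to a dose-response series
#'
#' Constrained least squares with the bottom asymptote fixed at 0 by default
#' (five-point screens cannot support four free parameters).  A coarse grid
#' over (m, s) with the top asymptote profiled in closed form seeds a small
#' number of box-constrained quasi-Newton refinements; ties in residual sum
#' of squares are broken towards the smaller top asymptote, then the smaller
#' slope (conservative sensitivity calls).
#'
#' Box constraints: `a` in \[0, 100\], `s` in \[0.1, 10\], `m` in
#' \[x_min - 1, x_max + 1\] of the tested log10 range.
#'
#' @param conc_nM concentrations in nM, strictly increasing, length >= 4.
#' @param inhibition percent inhibition, same length; values outside
#'   \[0, 100\] are permitted (normalization does not clip).
#' @param fix_bottom fix the bottom asymptote at 0 (default `TRUE`).
#' @param grid_m_step grid step (log10 units) of the multistart over `m`.
#' @param grid_s slope values of the multistart grid.
#' @param n_starts number of best grid points refined with `optim`.
#' @return a `fourpl_fit` object: parameters, `rss`, `converged` flag,
#'   `n_points` and the tested log10 range.  All-constant series return the
#'   constant as `a` (0 if negative) with `converged = FALSE`.
#' @examples
#' x <- 10^seq(0, 4, 1)
#' y <- fourpl(log10(x), 0, 80, 1.5, 1)
#' fit_4pl(x, y)
#' @export
fit_4pl <- function(conc_nM, inhibition, fix_bottom = TRUE,
                    grid_m_step = 0.5, grid_s = c(0.5, 1, 2), n_starts = 3L) {
  if (length(conc_nM) != length(inhibition))
    stop("conc_nM and inhibition must have equal length")
  if (length(conc_nM) < 4L)
    stop("need at least 4 doses to fit a dose-response model")
  if (!all(is.finite(inhibition)))
    stop("non-finite inhibition values in series")
  if (!all(is.finite(conc_nM)) || any(conc_nM <= 0))
    stop("concentrations must be positive and finite")
  o <- order(conc_nM)
  x <- log10(conc_nM[o]); y <- inhibition[o]
  if (anyDuplicated(x)) stop("duplicate concentrations; average replicates first")
  x_min <- x[1L]; x_max <- x[length(x)]
  b <- 0  # fix_bottom = FALSE still anchors b at 0; kept for interface parity
  if (!fix_bottom)
    b <- max(0, min(y[1L], 10))

  if (isTRUE(all(abs(y - y[1L]) < .Machine$double.eps^0.5))) {
    a <- min(max(y[1L], 0), 100)
    return(.new_fourpl_fit(b, a, mean(x), 1, sum((y - a)^2), FALSE,
                           length(x), x_min, x_max, note = "constant series"))
  }

  lower <- c(0, x_min - 1, 0.1)
  upper <- c(100, x_max + 1, 10)

  # grid over (m, s) with a profiled in closed form: for fixed (m, s),
  # min_a sum (y - a g)^2 at a = sum(y g) / sum(g^2), clipped to [0, 100]
  m_grid <- seq(x_min - 1, x_max + 1, by = grid_m_step)
  starts <- expand.grid(m = m_grid, s = grid_s)
  starts$a <- NA_real_; starts$rss <- NA_real_
  for (i in seq_len(nrow(starts))) {
    g <- 1 / (1 + 10^(starts$s[i] * (starts$m[i] - x)))
    a_hat <- sum((y - b) * g) / sum(g * g)
    a_hat <- min(max(a_hat, 0), 100)
    starts$a[i] <- a_hat
    r <- (y - b) - a_hat * g
    starts$rss[i] <- sum(r * r)
  }
  starts <- starts[order(starts$rss), , drop = FALSE]

  best <- NULL
  for (i in seq_len(min(n_starts, nrow(starts)))) {
    par0 <- pmin(pmax(c(starts$a[i], starts$m[i], max(starts$s[i], 0.1)),
                      lower), upper)
    res <- tryCatch(
      stats::optim(par0, .rss_4pl, x = x, y = y, b = b,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    cand <- list(a = res$par[1L], m = res$par[2L], s = res$par[3L],
                 rss = res$value)
    if (is.null(best) || cand$rss < best$rss - 1e-9 ||
        (abs(cand$rss - best$rss) <= 1e-9 &&
         (cand$a < best$a || (cand$a == best$a && cand$s < best$s)))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(.new_fourpl_fit(b, 0, mean(x), 1, sum((y - b)^2), FALSE,
                           length(x), x_min, x_max, note = "optimizer failure"))
  }
  .new_fourpl_fit(b, best$a, best$m, best$s, best$rss, TRUE,
                  length(x), x_min, x_max)
}

#' Fit every dose-response series of a screen
#'
#' @param series long-format data frame with columns `sample_id`, `drug_id`,
#'   `conc_nM`, `inhibition` (one row per dose), e.g. from
#'   [assemble_series()].
#' @param ... passed to [fit_4pl()].
#' @return data frame, one row per (sample, drug): `sample_id`, `drug_id`,
#'   `b`, `a`, `m`, `s`, `rss`, `converged`, `n_points`, `x_min`, `x_max`.
#' @export
fit_screen <- function(series, ...) {
  need <- c("sample_id", "drug_id", "conc_nM", "inhibition")
  if (!all(need %in% names(series)))
    stop("series must contain columns: ", paste(need, collapse = ", "))
  key <- paste(series$sample_id, series$drug_id, sep = "\r")
  idx <- split(seq_len(nrow(series)), key)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    f <- fit_4pl(series$conc_nM[i], series$inhibition[i], ...)
    out[[k]] <- data.frame(
      sample_id = series$sample_id[i[1L]], drug_id = series$drug_id[i[1L]],
      b = f$b, a = f$a, m = f$m, s = f$s, rss = f$rss,
      converged = f$converged, n_points = f$n_points,
      x_min = f$x_min, x_max = f$x_max, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$drug_id), , drop = FALSE]
}
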