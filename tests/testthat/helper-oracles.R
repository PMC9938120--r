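# Independent oracles and shared fixtures.  Oracles are deliberately
# naive (quadrature, double loops, closed forms) and never call the code
# paths they check.

# Adaptive-quadrature partial AUC of (min(y, ceiling) - t) over the DSS
# dose window; independent of the package's closed form.
pauc_quadrature <- function(b, a, m, s, t = 10, ceiling = 100,
                            x_min, x_max) {
  if (a <= t) return(0)
  xt <- m - (1 / s) * log10((a - b) / (t - b) - 1)
  x1 <- max(x_min, xt)
  if (x1 >= x_max) return(0)
  f <- function(x) pmin(b + (a - b) / (1 + 10^(s * (m - x))), ceiling) - t
  stats::integrate(f, x1, x_max, rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 500L)$value
}

# Brute-force TAS: double loop over targets and member drugs.
tas_bruteforce <- function(dss, membership) {
  out <- data.frame(target_id = character(0), tas = numeric(0),
                    n_t = integer(0), stringsAsFactors = FALSE)
  for (t in names(membership)) {
    tot <- 0; n <- 0L
    for (d in membership[[t]]) {
      if (d %in% names(dss) && !is.na(dss[[d]])) {
        tot <- tot + dss[[d]]; n <- n + 1L
      }
    }
    if (n > 0L)
      out <- rbind(out, data.frame(target_id = t, tas = tot / n, n_t = n,
                                   stringsAsFactors = FALSE))
  }
  out[order(out$target_id), , drop = FALSE]
}

# Closed-form Welch t and two-sided p.
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Classic one-way ANOVA F and p.
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); n <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Spearman rho via average ranks then Pearson.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Benjamini-Hochberg step-up from scratch.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Sort-based quantile with linear interpolation between order statistics
# (type 7).
quantile_oracle <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Mean silhouette width of the samples in `cluster` on a distance matrix.
silhouette_oracle <- function(d, labels, cluster) {
  d <- as.matrix(d)
  idx <- which(labels == cluster)
  vapply(idx, function(i) {
    a <- mean(d[i, setdiff(idx, i)])
    b <- min(vapply(setdiff(unique(labels), cluster), function(cl)
      mean(d[i, labels == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
}

# Hand-built converged fit object (bypasses the optimizer).
mk_fit <- function(a, m, s, b = 0, x_min = 0, x_max = 4,
                   converged = TRUE) {
  structure(list(b = b, a = a, m = m, s = s, rss = 0,
                 converged = converged, n_points = 5L,
                 x_min = x_min, x_max = x_max, note = NA),
            class = "fourpl_fit")
}

# Small screen fixture shared by several test files (patients with a
# serial pair, modest library, default noise).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_samples_per_subtype = c(HGSOC = 3L, LGSOC = 3L, MUCOC = 2L),
        serial_counts = list(LGSOC = c(2L, 1L, 1L)),
        n_drugs = 160L, seed = 7L)
      sim <- simulate_screen(cfg)
      norm <- normalize_plates(sim$wells)
      series <- assemble_series(norm$wells)
      fits <- fit_screen(series)
      dss <- dss_screen(fits)
      mat <- screen_matrix(dss, sim$samples, sim$library)
      cache <<- list(cfg = cfg, sim = sim, norm = norm, series = series,
                     fits = fits, dss = dss, mat = mat)
    }
    cache
  }
})
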