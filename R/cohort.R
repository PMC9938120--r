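# Cohort-level statistics on a samples-by-drugs DSS matrix: subtype group
# comparisons (Welch t, one-way ANOVA), pairwise subtype Spearman
# correlations, Ward/Euclidean clustering, PCA, and moderated-t
# differential drug sensitivity with Benjamini-Hochberg adjustment.

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-subtype group statistics
#'
#' With `level = "class"`, per-sample effective-drug fractions (from
#' [effectiveness_calls()]) are aggregated per subtype as mean +/- SEM for
#' the drug classes all / chemotherapy / targeted, with two-tailed Welch t
#' tests for each subtype pair and one-way ANOVA across the three
#' subtypes.  With `level = "drug"`, the same machinery runs on each
#' drug's DSS values.
#'
#' Groups of size < 2 yield `NA` statistics (undefined, never 0).
#'
#' @param mat a [screen_matrix()].
#' @param level `"class"` (effective fractions per drug class) or
#'   `"drug"` (per-drug DSS).
#' @param threshold effectiveness threshold used at `level = "class"`.
#' @param drugs drug ids to test at `level = "drug"` (default all).
#' @return list with `summary` (per unit x subtype: n, mean, sem),
#'   `pairwise` (Welch t per subtype pair) and `anova` (one-way ANOVA per
#'   unit).
#' @export
subtype_group_stats <- function(mat, level = c("class", "drug"),
                                threshold = 10, drugs = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(mat, "screen_matrix"))
  anno <- attr(mat, "sample_anno")
  subtype <- anno$subtype
  if (level == "class") {
    fr <- effectiveness_calls(mat, threshold = threshold)$fractions
    units <- split(fr, fr$class)
    values <- lapply(units, function(u) {
      stats::setNames(u$fraction, u$sample_id)[rownames(mat)]
    })
  } else {
    if (is.null(drugs)) drugs <- colnames(mat)
    values <- lapply(stats::setNames(drugs, drugs),
                     function(d) mat[, d])
  }
  summary <- list(); pairwise <- list(); anova <- list()
  subs <- sort(unique(subtype))
  for (u in names(values)) {
    v <- values[[u]]
    by_sub <- split(as.numeric(v), subtype)
    summary[[u]] <- data.frame(
      unit = u, subtype = names(by_sub),
      n = vapply(by_sub, length, 0L),
      mean = vapply(by_sub, mean, 0),
      sem = vapply(by_sub, function(g)
        if (length(g) >= 2L) .sem(g) else NA_real_, 0),
      stringsAsFactors = FALSE)
    if (length(subs) >= 2L) {
      prs <- utils::combn(subs, 2L, simplify = FALSE)
      pairwise[[u]] <- do.call(rbind, lapply(prs, function(pr) {
        g1 <- by_sub[[pr[1L]]]; g2 <- by_sub[[pr[2L]]]
        ok <- length(g1) >= 2L && length(g2) >= 2L &&
          (stats::sd(g1) > 0 || stats::sd(g2) > 0)
        tt <- if (ok) stats::t.test(g1, g2) else NULL
        data.frame(unit = u, group1 = pr[1L], group2 = pr[2L],
                   statistic = if (ok) unname(tt$statistic) else NA_real_,
                   p = if (ok) tt$p.value else NA_real_,
                   test = "welch_t", stringsAsFactors = FALSE)
      }))
    }
    if (length(subs) >= 3L &&
        all(vapply(by_sub, length, 0L) >= 2L) &&
        stats::sd(as.numeric(v)) > 0) {
      ow <- stats::oneway.test(val ~ grp,
                               data = data.frame(val = as.numeric(v),
                                                 grp = subtype),
                               var.equal = TRUE)
      anova[[u]] <- data.frame(unit = u,
                               statistic = unname(ow$statistic),
                               p = ow$p.value, test = "one_way_anova",
                               stringsAsFactors = FALSE)
    } else if (length(subs) >= 3L) {
      anova[[u]] <- data.frame(unit = u, statistic = NA_real_,
                               p = NA_real_, test = "one_way_anova",
                               stringsAsFactors = FALSE)
    }
  }
  nr <- function(x) { x <- do.call(rbind, x); rownames(x) <- NULL; x }
  list(summary = nr(summary), pairwise = nr(pairwise), anova = nr(anova))
}

#' Pairwise subtype correlation of average drug sensitivity
#'
#' Per-drug mean DSS is computed within each subtype; each subtype pair is
#' compared by Spearman rank correlation (average ranks for ties).
#' Constant mean vectors give `NA` with a flag.
#'
#' @param mat a [screen_matrix()].
#' @return data frame `group1`, `group2`, `rho`, `n_drugs`, `flag`.
#' @export
pairwise_subtype_correlation <- function(mat) {
  stopifnot(inherits(mat, "screen_matrix"))
  subtype <- attr(mat, "sample_anno")$subtype
  subs <- sort(unique(subtype))
  means <- vapply(subs, function(s)
    colMeans(mat[subtype == s, , drop = FALSE]), numeric(ncol(mat)))
  prs <- utils::combn(subs, 2L, simplify = FALSE)
  out <- lapply(prs, function(pr) {
    x <- means[, pr[1L]]; y <- means[, pr[2L]]
    if (length(x) < 3L)
      stop("need >= 3 shared drugs for a rank correlation")
    const <- stats::sd(x) == 0 || stats::sd(y) == 0
    data.frame(group1 = pr[1L], group2 = pr[2L],
               rho = if (const) NA_real_ else
                 stats::cor(x, y, method = "spearman"),
               n_drugs = length(x),
               flag = if (const) "constant_vector" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward/Euclidean hierarchical clustering of sample profiles
#'
#' Euclidean distances between DSS rows, Ward linkage (`ward.D2`, i.e.
#' squared-distance variance minimization).  `stats::hclust` breaks
#' distance ties deterministically by merge index, so leaf order is
#' reproducible.
#'
#' @param mat a [screen_matrix()]; missing values are an error.
#' @return an `hclust` object.
#' @export
cluster_samples <- function(mat) {
  stopifnot(inherits(mat, "screen_matrix"))
  if (anyNA(mat)) stop("missing values; impute or filter before clustering")
  stats::hclust(stats::dist(unclass(mat)), method = "ward.D2")
}

#' PCA projection of sample drug-response profiles
#'
#' Columns are centred and (by default) scaled to unit variance;
#' zero-variance columns are dropped with a message.  Component signs are
#' fixed so the largest-magnitude loading of each PC is positive.
#'
#' @param mat a [screen_matrix()] with >= 3 samples.
#' @param scale. scale columns to unit variance (default `TRUE`).
#' @param n_pc number of components to return (default 2).
#' @return list: `scores` (samples x PCs), `loadings`,
#'   `explained_variance` (fractions, non-increasing), `dropped` column
#'   names.
#' @export
pca_projection <- function(mat, scale. = TRUE, n_pc = 2L) {
  stopifnot(inherits(mat, "screen_matrix"))
  if (nrow(mat) < 3L) stop("need >= 3 samples for PCA")
  x <- unclass(mat)
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    message(length(dropped), " zero-variance drugs dropped before PCA")
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  n_pc <- min(n_pc, ncol(pc$x))
  flip <- vapply(seq_len(n_pc), function(k) {
    w <- pc$rotation[, k]
    sign(w[which.max(abs(w))])
  }, 0)
  scores <- sweep(pc$x[, seq_len(n_pc), drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(n_pc), drop = FALSE], 2L,
                    flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(n_pc)], dropped = dropped)
}

# Moment-matching fit of a scaled inverse-chi-square prior to per-drug
# sample variances s2 with df degrees of freedom each: under
# s2 ~ s0^2 F(df, d0), Var/Mean^2 = 2 (df + d0 - 2) / (df (d0 - 4)).
.squeeze_var <- function(s2, df) {
  m <- mean(s2); v <- stats::var(s2)
  if (!is.finite(v) || m <= 0) return(list(d0 = Inf, s02 = max(m, 0)))
  r <- v / m^2
  if (r * df <= 2) return(list(d0 = Inf, s02 = m))
  d0 <- (4 * r * df + 2 * df - 4) / (r * df - 2)
  if (!is.finite(d0) || d0 <= 0) return(list(d0 = Inf, s02 = m))
  s02 <- if (d0 > 2) m * (d0 - 2) / d0 else m
  list(d0 = d0, s02 = s02)
}

#' Differential drug sensitivity between two sample groups
#'
#' Per-drug mean DSS difference with an empirical-Bayes moderated t
#' statistic: per-drug pooled variances are shrunk towards a prior
#' variance `s0^2` with `d0` prior degrees of freedom estimated from the
#' variance distribution by moment matching, and p-values use
#' `d0 + d` degrees of freedom.  Plain Welch t is available as an
#' alternative.  Drugs enter the analysis when their DSS reaches
#' `include_threshold` in at least `include_min_samples` of the compared
#' samples; Benjamini-Hochberg adjustment runs across the included drugs.
#'
#' @param mat a [screen_matrix()].
#' @param groupA,groupB character vectors of sample ids (>= 2 each).
#' @param include_threshold inclusion filter on DSS (default 10).
#' @param include_min_samples samples that must pass the filter
#'   (default 1).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data frame sorted by p: `drug_id`, `effect`
#'   (`mean(A) - mean(B)`), `t`, `df`, `p`, `q`; attributes `d0`, `s02`,
#'   `n_included`.
#' @export
differential_sensitivity <- function(mat, groupA, groupB,
                                     include_threshold = 10,
                                     include_min_samples = 1L,
                                     method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(mat, "screen_matrix"))
  if (!all(c(groupA, groupB) %in% rownames(mat)))
    stop("unknown sample ids in groups")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need >= 2 samples per group")
  A <- mat[groupA, , drop = FALSE]
  B <- mat[groupB, , drop = FALSE]
  both <- rbind(A, B)
  keep <- colSums(both >= include_threshold) >= include_min_samples
  if (!any(keep)) {
    warning("inclusion filter removed all drugs")
    return(data.frame(drug_id = character(0), effect = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  effect <- colMeans(A) - colMeans(B)
  if (method == "moderated") {
    df <- nA + nB - 2
    s2 <- (apply(A, 2L, stats::var) * (nA - 1) +
             apply(B, 2L, stats::var) * (nB - 1)) / df
    sq <- .squeeze_var(s2, df)
    s2_post <- if (is.finite(sq$d0))
      (sq$d0 * sq$s02 + df * s2) / (sq$d0 + df) else sq$s02
    tstat <- effect / sqrt(s2_post * (1 / nA + 1 / nB))
    df_tot <- df + sq$d0
    p <- 2 * stats::pt(-abs(tstat),
                       df = if (is.finite(df_tot)) df_tot else Inf)
    # zero-variance, zero-effect drugs are exact ties: p = 1
    p[effect == 0 & s2_post == 0] <- 1
    tstat[effect == 0] <- 0
    out <- data.frame(drug_id = colnames(A), effect = effect, t = tstat,
                      df = if (is.finite(df_tot)) df_tot else Inf, p = p,
                      stringsAsFactors = FALSE)
    attr(out, "d0") <- sq$d0; attr(out, "s02") <- sq$s02
  } else {
    res <- lapply(seq_len(ncol(A)), function(j) {
      ok <- stats::sd(A[, j]) > 0 || stats::sd(B[, j]) > 0
      tt <- if (ok) stats::t.test(A[, j], B[, j]) else NULL
      data.frame(drug_id = colnames(A)[j], effect = effect[j],
                 t = if (ok) unname(tt$statistic) else 0,
                 df = if (ok) unname(tt$parameter) else NA_real_,
                 p = if (ok) tt$p.value else 1, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_included") <- sum(keep)
  out
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return the Hubert-Arabie adjusted Rand index (1 for identical
#'   partitions, ~0 for independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
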