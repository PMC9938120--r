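# Cohort statistics: group comparisons, correlations, clustering, PCA,
# differential sensitivity.

mk_matrix <- function(values, subtypes, n_drugs = ncol(values)) {
  samples <- sprintf("S%02d", seq_len(nrow(values)))
  drugs <- sprintf("D%03d", seq_len(n_drugs))
  dss <- data.frame(sample_id = rep(samples, n_drugs),
                    drug_id = rep(drugs, each = nrow(values)),
                    dss = as.numeric(values), stringsAsFactors = FALSE)
  anno <- data.frame(sample_id = samples,
                     patient_id = samples, subtype = subtypes,
                     serial_index = 1, stringsAsFactors = FALSE)
  lib <- data.frame(drug_id = drugs, class = "targeted",
                    stringsAsFactors = FALSE)
  screen_matrix(dss, anno, lib)
}

test_that("group summaries report mean +/- SEM and handle tiny groups", {
  m <- mk_matrix(matrix(c(10, 20, 30, 0, 0, 5), ncol = 1),
                 c("LGSOC", "LGSOC", "LGSOC", "HGSOC", "HGSOC", "MUCOC"))
  gs <- subtype_group_stats(m, level = "drug")
  sm <- gs$summary
  expect_equal(sm$mean[sm$subtype == "LGSOC"], 20)
  expect_equal(sm$sem[sm$subtype == "LGSOC"], 10 / sqrt(3),
               tolerance = 1e-12)
  # group of size 1: statistics undefined, not zero
  expect_true(is.na(sm$sem[sm$subtype == "MUCOC"]))
  pw <- gs$pairwise
  expect_true(is.na(pw$p[pw$group1 == "HGSOC" & pw$group2 == "MUCOC"]))
})

test_that("Welch t matches its closed form and degenerates sensibly", {
  x <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  y <- c(0.5, 0.6, 0.55, 0.65)
  m <- mk_matrix(matrix(c(x, y) * 100, ncol = 1),
                 rep(c("HGSOC", "LGSOC"), c(5, 4)))
  pw <- subtype_group_stats(m, level = "drug")$pairwise
  want <- welch_oracle(x * 100, y * 100)
  expect_equal(pw$statistic, want$t, tolerance = 1e-10)
  expect_equal(pw$p, want$p, tolerance = 1e-10)
  # identical distributions: t = 0, p = 1
  m2 <- mk_matrix(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1),
                  rep(c("HGSOC", "LGSOC"), each = 3))
  pw2 <- subtype_group_stats(m2, level = "drug")$pairwise
  expect_equal(pw2$statistic, 0)
  expect_equal(pw2$p, 1)
  # near-separated groups reject
  m3 <- mk_matrix(matrix(c(0.01, -0.02, 0.02, 10.01, 9.98, 10.02),
                         ncol = 1), rep(c("HGSOC", "LGSOC"), each = 3))
  expect_lt(subtype_group_stats(m3, level = "drug")$pairwise$p[1], 0.01)
})

test_that("one-way ANOVA matches its closed form", {
  v <- c(1, 2, 3, 6, 7, 8, 2, 4, 9)
  g <- rep(c("HGSOC", "LGSOC", "MUCOC"), each = 3)
  m <- mk_matrix(matrix(v, ncol = 1), g)
  an <- subtype_group_stats(m, level = "drug")$anova
  want <- anova_oracle(v, g)
  expect_equal(an$statistic, want$f, tolerance = 1e-10)
  expect_equal(an$p, want$p, tolerance = 1e-10)
})

test_that("pairwise subtype correlations are Spearman on per-drug means", {
  set.seed(41)
  v <- matrix(rnorm(4 * 30, 10, 4), nrow = 4)
  m <- mk_matrix(v, c("LGSOC", "LGSOC", "HGSOC", "HGSOC"))
  out <- pairwise_subtype_correlation(m)
  muL <- colMeans(v[1:2, ]); muH <- colMeans(v[3:4, ])
  expect_equal(out$rho, spearman_oracle(muH, muL), tolerance = 1e-12)
  # identical mean vectors -> rho = 1; reversed ranks -> rho = -1
  m1 <- mk_matrix(rbind(1:10, 1:10), c("LGSOC", "HGSOC"))
  expect_equal(pairwise_subtype_correlation(m1)$rho, 1)
  m2 <- mk_matrix(rbind(1:10, 10:1), c("LGSOC", "HGSOC"))
  expect_equal(pairwise_subtype_correlation(m2)$rho, -1)
  # constant vector flagged, not fabricated
  m3 <- mk_matrix(rbind(rep(5, 10), 1:10), c("LGSOC", "HGSOC"))
  out3 <- pairwise_subtype_correlation(m3)
  expect_true(is.na(out3$rho))
  expect_identical(out3$flag, "constant_vector")
})

test_that("clustering merges duplicates first; PCA fixes signs and order", {
  set.seed(42)
  v <- matrix(rnorm(5 * 40, 10, 3), nrow = 5)
  v[2, ] <- v[1, ]                      # exact duplicate pair
  m <- mk_matrix(v, c(rep("LGSOC", 2), rep("HGSOC", 3)))
  hc <- cluster_samples(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  pc <- pca_projection(m)
  expect_equal(pc$scores[1, ], pc$scores[2, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # duplicated drug column with zero variance is dropped with a message
  v2 <- cbind(v, 7)
  expect_message(pca_projection(mk_matrix(v2, c(rep("LGSOC", 2),
                                                rep("HGSOC", 3)))),
                 "zero-variance")
})

test_that("differential sensitivity: nulls, planted shift, BH oracle", {
  set.seed(43)
  base <- matrix(rnorm(10 * 50, 12, 2), nrow = 10)
  groups <- rep(c("LGSOC", "HGSOC"), each = 5)
  # identical groups: all effects 0, all q = 1
  same <- base; same[6:10, ] <- same[1:5, ]
  m0 <- mk_matrix(same, groups)
  v0 <- differential_sensitivity(m0, sprintf("S%02d", 1:5),
                                 sprintf("S%02d", 6:10))
  expect_true(all(abs(v0$effect) < 1e-12))
  expect_true(all(v0$q == 1))
  # +20 DSS shift in group A tops the ranking
  shifted <- base; shifted[1:5, 7] <- shifted[1:5, 7] + 20
  m1 <- mk_matrix(shifted, groups)
  v1 <- differential_sensitivity(m1, sprintf("S%02d", 1:5),
                                 sprintf("S%02d", 6:10))
  expect_identical(v1$drug_id[which.max(abs(v1$t))], "D007")
  expect_identical(v1$drug_id[1], "D007")   # sorted by p
  # BH on fixed p-values
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(v1$q, bh_oracle(v1$p), tolerance = 1e-10)
  # inclusion filter: drugs never reaching the threshold are absent
  low <- base; low[, 3] <- 1
  m2 <- mk_matrix(low, groups)
  v2 <- differential_sensitivity(m2, sprintf("S%02d", 1:5),
                                 sprintf("S%02d", 6:10))
  expect_false("D003" %in% v2$drug_id)
  expect_warning(
    differential_sensitivity(m2, sprintf("S%02d", 1:5),
                             sprintf("S%02d", 6:10),
                             include_threshold = 1e6),
    "filter")
})

test_that("moderated t reduces to the pooled-variance form when d0 = 0-ish", {
  # two-group balanced data: the moderated statistic with finite d0 shrinks
  # towards s0; with identical per-drug variances, moment matching yields a
  # large d0 and the statistic matches the classic pooled t closely
  set.seed(44)
  v <- matrix(rnorm(8 * 40, 15, 3), nrow = 8)
  m <- mk_matrix(v, rep(c("LGSOC", "HGSOC"), each = 4))
  out <- differential_sensitivity(m, sprintf("S%02d", 1:4),
                                  sprintf("S%02d", 5:8),
                                  include_threshold = 0)
  for (d in out$drug_id[1:5]) {
    j <- as.integer(sub("D", "", d))
    x <- v[1:4, j]; y <- v[5:8, j]
    sp2 <- (3 * var(x) + 3 * var(y)) / 6
    t_pool <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 2))
    t_mod <- out$t[out$drug_id == d]
    expect_equal(sign(t_mod), sign(t_pool))
    expect_lt(abs(t_mod - t_pool) / abs(t_pool), 0.6)
  }
})

test_that("adjusted Rand index: identical, permuted labels, independence", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(rep("x", 10), rep("y", 10),
                                        rep("z", 10))), 1)
  set.seed(45)
  r <- replicate(50, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(r)), 0.1)
})
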