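# DSS scoring: closed form vs quadrature, boundary behaviour,
# monotonicity/invariance, selective DSS, effectiveness calls.

test_that("flat, inactive and threshold-level curves score zero", {
  cfg <- dss_config()
  expect_identical(compute_dss(mk_fit(0.5, 2, 1), cfg)$dss, 0)
  expect_identical(compute_dss(mk_fit(10, 2, 1), cfg)$dss, 0)   # a = t
  expect_identical(compute_dss(mk_fit(80, 2, 1, converged = FALSE),
                               cfg)$dss, 0)
  # threshold reached only beyond the tested range
  expect_identical(compute_dss(mk_fit(60, 8, 1), cfg)$dss, 0)
})

test_that("a saturating curve approaches DSS1 = 100 and DSS3 = 50", {
  d <- compute_dss(mk_fit(100, -8, 1), dss_config())
  expect_equal(d$dss1, 100, tolerance = 1e-4)
  expect_equal(d$dss3, 50, tolerance = 1e-4)
  expect_equal(d$x1, 0)
  expect_equal(d$x2, 4)
})

test_that("closed-form partial AUC matches adaptive quadrature", {
  set.seed(11)
  for (k in 1:200) {
    a <- runif(1, 11, 100); m <- runif(1, -1, 5); s <- runif(1, 0.3, 5)
    d <- compute_dss(mk_fit(a, m, s), dss_config())
    I <- pauc_quadrature(0, a, m, s, x_min = 0, x_max = 4)
    if (I > 0) expect_lt(abs(d$pauc - I) / I, 1e-6)
    else expect_identical(d$dss, 0)
  }
})

test_that("DSS is monotone in the asymptote and the log-EC50", {
  set.seed(12)
  for (k in 1:30) {
    m <- runif(1, 0, 4); s <- runif(1, 0.4, 3)
    dss_a <- vapply(seq(12, 100, length.out = 15), function(a)
      compute_dss(mk_fit(a, m, s), dss_config())$dss, 0)
    expect_true(all(diff(dss_a) >= -1e-10))
    d1_a <- vapply(seq(12, 100, length.out = 15), function(a)
      compute_dss(mk_fit(a, m, s), dss_config())$dss1, 0)
    expect_true(all(diff(d1_a) >= -1e-10))
    a <- runif(1, 30, 100)
    dss_m <- vapply(seq(-1, 5, length.out = 15), function(m2)
      compute_dss(mk_fit(a, m2, s), dss_config())$dss, 0)
    expect_true(all(diff(dss_m) <= 1e-10))
  }
  # DSS1 bounded in [0, 100]
  set.seed(13)
  for (k in 1:50) {
    d <- compute_dss(mk_fit(runif(1, 1, 100), runif(1, -2, 6),
                            runif(1, 0.2, 8)), dss_config())
    expect_gte(d$dss1, 0); expect_lte(d$dss1, 100)
  }
})

test_that("DSS is invariant under joint concentration-unit rescaling", {
  set.seed(14)
  for (k in 1:20) {
    a <- runif(1, 15, 100); m <- runif(1, 0, 4); s <- runif(1, 0.4, 3)
    shift <- 3  # nM -> pM
    d1 <- compute_dss(mk_fit(a, m, s), dss_config())
    d2 <- compute_dss(mk_fit(a, m + shift, s, x_min = shift,
                             x_max = 4 + shift), dss_config())
    expect_equal(d1$dss, d2$dss, tolerance = 1e-9)
    expect_equal(d2$x1 - d1$x1, shift, tolerance = 1e-9)
  }
})

test_that("selective DSS subtracts the control-donor mean", {
  dss <- data.frame(sample_id = "S1", drug_id = c("D1", "D2", "D3"),
                    dss = c(15, 8, 12), stringsAsFactors = FALSE)
  ctrl <- data.frame(donor_id = rep(c("HC1", "HC2"), each = 2),
                     drug_id = c("D1", "D2", "D1", "D2"),
                     dss = c(5, 8, 5, 8), stringsAsFactors = FALSE)
  out <- selective_dss(dss, ctrl)
  expect_equal(out$sdss[1], 10)
  expect_equal(out$sdss[2], 0)
  expect_true(is.na(out$sdss[3]))
  expect_identical(attr(out, "missing_controls"), "D3")
  # a sample identical to a sole control scores 0 everywhere
  sole <- data.frame(donor_id = "HC1", drug_id = dss$drug_id,
                     dss = dss$dss, stringsAsFactors = FALSE)
  expect_equal(selective_dss(dss, sole)$sdss, c(0, 0, 0))
})

test_that("effectiveness fractions count threshold calls per class", {
  dss <- expand.grid(sample_id = c("S1", "S2"),
                     drug_id = sprintf("D%02d", 1:20),
                     stringsAsFactors = FALSE)
  dss$dss <- 0
  dss$dss[dss$sample_id == "S1" & dss$drug_id %in%
            c("D01", "D02", "D03")] <- 15
  anno <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
                     subtype = c("LGSOC", "HGSOC"), serial_index = 1,
                     stringsAsFactors = FALSE)
  lib <- data.frame(drug_id = sprintf("D%02d", 1:20),
                    class = rep(c("chemotherapy", "targeted"), each = 10),
                    stringsAsFactors = FALSE)
  mat <- screen_matrix(dss, anno, lib)
  eff <- effectiveness_calls(mat)
  fr <- eff$fractions
  expect_equal(fr$fraction[fr$sample_id == "S1" & fr$class == "all"], 0.15)
  expect_equal(fr$fraction[fr$sample_id == "S1" &
                             fr$class == "chemotherapy"], 0.3)
  expect_equal(fr$fraction[fr$sample_id == "S1" & fr$class == "targeted"],
               0)
  expect_true(all(fr$fraction[fr$sample_id == "S2"] == 0))
  # unknown class errors
  lib2 <- lib; lib2$class[1] <- "hormonal"
  expect_error(effectiveness_calls(screen_matrix(dss, anno, lib2)),
               "class")
})

test_that("the pooled 85% quantile matches a sorting oracle", {
  set.seed(15)
  x <- c(rexp(170, 1 / 4), runif(30, 10, 35))
  dss <- data.frame(sample_id = rep(c("S1", "S2"), each = 100),
                    drug_id = rep(sprintf("D%03d", 1:100), 2),
                    dss = x, stringsAsFactors = FALSE)
  anno <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
                     subtype = c("LGSOC", "HGSOC"), serial_index = 1,
                     stringsAsFactors = FALSE)
  lib <- data.frame(drug_id = sprintf("D%03d", 1:100), class = "targeted",
                    stringsAsFactors = FALSE)
  eff <- effectiveness_calls(screen_matrix(dss, anno, lib))
  expect_equal(eff$pooled_q85, quantile_oracle(x, 0.85),
               tolerance = 1e-12)
})

test_that("replicate and serial profiles correlate as the noise model implies", {
  ts <- tiny_sim()
  mat <- ts$mat
  anno <- attr(mat, "sample_anno")
  cors <- cor(t(unclass(mat)), method = "pearson")
  serial <- anno$sample_id[anno$patient_id == "P04"]
  serial_r <- cors[serial[1], serial[2]]
  expect_gt(serial_r, 0.9)
  cross <- cors[anno$patient_id != "P04", anno$patient_id != "P04"]
  diag(cross) <- NA
  expect_gt(serial_r, max(cross, na.rm = TRUE))
})
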