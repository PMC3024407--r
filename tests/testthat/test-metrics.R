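test_that("peak factor is the ratio of velocity ranges", {
  expect_equal(peak_factor(10, 10), 1.0)
  expect_equal(peak_factor(10, 5), 0.5)
  expect_equal(peak_factor(-8, -4), 0.5)
  expect_warning(pf0 <- peak_factor(0, 5), "undefined")
  expect_true(is.na(pf0))
})

test_that("nRMSD matches the direct formula and is symmetric", {
  u <- c(1, 2, 3); w <- u
  expect_equal(nrmsd(u, w, 10), 0)
  expect_equal(nrmsd(u, u + 1, 10), 0.1)
  set.seed(7)
  u <- rnorm(500); w <- rnorm(500)
  direct <- sqrt(sum((u - w)^2) / 500) / abs(3.2)   # element-wise oracle
  expect_equal(nrmsd(u, w, 3.2), direct, tolerance = 1e-12)
  expect_equal(nrmsd(u, w, 3.2), nrmsd(w, u, 3.2))
  expect_equal(nrmsd(u, w, -3.2), nrmsd(u, w, 3.2))
  expect_error(nrmsd(u, w[-1], 1), "grids")
  expect_error(nrmsd(u, w, 0), "zero")
})

test_that("curve correlation is normalized Pearson", {
  u <- c(1, 2, 3, 4)
  expect_equal(curve_correlation(u, u), 1.0)
  expect_equal(curve_correlation(u, -u), -1.0)
  w <- c(1, 2, 2, 5)
  # brute-force normalized cross-sum oracle
  oracle <- sum(((u - mean(u)) / sd(u)) * ((w - mean(w)) / sd(w))) /
    (length(u) - 1)
  expect_equal(curve_correlation(u, w), oracle, tolerance = 1e-12)
  # invariant under positive affine transforms of either input
  set.seed(8)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(curve_correlation(2.5 * a + 7, b),
               curve_correlation(a, b), tolerance = 1e-12)
  expect_error(curve_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Bland-Altman statistics follow the seq2 - seq1 convention", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  ba <- bland_altman(c(0, 0), c(1, 3))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_upper, 2 + 1.96 * sqrt(2))
  # swapping the sequences negates the mean and keeps the spread
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(bland_altman(y, x)$mean_diff, -bland_altman(x, y)$mean_diff)
  expect_equal(bland_altman(y, x)$sd_diff, bland_altman(x, y)$sd_diff)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("pooled t-test matches the textbook formula", {
  t0 <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)
  tshift <- pooled_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(tshift$p_value, 0.05)
  set.seed(10)
  a <- rnorm(8); b <- rnorm(11, mean = 0.4)
  got <- pooled_t_test(a, b)
  sp2 <- ((8 - 1) * var(a) + (11 - 1) * var(b)) / (8 + 11 - 2)
  t_direct <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 11))
  p_direct <- 2 * pt(-abs(t_direct), df = 8 + 11 - 2)
  expect_equal(got$t, t_direct, tolerance = 1e-10)
  expect_equal(got$p_value, p_direct, tolerance = 1e-10)
  expect_equal(got$df, 17)
})

test_that("cohort summary aggregates and tests against the reference arm", {
  one <- tibble::tibble(
    arm = c("ref", "kt2"), direction = "radial",
    pf = c(1.0, 0.8), nrmsd = c(0.04, 0.09), corr = c(0.99, 0.95),
    dv_diff = c(0.1, 1.2), dt_dias_ms = c(1, 6)
  )
  results <- dplyr::bind_rows(lapply(1:5, function(s)
    dplyr::mutate(one, subject = s)))
  tab <- summarize_cohort(results)
  # duplicated subjects: sd is zero everywhere, means equal the inputs
  expect_true(all(tab$sd == 0))
  pf_kt2 <- dplyr::filter(tab, metric == "pf", arm == "kt2")
  expect_equal(pf_kt2$mean, 0.8)
  expect_true(all(is.na(dplyr::filter(tab, arm == "ref")$p_value)))
  # degenerate equal groups give p = 1
  same <- dplyr::mutate(results, pf = 1, nrmsd = 1, corr = 1,
                        dv_diff = 1, dt_dias_ms = 1)
  tab_same <- summarize_cohort(same)
  expect_true(all(tab_same$p_value[tab_same$arm != "ref"] == 1))
  # Bland-Altman columns only for the difference metrics
  expect_true(all(is.na(dplyr::filter(tab, metric == "pf")$loa_lower)))
  ba <- dplyr::filter(tab, metric == "dv_diff", arm == "kt2")
  expect_equal(ba$loa_upper, ba$mean + 1.96 * ba$sd)
})

test_that("cohort tables match an independent recomputation", {
  set.seed(11)
  results <- tidyr::expand_grid(subject = 1:6, arm = c("ref", "kt2", "kt4"),
                                direction = c("radial", "longitudinal")) |>
    dplyr::mutate(pf = rnorm(dplyr::n(), 0.9, 0.1),
                  nrmsd = abs(rnorm(dplyr::n(), 0.1, 0.03)),
                  corr = runif(dplyr::n(), 0.8, 1),
                  dv_diff = rnorm(dplyr::n()),
                  dt_dias_ms = rnorm(dplyr::n(), 0, 5))
  tab <- summarize_cohort(results)
  for (mm in c("pf", "nrmsd")) for (aa in c("kt2", "kt4")) {
    sel <- results[results$arm == aa & results$direction == "radial", mm,
                   drop = TRUE]
    ref <- results[results$arm == "ref" & results$direction == "radial", mm,
                   drop = TRUE]
    row <- dplyr::filter(tab, metric == mm, arm == aa,
                         direction == "radial")
    expect_equal(row$mean, mean(sel))
    expect_equal(row$sd, sd(sel))
    expect_equal(row$p_value, t.test(ref, sel, var.equal = TRUE)$p.value)
  }
})
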