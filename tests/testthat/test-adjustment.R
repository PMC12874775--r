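# Selection/spillover toolkit: stabilised IPW, balance diagnostics,
# leave-one-out community intensity, and the community-block bootstrap.

test_that("stabilised weights are flat under null confounding and average to one", {
  panel <- generate_panel(synthetic_config(n_units = 2000, seed = 14))
  cov0 <- baseline_covariates(panel, smd_target = 0, seed = 1)
  ws <- stabilized_ipw(cov0[, -(1:2)], cov0$participation)
  # the maximum deviation over units is an extreme-value statistic driven by
  # covariate outliers even under null confounding, so the flatness check is
  # on the distribution: unit mean, small spread, bulk within 0.1 of 1
  expect_within(mean(ws$weights), 1, 0.02)
  expect_lt(stats::sd(ws$weights), 0.1)
  expect_lt(stats::median(abs(ws$weights - 1)), 0.1)
  # mean-one property at larger n
  panel5 <- generate_panel(synthetic_config(n_units = 5000, seed = 15))
  cov5 <- baseline_covariates(panel5, smd_target = 0.18, seed = 2)
  ws5 <- stabilized_ipw(cov5[, -(1:2)], cov5$participation)
  expect_within(mean(ws5$weights), 1, 0.05)
  expect_true(all(ws5$weights > 0))
})

test_that("weights match hand-computed frequency ratios in a 2x2 design", {
  x <- c(rep(0, 60), rep(1, 40))
  a <- c(rep(1, 30), rep(0, 30), rep(1, 10), rep(0, 30))
  ws <- stabilized_ipw(data.frame(x = x), a)
  # P(A=1) = 0.4; P(A=1|x=0) = 0.5; P(A=1|x=1) = 0.25
  expect_equal(unname(ws$weights[1]), 0.4 / 0.5, tolerance = 1e-6)
  expect_equal(unname(ws$weights[31]), 0.6 / 0.5, tolerance = 1e-6)
  expect_equal(unname(ws$weights[61]), 0.4 / 0.25, tolerance = 1e-6)
  expect_equal(unname(ws$weights[71]), 0.6 / 0.75, tolerance = 1e-6)
  expect_error(stabilized_ipw(data.frame(x = x), rep(1, 100)),
               "both participation classes")
  # perfect separation is refused with advice
  expect_error(stabilized_ipw(data.frame(x = c(rep(0, 20), rep(1, 20))),
                              c(rep(0L, 20), rep(1L, 20))), "separation")
})

test_that("weighting improves covariate balance on confounded data", {
  better <- 0
  for (seed in 1:10) {
    panel <- generate_panel(synthetic_config(n_units = 1500, seed = seed))
    cov <- baseline_covariates(panel, smd_target = 0.25, seed = seed)
    ws <- stabilized_ipw(cov[, -(1:2)], cov$participation)
    raw <- max(abs(balance_smd(cov[, -(1:2)], cov$participation)$smd))
    wtd <- max(abs(balance_smd(cov[, -(1:2)], cov$participation,
                               weights = ws$weights)$smd))
    if (wtd <= raw) better <- better + 1
  }
  expect_gte(better, 10 - 1)
})

test_that("standardised mean differences follow their definition", {
  g <- c(1, 1, 0, 0)
  same <- data.frame(x = c(2, 4, 2, 4))
  expect_equal(balance_smd(same, g)$smd, 0)
  unit <- data.frame(x = c(1 - sqrt(0.5), 1 + sqrt(0.5),
                           0 - sqrt(0.5), 0 + sqrt(0.5)))
  expect_equal(balance_smd(unit, g)$smd, 1, tolerance = 1e-12)
  degen <- data.frame(x = c(1, 1, 1, 1))
  out <- balance_smd(degen, g)
  expect_true(out$degenerate)
  expect_true(is.na(out$smd))
})

test_that("leave-one-out community intensity equals a brute-force recount", {
  d <- data.frame(
    unit_id = 1:12,
    community_id = c(rep("a", 5), rep("b", 6), "c"),
    wave = "2009",
    PS = c("P", "C", "E", "C", "C",  "C", "C", "H", "PEH", "C", "P",  "C"),
    stringsAsFactors = FALSE)
  schema <- list(PS = var_schema("ordinal",
                                 levels = colnames(table1_fixture()$margins)))
  panel <- panel_dataset(d, schema, waves = "2009")
  cpi <- cpi_leave_one_out(panel, "2009")
  # unit 2 (control, community a): 2 of its 4 neighbours participate
  expect_equal(cpi$cpi[cpi$unit_id == 2], 0.5)
  # singleton community is flagged missing
  expect_true(is.na(cpi$cpi[cpi$unit_id == 12]))
  # brute-force recount over every unit
  for (i in seq_len(nrow(d))) {
    others <- d[d$community_id == d$community_id[i] & d$unit_id != d$unit_id[i], ]
    expected <- if (nrow(others) == 0) NA_real_ else mean(others$PS != "C")
    expect_equal(cpi$cpi[cpi$unit_id == d$unit_id[i]], expected)
  }
  # all-others-participate edge case
  d2 <- d; d2$PS <- "P"; d2$PS[1] <- "C"
  cpi2 <- cpi_leave_one_out(panel_dataset(d2, schema, waves = "2009"), "2009")
  expect_equal(cpi2$cpi[cpi2$unit_id == 1], 1.0)
  expect_error(cpi_leave_one_out(panel, "2009", "nope"), "unknown program")
})

test_that("community-block bootstrap is reproducible with sane intervals", {
  panel <- generate_panel(synthetic_config(n_units = 400, seed = 19))
  const <- function(p) 7
  bc <- community_block_bootstrap(panel, const, B = 100, seed = 1)
  expect_equal(unname(bc$ci), c(7, 7))
  expect_equal(bc$point, 7)
  stat <- function(p) tau_trajectory(p, c("PS", "FS"), waves = "2013")$tau
  b1 <- community_block_bootstrap(panel, stat, B = 120, seed = 9)
  b2 <- community_block_bootstrap(panel, stat, B = 120, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$ci[1] <= b1$point && b1$point <= b1$ci[2])
})

test_that("unit weights reproduce the unweighted tau through the panel path", {
  panel <- generate_panel(single_edge_config(c(0.4, 0.5, 0.6), n_units = 400,
                                             seed = 23))
  ids <- unique(panel$data$unit_id)
  w1 <- stats::setNames(rep(1, length(ids)), ids)
  expect_equal(tau_trajectory(panel, c("PS", "FS"), weights = w1)$tau,
               tau_trajectory(panel, c("PS", "FS"))$tau, tolerance = 1e-12)
})
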