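# Regression, implementation-cell classifiers, power-model translation and
# the spill-over linearity summary.

random_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sec_type = sample(rep(c("FIX1", "FIX2", "FIX3", "P2P"), length.out = n)),
    demand_vph = sample(seq(500, 3500, 500), n, replace = TRUE),
    pct_B = runif(n, 10, 50), pct_C = runif(n, 1, 5),
    telematics_pct = runif(n, 0, 10))
}

test_that("OLS fit equals an independent normal-equations solve", {
  for (s in 1:100) {
    d <- random_design(50, seed = 1000 + s)
    d$rud_pct <- runif(50, 0, 40)
    fit <- fit_rud_regression(d)
    # oracle: solve the normal equations directly
    X <- cbind(1, d$sec_type == "FIX2", d$sec_type == "FIX3",
               d$sec_type == "P2P", d$demand_vph / 1000, d$pct_B, d$pct_C,
               d$telematics_pct)
    beta <- solve(crossprod(X), crossprod(X, d$rud_pct))
    expect_equal(unname(fit$table$coefficient), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("regression recovers known effects from synthetic RUD data", {
  d <- random_design(2000, seed = 7)
  set.seed(8)
  d$rud_pct <- 5 - 0.3 * d$telematics_pct + rnorm(2000, sd = 0.01)
  fit <- fit_rud_regression(d)
  tel <- fit$table[fit$table$variable == "telematics_pct", ]
  expect_gt(tel$coefficient, -0.31)
  expect_lt(tel$coefficient, -0.29)
  expect_lt(abs(tel$coefficient + 0.3), 2 * tel$se)
  # confidence interval is coefficient +/- 1.96 SE
  expect_equal(tel$ci_low, tel$coefficient - qnorm(0.975) * tel$se)

  # noise-free linear data fits perfectly
  d2 <- random_design(500, seed = 9)
  d2$rud_pct <- 10 + 2 * (d2$sec_type == "P2P") - 0.5 * d2$demand_vph / 1000 +
    0.4 * d2$pct_B
  # summary.lm warns about the (intentionally) perfect fit
  fit2 <- suppressWarnings(fit_rud_regression(d2))
  expect_equal(fit2$adj_r_squared, 1, tolerance = 1e-9)
})

test_that("a rank-deficient design is rejected naming the collinear column", {
  d <- random_design(50, seed = 11)
  d$demand_vph <- 1000  # constant: collinear with the intercept
  d$rud_pct <- runif(50)
  expect_error(fit_rud_regression(d), "collinear.*demand_per_1000vph")
  expect_error(fit_rud_regression(d[, -1]), "missing columns")
})

test_that("community, traffic and telematics classifiers match the bins", {
  expect_equal(classify_community(15, 1), "law-abiding")
  expect_equal(classify_community(40, 3), "law-avoiding")
  expect_equal(classify_community(25, 5), "law-carefree")
  expect_equal(classify_community(25, 3), "average")
  expect_true(is.na(classify_community(50, 5)))
  expect_true(is.na(classify_community(30, 1)))
  # boundary ties resolve deterministically
  expect_equal(classify_community(c(20, 30), c(3, 3)), rep("average", 2))
  expect_equal(classify_community(20, 2), "law-abiding")

  expect_equal(classify_traffic(c(500, 1000, 1500)), rep("low", 3))
  expect_equal(classify_traffic(c(2500, 3000, 3500)), rep("moderate", 3))
  expect_true(is.na(classify_traffic(2000)))

  expect_equal(classify_telematics(0), "none")
  expect_equal(classify_telematics(9), "enforcement")
  expect_true(is.na(classify_telematics(5)))
})

test_that("crash relative risk is the cubed speed ratio", {
  expect_equal(crash_relative_risk(90, 90)$relative_risk, 1)
  expect_equal(crash_relative_risk(90, 90)$pct_change, 0)
  r <- crash_relative_risk(100, 90)
  expect_equal(r$relative_risk, 0.729, tolerance = 1e-12)
  expect_equal(r$pct_change, -27.1, tolerance = 1e-12)
  r2 <- crash_relative_risk(80, 88)
  expect_equal(r2$relative_risk, 1.331, tolerance = 1e-12)
  expect_equal(r2$pct_change, 33.1, tolerance = 1e-9)
  expect_error(crash_relative_risk(0, 90), "positive")
  expect_error(crash_relative_risk(90, -1), "positive")
})

test_that("relative risk is monotone and chain-consistent", {
  set.seed(12)
  a <- runif(500, 40, 120); b <- runif(500, 40, 120); c_ <- runif(500, 40, 120)
  rr_ab <- crash_relative_risk(a, b)$relative_risk
  rr_bc <- crash_relative_risk(b, c_)$relative_risk
  rr_ac <- crash_relative_risk(a, c_)$relative_risk
  expect_equal(rr_ab * rr_bc, rr_ac, tolerance = 1e-12)
  # monotone in the alternative speed
  v <- seq(50, 110, 5)
  expect_true(all(diff(crash_relative_risk(80, v)$relative_risk) > 0))
})

test_that("the crash-risk table pools cells and compares against FIX1", {
  # synthetic results over the full default grid: constant speeds
  g <- enumerate_scenarios()
  g$seed <- 1
  g$rud_pct <- 10
  g$mean_speed_kmh <- 80
  g$total_distance_vkm <- 1000
  g$total_time_vh <- g$total_distance_vkm / g$mean_speed_kmh
  tab <- build_crash_risk_table(g)
  # 4 communities x 2 traffic x 2 telematics cells, 3 comparisons each
  expect_equal(nrow(tab), 48)
  expect_true(all(abs(tab$pct_change) < 1e-9))

  # a known speed ratio: P2P at 96.4% of the FIX1 speed
  g2 <- g
  p2p <- g2$sec_type == "P2P"
  g2$mean_speed_kmh[p2p] <- 80 * 0.964
  g2$total_time_vh <- g2$total_distance_vkm / g2$mean_speed_kmh
  tab2 <- build_crash_risk_table(g2)
  p2p_rows <- tab2[tab2$comparison == "P2P-vs-FIX1", ]
  expect_equal(p2p_rows$pct_change, rep(100 * (0.964^3 - 1), nrow(p2p_rows)),
               tolerance = 1e-9)
  expect_equal(p2p_rows$pct_change[1], -10.4, tolerance = 0.05)

  # missing reference is an error
  expect_error(build_crash_risk_table(g[g$sec_type != "FIX1", ]),
               "missing the FIX1 reference")
})

test_that("spill-over linearity recovers slopes and flags curvature", {
  tel <- seq(10, 90, 10)
  base <- expand.grid(sec_type = c("FIX1", "P2P"), demand_vph = c(2000, 3000),
                      telematics_pct = tel, stringsAsFactors = FALSE)
  lin <- base
  lin$rud_pct <- 20 - 0.2 * lin$telematics_pct
  out <- spillover_linearity(lin)
  expect_equal(out$slope, rep(-0.2, 4), tolerance = 1e-12)
  expect_equal(out$r_squared, rep(1, 4), tolerance = 1e-12)

  quad <- base
  quad$rud_pct <- 20 - 0.2 * quad$telematics_pct +
    0.01 * (quad$telematics_pct - 50)^2
  out2 <- spillover_linearity(quad)
  expect_true(all(out2$r_squared < 1))
  expect_true(all(out2$max_abs_residual > 0.5))

  expect_error(spillover_linearity(lin[lin$telematics_pct <= 20, ]),
               "at least 3 telematics levels")
})
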