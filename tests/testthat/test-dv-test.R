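mk_fit <- function(sigma, var_sigma) {
  structure(list(cp = list(mu = 0, sigma = sigma, gamma = 0),
                 se = c(mu = 0.1, sigma = sqrt(var_sigma), gamma = 0.1),
                 var_sigma = var_sigma, loglik = 0, method = "mle",
                 converged = TRUE, n = 100), class = "sn_fit")
}

test_that("the Wald statistic matches its definition", {
  expect_equal(wald_z(mk_fit(1.3, 0.01), mk_fit(1.3, 0.02)), 0)
  z <- wald_z(mk_fit(1, 0.125), mk_fit(2, 0.125))
  expect_equal(z, 2)
  expect_equal(2 * pnorm(-abs(z)), 0.0455, tolerance = 1e-3)
  # antisymmetry under group swap
  expect_equal(wald_z(mk_fit(2, 0.125), mk_fit(1, 0.125)), -z)
  bad <- mk_fit(1, NA_real_)
  expect_error(wald_z(bad, mk_fit(1, 0.1)), "finite")
})

test_that("BY adjustment matches the hand-computed example", {
  expect_equal(by_adjust(0.2), 0.2)  # m = 1: c(1) = 1
  # m = 3, c(3) = 11/6: all three adjust to 3 * (11/6) * 0.01 = 0.055
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  expect_error(by_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BY equals the brute-force step-up scan and dominates BH", {
  set.seed(21)
  for (i in 1:50) {
    m <- sample(1:400, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- by_adjust(p)
    expect_equal(q, brute_force_by(p), tolerance = 1e-12)
    expect_true(all(q >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("missing p-values are excluded from the BY family", {
  p <- c(0.01, NA, 0.02, 0.03, NA)
  q <- by_adjust(p)
  expect_true(all(is.na(q[c(2, 5)])))
  expect_equal(q[!is.na(q)], by_adjust(c(0.01, 0.02, 0.03)))
})

test_that("run_clrdv flags a strongly spiked gene and not a null cohort", {
  params <- synth_nb2_params(80, seed = 31)
  params$phi <- pmax(params$phi, 0.05)
  sim <- simulate_two_groups(params, 200, prop_dv = 0, seed = 32)
  # spike the first gene by hand with fold 4 on the size parameter
  spiked <- params[1, ]
  set.seed(33)
  sim$counts[1, sim$groups$group == "treatment"] <-
    rnbinom(200, mu = spiked$mu, size = 4 / spiked$phi)
  res <- run_clrdv(sim$counts, sim$groups, reference = "control")
  d <- tidy(res)
  expect_equal(nrow(d), sum(!attr(res, "filter_report")$removed))
  expect_true(d$q_value[d$gene_id == params$gene_id[1]] < 0.05)
  # spiked group tightened (fold > 1 lowers dispersion): sd ratio < 1
  expect_lt(d$sd_ratio[1], 1)
  expect_equal(d$log2_sd_ratio, log2(d$sd_ratio))
  # null genes essentially never called under conservative BY
  expect_lte(sum(d$q_value[-1] < 0.05, na.rm = TRUE), 2)
})

test_that("swapping groups negates z and inverts the SD ratio", {
  params <- synth_nb2_params(40, seed = 34)
  sim <- simulate_two_groups(params, 60, prop_dv = 0.2, seed = 35)
  res_ab <- run_clrdv(sim$counts, sim$groups, reference = "control")
  res_ba <- run_clrdv(sim$counts, sim$groups, reference = "treatment")
  a <- tidy(res_ab)
  b <- tidy(res_ba)
  ok <- a$status == "ok" & b$status == "ok"
  expect_equal(b$z[ok], -a$z[ok], tolerance = 1e-8)
  expect_equal(b$p_value[ok], a$p_value[ok], tolerance = 1e-8)
  expect_equal(b$q_value[ok], a$q_value[ok], tolerance = 1e-8)
  expect_equal(b$sd_ratio[ok], 1 / a$sd_ratio[ok], tolerance = 1e-8)
  expect_equal(b$log2_sd_ratio[ok], -a$log2_sd_ratio[ok],
               tolerance = 1e-8)
})

test_that("design validation enforces two sufficiently large groups", {
  params <- synth_nb2_params(30, seed = 36)
  sim <- simulate_two_groups(params, 30, prop_dv = 0, seed = 37)
  expect_error(
    run_clrdv(sim$counts, rep("one", 60)), "exactly two"
  )
  expect_error(
    run_clrdv(sim$counts, c(rep("a", 10), rep("b", 50))), "at least 20"
  )
  expect_warning(
    run_clrdv(sim$counts, sim$groups), "below 50"
  )
  expect_error(
    run_clrdv(sim$counts, sim$groups, reference = "nope"), "not found"
  )
})

test_that("null p-values are approximately uniform at n = 200 per group", {
  params <- synth_nb2_params(400, seed = 38)
  sim <- simulate_two_groups(params, 200, prop_dv = 0, seed = 39)
  res <- run_clrdv(sim$counts, sim$groups, reference = "control")
  d <- tidy(res)
  p <- d$p_value[d$status == "ok"]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  expect_lte(sum(d$q_value < 0.05, na.rm = TRUE), 2)
})

test_that("the volcano autoplot builds", {
  params <- synth_nb2_params(40, seed = 40)
  sim <- simulate_two_groups(params, 50, prop_dv = 0.1, seed = 41)
  res <- suppressWarnings(run_clrdv(sim$counts, sim$groups))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
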