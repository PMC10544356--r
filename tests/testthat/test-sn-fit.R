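test_that("input contracts: length floor, warning below 50, constant data", {
  expect_error(fit_sn_cp(rnorm(10)), "at least 20")
  expect_warning(fit_sn_cp(rnorm(30)), "unreliable")
  expect_error(fit_sn_cp(rep(3, 100)), "constant")
  expect_error(fit_sn_cp(c(rnorm(50), NA)), "NA")
})

test_that("normal data are recovered with near-zero skewness", {
  set.seed(11)
  y <- rnorm(10000, 2, 1)
  fit <- fit_sn_cp(y)
  expect_true(fit$converged)
  expect_lt(abs(fit$cp$mu - 2) / fit$se[["mu"]], 4)
  expect_lt(abs(fit$cp$sigma - 1) / fit$se[["sigma"]], 4)
  expect_lt(abs(fit$cp$gamma) / fit$se[["gamma"]], 4)
})

test_that("skewed data are recovered in centered parameters", {
  set.seed(12)
  y <- rsn_cp(10000, 0, 1, 0.5)
  fit <- fit_sn_cp(y)
  expect_true(fit$converged)
  expect_lt(abs(fit$cp$mu - 0) / fit$se[["mu"]], 4)
  expect_lt(abs(fit$cp$sigma - 1) / fit$se[["sigma"]], 4)
  expect_lt(abs(fit$cp$gamma - 0.5) / fit$se[["gamma"]], 4)
  expect_equal(fit$var_sigma, fit$se[["sigma"]]^2)
})

test_that("fitted log-likelihood dominates the normal submodel", {
  set.seed(13)
  for (g in c(-0.6, 0, 0.3, 0.8)) {
    y <- rsn_cp(400, 1, 1.5, g)
    fit <- fit_sn_cp(y, warn_small = FALSE)
    m <- mean(y)
    s <- sqrt(mean((y - m)^2))
    ll_norm <- sum(dnorm(y, m, s, log = TRUE))
    expect_gte(fit$loglik, ll_norm - 1e-6)
  }
})

test_that("sigma standard error approaches the normal-theory limit", {
  set.seed(14)
  y <- rnorm(10000, 0, 2)
  fit <- fit_sn_cp(y)
  expect_equal(fit$se[["sigma"]], 2 / sqrt(2 * 10000), tolerance = 0.1)
})

test_that("se_sigma_cp agrees with an independent finite-difference scheme", {
  set.seed(15)
  y <- rsn_cp(1000, 0, 1, 0.4)
  fit <- fit_sn_cp(y)
  # independent oracle: central differences of the CP log-likelihood with
  # a fixed step, assembled by hand
  nll <- function(th) {
    dp <- cp_to_dp(th[1], th[2], th[3])
    -sum(dsn(y, dp$xi, dp$omega, dp$alpha, log = TRUE))
  }
  th <- c(fit$cp$mu, fit$cp$sigma, fit$cp$gamma)
  h <- 1e-4 * pmax(abs(th), 1)
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ei <- ej <- numeric(3)
    ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (nll(th + ei + ej) - nll(th + ei - ej) -
                nll(th - ei + ej) + nll(th - ei - ej)) / (4 * h[i] * h[j])
  }
  se_ref <- sqrt(diag(solve(H)))
  expect_equal(se_sigma_cp(y, fit$cp), se_ref[2], tolerance = 1e-4)
  expect_equal(unname(fit$se), se_ref, tolerance = 1e-3)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  set.seed(16)
  y1 <- rsn_cp(2000, 0, 1, 0.3)
  y2 <- c(y1, rsn_cp(2000, 0, 1, 0.3))
  f1 <- fit_sn_cp(y1)
  f2 <- fit_sn_cp(y2)
  expect_equal(f1$se[["sigma"]] / f2$se[["sigma"]], sqrt(2),
               tolerance = 0.15)
})

test_that("the ladder returns a flagged finite fit on hard inputs", {
  # heavily boundary-skewed data push plain MLE to diverging alpha
  set.seed(17)
  y <- abs(rnorm(80))  # half-normal: the alpha -> Inf limit
  fit <- fit_sn_cp(y, warn_small = FALSE)
  expect_true(fit$converged)
  expect_true(fit$method %in% c("mle", "penalized_q", "normal"))
  expect_true(all(is.finite(unlist(fit$cp))))
  expect_true(all(is.finite(fit$se)))
  expect_lt(abs(fit$cp$gamma), sn_skewness_bound())
})

test_that("Wald 95% intervals for sigma cover the truth", {
  set.seed(18)
  n_rep <- 200
  cp <- random_cp(n_rep)
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    y <- rsn_cp(200, cp$mu[i], cp$sigma[i], cp$gamma[i])
    fit <- fit_sn_cp(y)
    covered[i] <- abs(fit$cp$sigma - cp$sigma[i]) <=
      qnorm(0.975) * fit$se[["sigma"]]
  }
  # binomial 3-sigma band around 0.95 at 200 replicates is about 0.046
  expect_gte(mean(covered), 0.93 - 3 * sqrt(0.95 * 0.05 / n_rep))
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(19)
  fit <- fit_sn_cp(rsn_cp(300, 1, 2, 0.2), warn_small = FALSE)
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "sigma", "gamma"))
  expect_equal(td$estimate[2], fit$cp$sigma)
  gl <- glance(fit)
  expect_equal(gl$nobs, 300)
  expect_true(gl$converged)
})
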