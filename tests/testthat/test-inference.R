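test_that("records extract observed transitions, gaps lengthening dt", {
  # worked example: response at week 1, relapse at 2, dropout at 4
  rec <- patient_record("k", "A", times = c(1, 2, 4), states = c(2, 1, 3))
  tr <- transitions_from_record(rec)
  expect_equal(tr$from, c(1L, 2L, 1L))
  expect_equal(tr$to, c(2L, 1L, 3L))
  expect_equal(tr$dt, c(1, 1, 2))
  # staying put is informative
  one <- transitions_from_record(patient_record("k", "A", 1, 1))
  expect_equal(one, data.frame(from = 1L, to = 1L, dt = 1))
  # a skipped visit only lengthens the elapsed time
  gap <- transitions_from_record(
    patient_record("k", "A", times = c(1, 2), states = c(NA, 2)))
  expect_equal(gap, data.frame(from = 1L, to = 2L, dt = 2))
})

test_that("dropout is enforced as absorbing at record construction", {
  expect_error(patient_record("k", "A", c(1, 2, 4), c(3, NA, 1)),
               "absorbing")
  expect_silent(patient_record("k", "A", c(1, 2, 4), c(3, NA, 3)))
  expect_error(patient_record("k", "A", c(2, 1), c(1, 2)), "increasing")
})

test_that("log-likelihood sums per-transition multinomial log-probabilities", {
  r <- ami_rates()
  # a transition out of the absorbing state contributes log(1) = 0
  ds3 <- study_dataset(list(patient_record("a", "T", c(1, 2), c(3, 3))))
  ds3b <- study_dataset(list(patient_record("a", "T", 1, 3)))
  expect_equal(log_likelihood(ds3, list(T = r)),
               log_likelihood(ds3b, list(T = r)))
  # one observed 1 -> 2 transition over one week
  ds1 <- study_dataset(list(patient_record("a", "T", 1, 2)))
  expect_equal(log_likelihood(ds1, list(T = r)),
               log(transition_probs(r, 1)[1, 2]))
  expect_error(log_likelihood(ds1, list(OTHER = r)), "arm")
})

test_that("likelihood equals the naive path-probability product", {
  r <- ris_rates()
  rec <- patient_record("a", "T", c(1, 2, 4, 6), c(1, 2, 2, 3))
  ds <- study_dataset(list(rec))
  path <- transition_probs(r, 1)[1, 1] * transition_probs(r, 1)[1, 2] *
    transition_probs(r, 2)[2, 2] * transition_probs(r, 2)[2, 3]
  expect_equal(log_likelihood(ds, list(T = r)), log(path), tolerance = 1e-12)
})

test_that("a flanked missing visit changes nothing but the bookkeeping", {
  r <- ami_rates()
  with_gap <- study_dataset(list(
    patient_record("a", "T", c(1, 2), c(NA, 1))))
  without <- study_dataset(list(patient_record("a", "T", 2, 1)))
  expect_identical(log_likelihood(with_gap, list(T = r)),
                   log_likelihood(without, list(T = r)))
})

test_that("true rates beat grossly perturbed rates in likelihood", {
  truth <- ami_rates()
  wrong <- transition_rates3(0.189 * 2, 0.052 * 2, 0.076 * 2, 0.024 * 2)
  wins <- 0L
  n_rep <- 40L
  for (k in seq_len(n_rep)) {
    ds <- simulate_study(sim_config(list(T = truth), 200, seed = 100 + k))
    wins <- wins +
      (log_likelihood(ds, list(T = truth)) >
       log_likelihood(ds, list(T = wrong)))
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("maximum likelihood recovers the generating rates", {
  ds <- simulate_study(sim_config(list(T = ami_rates()), 5000,
                                  schedule = 1:8, seed = 20260101))
  fit <- fit_mle(ds)
  est <- fitted_rates(fit)$T
  expect_equal(unclass(est), unclass(ami_rates()), tolerance = 0.10)
  expect_length(fit$flags, 0)
  expect_equal(fit$convergence, 0L)
})

test_that("an arm where nobody leaves nonresponse is flagged", {
  recs <- lapply(1:30, function(i)
    patient_record(paste0("p", i), "T", c(1, 2, 4), c(1, 1, 1)))
  fit <- fit_mle(study_dataset(recs))
  expect_match(fit$flags, "non-identifiable")
  est <- fit$par
  expect_lt(est[["lgamma12.T"]], -9)
  expect_lt(est[["lgamma13.T"]], -9)
})

test_that("the gamma13 = gamma23 constraint is a proper nested model", {
  ds <- simulate_study(sim_config(both_arms(), 250, seed = 5))
  free_fit <- fit_mle(ds)
  con_fit <- fit_mle(ds, model_spec(constraints = "gamma13=gamma23"))
  expect_equal(length(con_fit$par), length(free_fit$par) - 2L)
  expect_lte(con_fit$loglik, free_fit$loglik + 1e-6)
  for (a in con_fit$arms) {
    r <- fitted_rates(con_fit)[[a]]
    expect_identical(r[["gamma13"]], r[["gamma23"]])
  }
})

test_that("psrf behaves as a between/within variance diagnostic", {
  set.seed(2)
  same <- list(rnorm(10000), rnorm(10000))
  expect_lt(psrf(same), 1.01)
  apart <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(psrf(apart), 5)
  x <- rnorm(500)
  expect_equal(psrf(list(x, x)), 1, tolerance = 1e-9)
  expect_error(psrf(list(x)), "2 chains")
  expect_error(psrf(list(rnorm(5), rnorm(5))), ">= 10")
  # matrix input, cross-checked against the classic coda implementation
  m <- cbind(rnorm(2000), rnorm(2000, 0.2))
  if (requireNamespace("coda", quietly = TRUE)) {
    cd <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(m[, 1]),
                                            coda::mcmc(m[, 2])),
                            autoburnin = FALSE)$psrf[1, 1]
    expect_equal(psrf(m), cd, tolerance = 0.01, ignore_attr = TRUE)
  }
})

test_that("with no data the posterior reproduces the uniform prior", {
  ds <- study_dataset(list(patient_record("p1", "T", 1, NA)))
  fit <- fit_bayes(ds, chains = 2, burnin = 1000, iter = 2500, thin = 4,
                   seed = 99)
  draws <- do.call(rbind, fit$draws)
  expect_equal(nrow(draws), 5000)
  for (p in colnames(draws)) {
    ks <- suppressWarnings(ks.test(draws[, p], punif, -10, 5))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Bayesian medians recover simulated rates and agree with the MLE", {
  ds <- simulate_study(sim_config(list(T = ami_rates()), 400, seed = 31))
  fit <- fit_bayes(ds, chains = 2, burnin = 1500, iter = 1500, seed = 8)
  draws <- do.call(rbind, fit$draws)
  truth <- log(unclass(ami_rates()))
  mle <- fit_mle(ds)
  for (j in seq_len(4)) {
    p <- fit$param_map$lgamma["T", j]
    med <- median(draws[, p])
    sdv <- sd(draws[, p])
    expect_lt(abs(med - truth[j]), 3 * sdv)
    expect_lt(abs(med - mle$par[[p]]), 2 * sdv)
  }
  expect_true(all(fit$summary$psrf < 1.2, na.rm = TRUE))
})

test_that("equality-constrained draws are bitwise identical", {
  ds <- simulate_study(sim_config(list(T = ami_rates()), 60, seed = 77))
  fit <- fit_bayes(ds, model_spec(constraints = "gamma13=gamma23"),
                   chains = 2, burnin = 300, iter = 300, seed = 4)
  pm <- fit$param_map
  expect_identical(pm$lgamma["T", "gamma13"], pm$lgamma["T", "gamma23"])
})

test_that("random-effects heterogeneity is recovered on the reported scale", {
  cfg <- sim_config(both_arms(), 500, tau = 0.6, seed = 2024)
  ds <- simulate_study(cfg)
  fit <- fit_bayes(ds, model_spec(random_effects = "all"),
                   chains = 2, burnin = 800, iter = 800, seed = 12)
  tau_med <- fit$summary$estimate[fit$summary$parameter == "tau"]
  expect_gt(tau_med, 0.3)
  expect_lt(tau_med, 0.9)
})

test_that("covariate coefficients are recoverable by maximum likelihood", {
  cfg <- sim_config(list(T = ami_rates()), 1500,
                    covariate_coefs = list(gamma12 = 0.5), seed = 55)
  ds <- simulate_study(cfg)
  fit <- fit_mle(ds, model_spec(covariates = list(gamma12 = "c1")))
  b <- fit$par[["b_gamma12.T"]]
  expect_lt(abs(b - 0.5), 0.15)
})
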