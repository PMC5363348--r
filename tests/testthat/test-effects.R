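test_that("expected time in state reproduces the published plug-in values", {
  ets_ami <- sapply(1:3, function(s) expected_time_in_state(ami_rates(), 8, s))
  ets_ris <- sapply(1:3, function(s) expected_time_in_state(ris_rates(), 8, s))
  expect_equal(ets_ami, oracle$ets_ami, tolerance = 1e-5)
  expect_equal(ets_ris, oracle$ets_ris, tolerance = 1e-5)
  # printed to one decimal: 4.0 / 2.8 / 1.2 and 4.5 / 2.4 / 1.1
  expect_equal(round(ets_ami, 1), c(4.0, 2.8, 1.2))
  expect_equal(round(ets_ris, 1), c(4.5, 2.4, 1.1))
})

test_that("times in state conserve the horizon and match quadrature", {
  set.seed(17)
  for (i in 1:10) {
    r <- random_rates()
    T <- runif(1, 1, 15)
    ets <- sapply(1:3, function(s) expected_time_in_state(r, T, s))
    expect_equal(sum(ets), T, tolerance = 1e-9)
    expect_true(all(ets >= -1e-12 & ets <= T + 1e-12))
    for (s in 1:2)
      expect_equal(ets[s], expected_time_in_state_quad(r, T, s),
                   tolerance = 1e-8)
  }
  expect_equal(expected_time_in_state(transition_rates3(0, 0, 0, 0), 8, 1), 8)
})

test_that("fractions of time in state sum to one and match the reported shares", {
  expect_equal(time_in_state_fraction(ami_rates(), 8, 1), 0.50,
               tolerance = 0.01)
  expect_equal(time_in_state_fraction(ami_rates(), 8, 2), 0.35,
               tolerance = 0.01)
  set.seed(23)
  fr <- sapply(1:3, function(s) time_in_state_fraction(random_rates(), 8, s))
  r <- random_rates()
  expect_equal(sum(sapply(1:3, function(s) time_in_state_fraction(r, 8, s))),
               1, tolerance = 1e-9)
  expect_error(time_in_state_fraction(ami_rates(), 0, 1), "positive")
})

test_that("plug-in odds ratios at the study endpoint match the published table", {
  arms <- both_arms()
  rv <- c("risperidone", "amisulpride")
  or12 <- relative_effect(arms, 1, 2, 8, "logit", arms = rv,
                          summary = "plugin")
  or13 <- relative_effect(arms, 1, 3, 8, "logit", arms = rv,
                          summary = "plugin")
  expect_equal(or12$estimate, oracle$or12, tolerance = 1e-6)
  expect_equal(or13$estimate, oracle$or13, tolerance = 1e-6)
  expect_equal(round(or12$estimate, 2), 0.93)
  expect_equal(round(or13$estimate, 2), 0.81)
  expect_equal(or12$scale, "OR")
})

test_that("relative effects vanish for identical arms and invert with the arm order", {
  same <- list(a = ami_rates(), b = ami_rates())
  expect_identical(relative_effect(same, 1, 2, 8, "identity",
                                   summary = "plugin")$estimate, 0)
  expect_equal(relative_effect(same, 1, 2, 8, "logit",
                               summary = "plugin")$estimate, 1)
  arms <- both_arms()
  ab <- relative_effect(arms, 1, 2, 8, "logit",
                        arms = c("risperidone", "amisulpride"),
                        summary = "plugin")$estimate
  ba <- relative_effect(arms, 1, 2, 8, "logit",
                        arms = c("amisulpride", "risperidone"),
                        summary = "plugin")$estimate
  expect_equal(ab * ba, 1, tolerance = 1e-12)
})

test_that("rate ratios reproduce the published ratios and are reciprocal", {
  arms <- both_arms()
  rv <- c("risperidone", "amisulpride")
  for (tr in names(oracle$rate_ratios))
    expect_equal(rate_ratio(arms, tr, arms = rv, summary = "plugin")$estimate,
                 oracle$rate_ratios[[tr]], tolerance = 1e-6)
  expect_equal(round(rate_ratio(arms, "gamma12", arms = rv,
                                summary = "plugin")$estimate, 2), 0.72)
  expect_equal(rate_ratio(arms, "gamma21", arms = rv,
                          summary = "plugin")$estimate *
               rate_ratio(arms, "gamma21", arms = rev(rv),
                          summary = "plugin")$estimate, 1, tolerance = 1e-12)
  expect_equal(rate_ratio(list(a = ami_rates(), b = ami_rates()), "gamma12",
                          summary = "plugin")$estimate, 1)
})

test_that("dropout-without-response has the stated closed form and limits", {
  r <- ami_rates()
  expect_equal(prob_dropout_without_response(r, 8), oracle$pdwr_ami_8,
               tolerance = 1e-6)
  lim <- 0.052 / 0.241
  expect_equal(prob_dropout_without_response(r, 1e6), lim, tolerance = 1e-9)
  grid <- seq(0, 20, by = 0.5)
  v <- vapply(grid, function(t) prob_dropout_without_response(r, t), 0)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= lim + 1e-12))
  expect_equal(prob_dropout_without_response(
    transition_rates3(0.2, 0, 0.1, 0.05), 8), 0)
  expect_equal(prob_dropout_without_response(
    transition_rates3(0, 0, 0.1, 0.05), 8), 0)
})

test_that("the dropout split partitions pi_13 by last transient state", {
  expect_equal(dropout_split(ami_rates(), 8), oracle$split_ami_8,
               tolerance = 1e-6)
  expect_equal(prob_dropout_after_response(
    transition_rates3(0.2, 0.05, 0.1, 0), 8), 0)
  set.seed(29)
  for (i in 1:20) {
    r <- random_rates()
    dt <- runif(1, 0, 10)
    sp <- dropout_split(r, dt)
    expect_equal(sum(sp), transition_probs(r, dt)[1, 3], tolerance = 1e-10)
  }
})

test_that("dropout-path probabilities match the Monte-Carlo path oracle", {
  r <- ami_rates()
  mc1 <- monte_carlo_path_probability(
    r, 8, function(p) p$final == 3 & !p$visited_2, n_paths = 4e4, seed = 41)
  expect_lt(abs(mc1$estimate - prob_dropout_without_response(r, 8)),
            3 * mc1$se)
  mc2 <- monte_carlo_path_probability(
    r, 8, function(p) p$final == 3 & p$dropout_from == 2 &
      !is.na(p$dropout_from), n_paths = 4e4, seed = 43)
  expect_lt(abs(mc2$estimate - prob_dropout_after_response(r, 8)),
            3 * mc2$se)
})

test_that("complete-case and LOCF odds ratios work on a hand-built table", {
  # numerator arm: 3/4 responders at week 2; denominator arm: 1/4
  mk <- function(arm, i, s2) patient_record(paste0(arm, i), arm, c(1, 2),
                                            c(1, if (s2) 2 else 1))
  recs <- c(lapply(1:4, function(i) mk("N", i, i <= 3)),
            lapply(1:4, function(i) mk("D", i, i <= 1)))
  ds <- study_dataset(recs)
  cca <- cca_odds_ratio(ds, 2, arms = c("N", "D"))
  expect_equal(cca$estimate, 9)
  # no dropouts, no missingness: LOCF must coincide with CCA
  locf <- locf_odds_ratio(ds, 2, arms = c("N", "D"))
  expect_identical(cca$estimate, locf$estimate)
  expect_true(cca$lower < 9 && cca$upper > 9)
})

test_that("LOCF carries the last transient state past dropout and gaps", {
  recs <- list(
    patient_record("a", "X", c(1, 2, 4), c(2, 3, 3)),  # responder, dropped
    patient_record("b", "X", c(1, 2, 4), c(1, NA, NA)), # missing tail
    patient_record("c", "X", c(1, 2, 4), c(1, 1, 2)),
    patient_record("d", "Y", c(1, 2, 4), c(1, 3, 3)),
    patient_record("e", "Y", c(1, 2, 4), c(2, 2, 2)),
    patient_record("f", "Y", c(1, 2, 4), c(1, 1, 1)))
  ds <- study_dataset(recs)
  locf <- locf_odds_ratio(ds, 4, arms = c("X", "Y"))
  # X: a -> 2 (carried), b -> 1 (carried), c -> 2 observed: 2/1
  # Y: d -> 1 (carried), e -> 2, f -> 1: 1/2
  expect_equal(unname(locf$table["X", ]), c(2, 1))
  expect_equal(unname(locf$table["Y", ]), c(1, 2))
  cca <- cca_odds_ratio(ds, 4, arms = c("X", "Y"))
  expect_equal(unname(cca$table["X", ]), c(1, 0))
})

test_that("under MCAR dropout the complete-case OR is consistent with the model", {
  # dropout independent of state: gamma13 = gamma23
  a <- transition_rates3(0.189, 0.04, 0.076, 0.04)
  b <- transition_rates3(0.136, 0.04, 0.056, 0.04)
  ds <- simulate_study(sim_config(list(A = a, B = b), 1500, seed = 314))
  cca <- cca_odds_ratio(ds, 8, arms = c("B", "A"))
  # completers' response probability is pi12 / (pi11 + pi12); with dropout
  # independent of the response process CCA estimates exactly this
  podds <- function(r) {
    P <- transition_probs(r, 8)
    P[1, 2] / P[1, 1]
  }
  truth <- podds(b) / podds(a)
  # within Monte-Carlo error measured by the Woolf SE of the CCA estimate
  se_log <- (log(cca$upper) - log(cca$lower)) / (2 * 1.96)
  expect_lt(abs(log(cca$estimate) - log(truth)), 3 * se_log)
})
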