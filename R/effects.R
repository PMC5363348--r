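.new_effect <- function(estimate, lower, upper, scale, dt, detail = list()) {
  structure(c(list(estimate = estimate, lower = lower, upper = upper,
                   scale = scale, dt = dt), detail),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  ci <- if (is.finite(x$lower) || is.finite(x$upper))
    sprintf(" [%.3g; %.3g]", x$lower, x$upper) else ""
  cat(x$scale,
      if (!is.null(x$dt) && is.finite(x$dt)) paste0(" at dt = ", x$dt),
      ": ", format(x$estimate, digits = 4), ci, "\n", sep = "")
  if (!is.null(x$n_skipped) && x$n_skipped > 0)
    cat("(", x$n_skipped, "posterior draws skipped: probability at 0 or 1 )\n")
  invisible(x)
}

# Per-arm rate matrices from either a markov_fit or a named list of
# transition_rates3. Returns list(point = list(arm -> rates),
# draws = list(arm -> draws x 4 matrix) or NULL).
.rates_source <- function(fit) {
  if (inherits(fit, "markov_fit")) {
    point <- fitted_rates(fit)
    draws <- NULL
    if (fit$mode == "bayes") {
      pooled <- .all_draws(fit)
      pm <- fit$param_map
      draws <- lapply(pm$arms, function(a)
        exp(pooled[, pm$lgamma[a, ], drop = FALSE]))
      names(draws) <- pm$arms
    }
    return(list(point = point, draws = draws))
  }
  if (is.list(fit) && length(fit) >= 1L && !is.null(names(fit))) {
    point <- lapply(fit, .assert_rates3)
    return(list(point = point, draws = NULL))
  }
  stop("expected a markov_fit or a named list of transition_rates3",
       call. = FALSE)
}

.pick_arms <- function(src, arms) {
  available <- names(src$point)
  if (is.null(arms)) {
    if (length(available) < 2L)
      stop("need two arms for a relative effect", call. = FALSE)
    arms <- available[1:2]
  }
  if (!all(arms %in% available))
    stop("arm(s) not in fit: ",
         paste(setdiff(arms, available), collapse = ", "), call. = FALSE)
  arms
}

.summarize_draws <- function(v, transform = identity) {
  q <- stats::quantile(v, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  list(estimate = transform(q[2]), lower = transform(q[1]),
       upper = transform(q[3]))
}

#' Relative treatment effect on a transition probability
#'
#' The arm contrast `delta = l(pi_XY^num(dt)) - l(pi_XY^den(dt))` under a
#' link `l`: with the logit link and the 1 -> 2 transition this is the log
#' odds ratio for response at `dt`; with the log link, a log relative risk.
#' Results on the logit/log scale are returned exponentiated (OR / RR).
#'
#' @param fit a `"markov_fit"` covering both arms, or a named list of
#'   [transition_rates3()] (plug-in only).
#' @param from,to states of the transition probability compared.
#' @param dt elapsed time at which the probability is evaluated.
#' @param link `"logit"`, `"log"` or `"identity"`.
#' @param arms `c(numerator, denominator)` arm labels; default first two.
#' @param summary `"posterior"` (per-draw transform, summarized by median
#'   and central 95% interval — only for Bayesian fits) or `"plugin"`
#'   (transform of the point rates; no interval).
#' @return An `"effect_estimate"`. Draws where the probability is exactly 0
#'   or 1 under the logit/log link are skipped and counted; more than half
#'   skipped is an error.
#' @export
relative_effect <- function(fit, from, to, dt,
                            link = c("logit", "log", "identity"),
                            arms = NULL,
                            summary = c("posterior", "plugin")) {
  link <- match.arg(link)
  summary <- match.arg(summary)
  src <- .rates_source(fit)
  arms <- .pick_arms(src, arms)
  lfun <- switch(link, logit = stats::qlogis, log = log, identity = identity)
  back <- switch(link, logit = exp, log = exp, identity = identity)
  scale <- switch(link, logit = "OR", log = "RR", identity = "difference")
  pi_of <- function(r, dtv) transition_probs(transition_rates3(
    r[[1]], r[[2]], r[[3]], r[[4]]), dtv)[from, to]
  if (summary == "plugin" || is.null(src$draws)) {
    p1 <- pi_of(src$point[[arms[1]]], dt)
    p2 <- pi_of(src$point[[arms[2]]], dt)
    if (link != "identity" && (p1 %in% c(0, 1) || p2 %in% c(0, 1)))
      stop("probability at 0 or 1: link undefined", call. = FALSE)
    return(.new_effect(back(lfun(p1) - lfun(p2)), NA_real_, NA_real_,
                       scale, dt,
                       list(from = from, to = to, arms = arms,
                            link = link, summary = "plugin", n_skipped = 0L)))
  }
  d1 <- src$draws[[arms[1]]]; d2 <- src$draws[[arms[2]]]
  n <- nrow(d1)
  p1 <- vapply(seq_len(n), function(i) pi_of(d1[i, ], dt), 0)
  p2 <- vapply(seq_len(n), function(i) pi_of(d2[i, ], dt), 0)
  ok <- if (link == "identity") rep(TRUE, n)
        else !(p1 %in% c(0, 1) | p2 %in% c(0, 1))
  n_skipped <- sum(!ok)
  if (n_skipped > n / 2)
    stop("more than half of the posterior draws give degenerate ",
         "probabilities under the ", link, " link", call. = FALSE)
  s <- .summarize_draws(lfun(p1[ok]) - lfun(p2[ok]), back)
  .new_effect(s$estimate, s$lower, s$upper, scale, dt,
              list(from = from, to = to, arms = arms, link = link,
                   summary = "posterior", n_skipped = n_skipped))
}

#' Transition-rate ratio between arms
#'
#' @inheritParams relative_effect
#' @param transition one of `"gamma12"`, `"gamma13"`, `"gamma21"`,
#'   `"gamma23"`.
#' @return An `"effect_estimate"` on the rate-ratio scale
#'   (numerator / denominator arm).
#' @export
rate_ratio <- function(fit, transition, arms = NULL,
                       summary = c("posterior", "plugin")) {
  summary <- match.arg(summary)
  if (!transition %in% .TRANSITIONS)
    stop("unknown transition: ", transition, call. = FALSE)
  src <- .rates_source(fit)
  arms <- .pick_arms(src, arms)
  j <- match(transition, .TRANSITIONS)
  if (summary == "plugin" || is.null(src$draws)) {
    ratio <- src$point[[arms[1]]][[j]] / src$point[[arms[2]]][[j]]
    return(.new_effect(ratio, NA_real_, NA_real_, "rate ratio", NA_real_,
                       list(transition = transition, arms = arms,
                            summary = "plugin")))
  }
  v <- src$draws[[arms[1]]][, j] / src$draws[[arms[2]]][, j]
  s <- .summarize_draws(v)
  .new_effect(s$estimate, s$lower, s$upper, "rate ratio", NA_real_,
              list(transition = transition, arms = arms,
                   summary = "posterior"))
}

# integral of exp(-r t) over [0, T]
.int_exp <- function(r, T) if (r < 1e-12) T else -expm1(-r * T) / r

#' Expected time in state over a horizon
#'
#' The expected time a patient starting in nonresponse spends in `state`
#' over `[0, horizon]`: the integral of the occupancy probability
#' `pi_{1,state}(t)`. Each occupancy is a sum of exponentials, so the
#' integral is analytic; degenerate rate configurations (discriminant near
#' zero) fall back to adaptive quadrature of the matrix-exponential
#' solution. The three values sum to the horizon.
#'
#' @param rates a [transition_rates3()].
#' @param horizon study duration `T >= 0` (weeks in the usual setup).
#' @param state 1, 2 or 3.
#' @return Expected time in `state`, in the unit of `horizon`.
#' @examples
#' ami <- transition_rates3(0.189, 0.052, 0.076, 0.024)
#' expected_time_in_state(ami, horizon = 8, state = 1)
#' @export
expected_time_in_state <- function(rates, horizon, state) {
  r <- .assert_rates3(rates)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0)
    stop("horizon must be a single nonnegative number", call. = FALSE)
  if (!state %in% 1:3) stop("state must be 1, 2 or 3", call. = FALSE)
  if (horizon == 0) return(0)
  ex <- exit_rates(r)
  if (ex$h < 1e-10) {
    if (state == 3) {
      e1 <- expected_time_in_state_quad(r, horizon, 1)
      e2 <- expected_time_in_state_quad(r, horizon, 2)
      return(horizon - e1 - e2)
    }
    return(expected_time_in_state_quad(r, horizon, state))
  }
  l1 <- ex$lambda1; l2 <- ex$lambda2; h <- ex$h
  r1 <- 0.5 * (l1 + l2 - h)
  r2 <- 0.5 * (l1 + l2 + h)
  i1 <- .int_exp(r1, horizon)
  i2 <- .int_exp(r2, horizon)
  ets1 <- ((-l1 + l2 + h) * i1 + (l1 - l2 + h) * i2) / (2 * h)
  ets2 <- r[["gamma12"]] * (i1 - i2) / h
  switch(state, ets1, ets2, horizon - ets1 - ets2)
}

#' Expected time in state by adaptive quadrature
#'
#' Numerical-integration counterpart of [expected_time_in_state()], used as
#' an independent check and as the fallback for degenerate rates.
#'
#' @inheritParams expected_time_in_state
#' @export
expected_time_in_state_quad <- function(rates, horizon, state) {
  r <- .assert_rates3(rates)
  if (horizon == 0) return(0)
  f <- function(t) vapply(t, function(tt)
    transition_probs(r, tt, method = "expm")[1, state], 0)
  stats::integrate(f, 0, horizon, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Fraction of the horizon spent in a state
#'
#' @inheritParams expected_time_in_state
#' @return `expected_time_in_state(...) / horizon`; fractions over the three
#'   states sum to 1.
#' @export
time_in_state_fraction <- function(rates, horizon, state) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be positive", call. = FALSE)
  expected_time_in_state(rates, horizon, state) / horizon
}

#' Probability of dropping out without ever responding
#'
#' The probability that a patient starting in nonresponse is absorbed into
#' dropout by `dt` without ever visiting the response state, i.e. the first
#' jump out of state 1 goes to state 3 and occurs before `dt`:
#' `(gamma13 / lambda1) * (1 - exp(-lambda1 * dt))`. Monotone in `dt` with
#' limit `gamma13 / lambda1`.
#'
#' @inheritParams expected_time_in_state
#' @param dt elapsed time >= 0.
#' @export
prob_dropout_without_response <- function(rates, dt) {
  r <- .assert_rates3(rates)
  if (!is.numeric(dt) || length(dt) != 1L || dt < 0)
    stop("dt must be a single nonnegative number", call. = FALSE)
  l1 <- r[["gamma12"]] + r[["gamma13"]]
  if (l1 == 0) return(0)
  (r[["gamma13"]] / l1) * (-expm1(-l1 * dt))
}

#' Split of the dropout probability by last transient state
#'
#' Splits `pi_13(dt)` into the probability of being absorbed from
#' nonresponse versus from response, by duplicating the dropout state into
#' two absorbing copies (one fed by each transient state) and exponentiating
#' the expanded 4 x 4 generator. The two parts sum to `pi_13(dt)`.
#'
#' @inheritParams prob_dropout_without_response
#' @return Named numeric vector `c(from_nonresponse, from_response)`.
#' @export
dropout_split <- function(rates, dt) {
  r <- .assert_rates3(rates)
  if (!is.numeric(dt) || length(dt) != 1L || dt < 0)
    stop("dt must be a single nonnegative number", call. = FALSE)
  l1 <- r[["gamma12"]] + r[["gamma13"]]
  l2 <- r[["gamma21"]] + r[["gamma23"]]
  G <- matrix(c(-l1, r[["gamma12"]], r[["gamma13"]], 0,
                r[["gamma21"]], -l2, 0, r[["gamma23"]],
                0, 0, 0, 0,
                0, 0, 0, 0), nrow = 4L, byrow = TRUE)
  M <- transition_probs_expm(G, dt)
  c(from_nonresponse = M[1, 3], from_response = M[1, 4])
}

#' Probability of dropping out straight after responding
#'
#' The probability that a patient starting in nonresponse is absorbed into
#' dropout by `dt` with the absorbing jump taken from the response state
#' (the `from_response` component of [dropout_split()]).
#'
#' @inheritParams prob_dropout_without_response
#' @export
prob_dropout_after_response <- function(rates, dt) {
  unname(dropout_split(rates, dt)[2])
}

# Imputed/observed response status per patient at a time point.
# method "cca": observed state at the time (NA when missing or dropped out);
# method "locf": last observed transient state carried forward (baseline
# nonresponse when nothing later was seen).
.response_at <- function(record, time, method) {
  tol <- 1e-8
  i <- which(abs(record$times - time) < tol)
  st <- if (length(i) == 1L) record$states[i] else NA_integer_
  if (method == "cca")
    return(if (!is.na(st) && st %in% 1:2) st == 2L else NA)
  if (!is.na(st) && st %in% 1:2) return(st == 2L)
  prior <- c(1L, record$states[record$times < time + tol])
  prior <- prior[!is.na(prior) & prior %in% 1:2]
  prior[length(prior)] == 2L
}

.two_by_two_or <- function(dataset, time, arms, method) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(arms)) {
    if (length(dataset$arms) < 2L)
      stop("need two arms", call. = FALSE)
    arms <- dataset$arms[1:2]
  }
  cells <- matrix(0, nrow = 2, ncol = 2,
                  dimnames = list(arms, c("responder", "nonresponder")))
  for (rec in dataset$records) {
    if (!rec$arm %in% arms) next
    resp <- .response_at(rec, time, method)
    if (is.na(resp)) next
    cells[rec$arm, if (resp) 1 else 2] <-
      cells[rec$arm, if (resp) 1 else 2] + 1
  }
  flagged <- any(rowSums(cells) == 0)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1, 1] / cc[1, 2]) / (cc[2, 1] / cc[2, 2])
  se <- sqrt(sum(1 / cc))
  .new_effect(if (flagged) NA_real_ else or,
              if (flagged) NA_real_ else exp(log(or) - 1.96 * se),
              if (flagged) NA_real_ else exp(log(or) + 1.96 * se),
              "OR", time,
              list(arms = arms, table = cells, method = method,
                   continuity_corrected = corrected, flagged = flagged))
}

#' Complete-case odds ratio for response at a time point
#'
#' Analyzes only patients with an observed transient state (1 or 2) at the
#' time point; dropouts and missed visits are excluded. The 95% interval is
#' a Woolf log-scale interval; any zero cell triggers the 0.5 continuity
#' correction (recorded in the result). An empty arm flags the estimate as
#' undefined.
#'
#' @param dataset a [study_dataset()].
#' @param time analysis time point (must match a visit time).
#' @param arms `c(numerator, denominator)` arm labels.
#' @export
cca_odds_ratio <- function(dataset, time, arms = NULL) {
  .two_by_two_or(dataset, time, arms, "cca")
}

#' Last-observation-carried-forward odds ratio for response
#'
#' Each patient without an observed transient state at the time point
#' contributes their last observed transient state (the implicit baseline
#' nonresponse when nothing was ever observed); dropouts carry their last
#' pre-dropout state. Interval as in [cca_odds_ratio()].
#'
#' @inheritParams cca_odds_ratio
#' @export
locf_odds_ratio <- function(dataset, time, arms = NULL) {
  .two_by_two_or(dataset, time, arms, "locf")
}
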