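#' Maximum-likelihood fit of the three-state model
#'
#' Maximizes the multinomial transition likelihood over the free log rates
#' (and covariate coefficients) with box constraints keeping the log rates in
#' the same range as the default Bayesian prior support. Several jittered
#' starting points guard against local optima; Wald-type 95% intervals come
#' from the numerical Hessian at the optimum. Random-effects models are not
#' supported here (they require integrating over patient effects); use
#' [fit_bayes()] for those.
#'
#' @param dataset a [study_dataset()].
#' @param model a [model_spec()] without random effects.
#' @param n_starts number of optimizer starts (first from a fixed default,
#'   the rest jittered).
#' @param lower,upper box bounds for the log rates.
#' @param seed seed for the start jitter.
#' @return A `"markov_fit"` object; see [fit_bayes()] for the shared
#'   structure. Parameters estimated at a box bound are flagged
#'   non-identifiable in `$flags`.
#' @export
fit_mle <- function(dataset, model = model_spec(), n_starts = 3,
                    lower = -10, upper = 5, seed = 1) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(model$random_effects))
    stop("fit_mle does not support random effects; use fit_bayes",
         call. = FALSE)
  if (length(dataset$records) == 0L)
    stop("dataset is empty", call. = FALSE)
  pm <- .param_map(model, dataset$arms)
  tab <- .transition_table(dataset)
  C <- .covariate_matrix(dataset, unique(stats::na.omit(as.vector(pm$cov_of))))
  use_agg <- ncol(C) == 0L
  agg <- if (use_agg) .aggregate_transitions(tab)
  negll <- function(theta) {
    names(theta) <- pm$free
    ex <- .expand_theta(theta, pm)
    ll <- if (use_agg) sum(.loglik_agg_by_arm(agg, exp(ex$log_rates)))
          else sum(.loglik_by_patient(tab, .rates_rows(tab, ex, pm, C),
                                      length(dataset$records)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  is_b <- pm$type == "b"
  lo <- ifelse(is_b, -Inf, lower)
  hi <- ifelse(is_b, Inf, upper)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- ifelse(is_b, 0, log(0.15))
    if (s > 1) th0 <- th0 + stats::rnorm(length(th0), 0, 0.7)
    th0 <- pmin(pmax(th0, lo + 0.5), hi - 0.5)
    opt <- try(stats::optim(th0, negll, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)
  H <- stats::optimHess(best$par, negll)
  se <- rep(NA_real_, length(pm$free))
  vcov <- matrix(NA_real_, length(pm$free), length(pm$free),
                 dimnames = list(pm$free, pm$free))
  vc <- try(solve(H), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
      all(diag(vc) > 0)) {
    vcov <- vc
    se <- sqrt(diag(vc))
  }
  est <- stats::setNames(best$par, pm$free)
  at_bound <- !is_b & (est <= lower + 1e-3 | est >= upper - 1e-3)
  flags <- if (any(at_bound))
    paste0("non-identifiable (estimate at box bound): ",
           paste(pm$free[at_bound], collapse = ", "))
  else character(0)
  smry <- data.frame(
    parameter = pm$free, type = unname(pm$type),
    estimate = unname(est), se = unname(se),
    lower = unname(est - 1.96 * se), upper = unname(est + 1.96 * se),
    at_bound = unname(at_bound),
    stringsAsFactors = FALSE)
  structure(list(mode = "mle", model = model, param_map = pm,
                 arms = dataset$arms, par = est, vcov = vcov,
                 summary = smry, loglik = -best$value,
                 convergence = best$convergence, flags = flags,
                 draws = NULL, psrf = NULL, seed = seed),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("3-state Markov model fit (", x$mode, ")\n", sep = "")
  cat("Arms:", paste(x$arms, collapse = ", "), "\n")
  s <- x$summary
  s$rate_scale <- ifelse(s$type == "lgamma", exp(s$estimate), NA)
  print(s, row.names = FALSE, digits = 4)
  if (x$mode == "mle")
    cat("log-likelihood:", format(x$loglik), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$warnings) && length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Arm-level rate estimates from a fit
#'
#' @param fit a `"markov_fit"` object.
#' @param what `"point"` for the point estimate (posterior median for
#'   Bayesian fits, MLE otherwise).
#' @return Named list of [transition_rates3()], one per arm.
#' @export
fitted_rates <- function(fit, what = "point") {
  stopifnot(inherits(fit, "markov_fit"))
  pm <- fit$param_map
  est <- if (fit$mode == "bayes")
    apply(.all_draws(fit), 2, stats::median)
  else fit$par
  out <- lapply(pm$arms, function(a) {
    lg <- est[pm$lgamma[a, ]]
    transition_rates3(exp(lg[[1]]), exp(lg[[2]]), exp(lg[[3]]), exp(lg[[4]]))
  })
  stats::setNames(out, pm$arms)
}

# Pooled posterior draws across chains (iterations x parameters).
.all_draws <- function(fit) {
  stopifnot(fit$mode == "bayes")
  do.call(rbind, fit$draws)
}
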