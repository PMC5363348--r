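#' Bayesian fit of the three-state model by adaptive Metropolis sampling
#'
#' Samples the posterior of the free log rates (uniform priors), covariate
#' coefficients (normal priors) and, for random-effects models, the
#' patient-level log-rate offsets together with their standard deviation
#' `tau` (uniform prior). Global parameters are updated one at a time by
#' random-walk Metropolis with step sizes adapted toward 44% acceptance
#' during burn-in only; patient offsets are updated in vectorized blocks
#' (one per affected transition type), which is valid because the likelihood
#' factorizes over patients given the arm-level parameters.
#'
#' Convergence is assessed by the potential scale reduction factor
#' ([psrf()]) for every retained parameter; any value above 1.1 attaches a
#' warning to the result rather than failing, so the samples remain
#' available for diagnosis.
#'
#' @param dataset a [study_dataset()]; may be empty of transitions, in which
#'   case the posterior equals the prior.
#' @param model a [model_spec()].
#' @param priors a [prior_spec()].
#' @param chains number of independent chains (>= 2 recommended; default 2).
#' @param burnin,iter burn-in and retained iterations per chain (defaults
#'   20000 each, the reference protocol; reduce for exploratory runs).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain `c` uses `seed + 1000 * c`.
#' @return A `"markov_fit"` object with `mode = "bayes"`: `$draws` is a list
#'   of per-chain matrices (retained iterations x parameters) of arm-level
#'   log rates, coefficients and `tau`; `$summary` holds posterior medians
#'   and central 95% credible intervals (type-7 percentiles) with per
#'   parameter PSRF; `$warnings` lists any non-convergence messages.
#' @export
fit_bayes <- function(dataset, model = model_spec(), priors = prior_spec(),
                      chains = 2, burnin = 20000, iter = 20000, thin = 1,
                      seed = 1) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(priors, "prior_spec"))
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  pm <- .param_map(model, if (length(dataset$arms)) dataset$arms else "1")
  tab <- .transition_table(dataset)
  C <- .covariate_matrix(dataset, unique(stats::na.omit(as.vector(pm$cov_of))))
  n_pat <- length(dataset$records)
  re_cols <- which(.TRANSITIONS %in% model$random_effects)
  has_latent <- length(re_cols) > 0L && n_pat > 0L
  use_agg <- !has_latent && ncol(C) == 0L
  agg <- if (use_agg) .aggregate_transitions(tab)
  np <- length(pm$free)
  type <- pm$type
  lo <- ifelse(type == "lgamma", priors$lgamma_lower,
        ifelse(type == "tau", priors$tau_lower, -Inf))
  hi <- ifelse(type == "lgamma", priors$lgamma_upper,
        ifelse(type == "tau", priors$tau_upper, Inf))
  # which arms each parameter's likelihood contribution touches
  arms_of <- lapply(pm$free, function(p) {
    rows <- unique(c(pm$arms[row(pm$lgamma)[pm$lgamma == p]],
                     pm$arms[row(pm$b)[!is.na(pm$b) & pm$b == p]]))
    rows
  })
  tab_arm <- match(tab$arm, pm$arms)
  draw_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    theta <- stats::setNames(ifelse(type == "lgamma",
                                    log(0.15) + stats::rnorm(np, 0, 0.5),
                             ifelse(type == "tau", stats::runif(np,
                                    priors$tau_lower + 0.1 * (priors$tau_upper - priors$tau_lower),
                                    priors$tau_upper - 0.1 * (priors$tau_upper - priors$tau_lower)),
                                    0)), pm$free)
    theta <- pmin(pmax(theta, lo + 1e-3), hi - 1e-3)
    u <- matrix(0, nrow = max(n_pat, 1L), ncol = 4L,
                dimnames = list(NULL, .TRANSITIONS))
    ls_theta <- stats::setNames(rep(log(0.5), np), pm$free)
    ls_theta[type == "tau"] <- log(0.1)
    ls_u <- matrix(log(0.5), nrow = max(n_pat, 1L), ncol = length(re_cols))
    ex <- .expand_theta(theta, pm)
    if (use_agg) {
      ll_arm <- .loglik_agg_by_arm(agg, exp(ex$log_rates))
    } else {
      ll_pat <- .loglik_by_patient(tab, .rates_rows(tab, ex, pm, C, u), n_pat)
    }
    keep <- matrix(NA_real_, nrow = iter, ncol = np,
                   dimnames = list(NULL, pm$free))
    kept <- 0L
    total <- burnin + iter * thin
    for (it in seq_len(total)) {
      adapting <- it <= burnin
      rate <- min(0.05, 1 / sqrt(it))
      ex <- .expand_theta(theta, pm)
      for (p in seq_len(np)) {
        prop <- theta
        prop[p] <- theta[p] + stats::rnorm(1, 0, exp(ls_theta[p]))
        acc <- FALSE
        if (prop[p] > lo[p] && prop[p] < hi[p]) {
          lr_prior <- 0
          if (type[p] == "b")
            lr_prior <- stats::dnorm(prop[p], priors$b_mean, priors$b_sd, log = TRUE) -
                        stats::dnorm(theta[p], priors$b_mean, priors$b_sd, log = TRUE)
          exp_prop <- .expand_theta(prop, pm)
          if (type[p] == "tau") {
            cols <- which(!is.na(pm$tau_of) & pm$tau_of == pm$free[p])
            d <- 0
            for (j in cols)
              d <- d + sum(stats::dnorm(u[seq_len(n_pat), j], 0, exp_prop$tau[j], log = TRUE)) -
                       sum(stats::dnorm(u[seq_len(n_pat), j], 0, ex$tau[j], log = TRUE))
            if (log(stats::runif(1)) < d + lr_prior) acc <- TRUE
          } else if (use_agg) {
            aff <- arms_of[[p]]
            agg_aff <- agg[agg$arm %in% aff, , drop = FALSE]
            Rn <- exp(exp_prop$log_rates)
            ll_new <- .loglik_agg_by_arm(agg_aff, Rn[aff, , drop = FALSE])
            d <- sum(ll_new) - sum(ll_arm[aff])
            if (is.finite(d) && log(stats::runif(1)) < d + lr_prior) {
              acc <- TRUE
              ll_arm[aff] <- ll_new
            }
          } else {
            aff <- arms_of[[p]]
            rows <- tab$arm %in% aff
            pats <- unique(tab$patient[rows])
            sub <- tab[rows, , drop = FALSE]
            ll_new <- .loglik_by_patient(sub,
                        .rates_rows(sub, exp_prop, pm, C, u), n_pat)[pats]
            d <- sum(ll_new) - sum(ll_pat[pats])
            if (is.finite(d) && log(stats::runif(1)) < d + lr_prior) {
              acc <- TRUE
              ll_pat[pats] <- ll_new
            }
          }
        }
        if (acc) { theta <- prop; ex <- .expand_theta(theta, pm) }
        if (adapting)
          ls_theta[p] <- ls_theta[p] + rate * ((if (acc) 1 else 0) - 0.44)
      }
      if (has_latent) {
        for (jj in seq_along(re_cols)) {
          j <- re_cols[jj]
          tau_j <- ex$tau[j]
          if (tau_j <= 0) next
          idx <- seq_len(n_pat)
          eps <- stats::rnorm(n_pat, 0, exp(ls_u[idx, jj]))
          u_new <- u
          u_new[idx, j] <- u[idx, j] + eps
          ll_new <- .loglik_by_patient(tab, .rates_rows(tab, ex, pm, C, u_new),
                                       n_pat)
          dprior <- stats::dnorm(u_new[idx, j], 0, tau_j, log = TRUE) -
                    stats::dnorm(u[idx, j], 0, tau_j, log = TRUE)
          a <- log(stats::runif(n_pat)) < (ll_new - ll_pat + dprior)
          a[!is.finite(ll_new) & !is.finite(ll_pat)] <- FALSE
          if (any(a)) {
            u[idx[a], j] <- u_new[idx[a], j]
            ll_pat[a] <- ll_new[a]
          }
          if (adapting)
            ls_u[idx, jj] <- ls_u[idx, jj] + rate * (as.numeric(a) - 0.44)
        }
      }
      if (!adapting && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        keep[kept, ] <- theta
      }
    }
    draw_list[[ch]] <- keep
  }
  pooled <- do.call(rbind, draw_list)
  psrf_val <- stats::setNames(rep(NA_real_, np), pm$free)
  if (chains >= 2)
    for (p in pm$free)
      psrf_val[p] <- psrf(lapply(draw_list, function(m) m[, p]))
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 7, names = FALSE)
  smry <- data.frame(parameter = pm$free, type = unname(type),
                     estimate = qs[2, ], lower = qs[1, ], upper = qs[3, ],
                     psrf = unname(psrf_val), stringsAsFactors = FALSE)
  rownames(smry) <- NULL
  warns <- character(0)
  if (chains >= 2 && any(psrf_val > 1.1, na.rm = TRUE))
    warns <- paste0("possible non-convergence (PSRF > 1.1): ",
                    paste(pm$free[which(psrf_val > 1.1)], collapse = ", "))
  structure(list(mode = "bayes", model = model, priors = priors,
                 param_map = pm, arms = pm$arms, par = NULL, vcov = NULL,
                 summary = smry, loglik = NA_real_, convergence = 0L,
                 flags = character(0), warnings = warns,
                 draws = draw_list, psrf = psrf_val, seed = seed,
                 mcmc = list(chains = chains, burnin = burnin, iter = iter,
                             thin = thin)),
            class = "markov_fit")
}

#' Potential scale reduction factor (Gelman-Rubin diagnostic)
#'
#' Classic between/within-chain variance-ratio form: with `m` chains of
#' length `n`, `W` the mean within-chain variance and `B/n` the variance of
#' the chain means, the statistic is
#' `sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)`, floored at 1 (values below 1
#' are sampling noise). Values near 1 indicate the chains have mixed.
#'
#' @param chains a list of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain.
#' @return The scalar PSRF.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L)
    stop("psrf needs draws from at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 10L) stop("chains must have length >= 10", call. = FALSE)
  m <- length(chains)
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
  max(1, sqrt(vhat / W))
}
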