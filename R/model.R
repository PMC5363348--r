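.TRANSITIONS <- c("gamma12", "gamma13", "gamma21", "gamma23")

#' Model specification for fitting the three-state model
#'
#' Describes which structural simplifications to impose on the eight
#' arm-by-transition rates before fitting: within-arm equality constraints
#' (for example `"gamma13=gamma23"`, the MCAR restriction that dropout does
#' not depend on the current state), rates shared across treatment arms (for
#' example a common responder dropout rate `gamma23`), patient-level random
#' effects on the log rates, and patient-level covariates with optional
#' coefficient sharing.
#'
#' @param constraints character vector of within-arm equalities of the form
#'   `"gammaXY=gammaZW"`; the tied rates collapse to one free parameter per
#'   arm.
#' @param shared character vector of transition names whose rate is common
#'   to all arms.
#' @param random_effects transitions receiving patient-level normal random
#'   effects on the log rate; `"all"` expands to all four.
#' @param common_tau single random-effects standard deviation shared by all
#'   affected transitions (default) or one per transition.
#' @param covariates named list mapping a transition name to the name of a
#'   patient covariate, e.g. `list(gamma13 = "severity")`.
#' @param b_groups list of character vectors; transitions in one vector share
#'   a single covariate coefficient (within arm), e.g.
#'   `list(c("gamma13", "gamma23"))`.
#' @param b_shared_across_arms if `TRUE` covariate coefficients are common
#'   to all arms.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(constraints = character(),
                       shared = character(),
                       random_effects = character(),
                       common_tau = TRUE,
                       covariates = list(),
                       b_groups = list(),
                       b_shared_across_arms = FALSE) {
  if (identical(random_effects, "all")) random_effects <- .TRANSITIONS
  chk <- function(x, what) {
    bad <- setdiff(x, .TRANSITIONS)
    if (length(bad))
      stop("unknown transition name(s) in ", what, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  parsed <- lapply(constraints, function(cs) {
    parts <- strsplit(gsub(" ", "", cs), "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("constraint must look like 'gamma13=gamma23': ", cs, call. = FALSE)
    chk(parts, "constraints")
    parts
  })
  chk(shared, "shared"); chk(random_effects, "random_effects")
  chk(names(covariates), "covariates"); chk(unlist(b_groups), "b_groups")
  structure(list(constraints = parsed, shared = shared,
                 random_effects = random_effects, common_tau = common_tau,
                 covariates = covariates, b_groups = b_groups,
                 b_shared_across_arms = b_shared_across_arms),
            class = "model_spec")
}

#' Prior specification for Bayesian fitting
#'
#' Defaults follow the minimally informative choices used throughout:
#' log rates uniform on (-10, 5) (natural log scale; the bounds only rule
#' out astronomically small or large rates), random-effects standard
#' deviation uniform on (0, 1), covariate coefficients normal with mean 0
#' and standard deviation 10.
#'
#' @param lgamma_lower,lgamma_upper uniform prior bounds for each log rate.
#' @param tau_lower,tau_upper uniform prior bounds for the random-effects SD.
#' @param b_mean,b_sd normal prior for covariate coefficients.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(lgamma_lower = -10, lgamma_upper = 5,
                       tau_lower = 0, tau_upper = 1,
                       b_mean = 0, b_sd = 10) {
  if (lgamma_lower >= lgamma_upper || tau_lower >= tau_upper || b_sd <= 0)
    stop("invalid prior bounds", call. = FALSE)
  structure(list(lgamma_lower = lgamma_lower, lgamma_upper = lgamma_upper,
                 tau_lower = tau_lower, tau_upper = tau_upper,
                 b_mean = b_mean, b_sd = b_sd),
            class = "prior_spec")
}

# Resolve within-arm equality constraints to one representative transition
# per equivalence class (tiny union-find over the four names).
.constraint_rep <- function(constraints) {
  rep_of <- stats::setNames(.TRANSITIONS, .TRANSITIONS)
  find <- function(x) { while (rep_of[[x]] != x) x <- rep_of[[x]]; x }
  for (p in constraints) {
    a <- find(p[1]); b <- find(p[2])
    if (a != b) rep_of[[max(a, b)]] <- min(a, b)
  }
  vapply(.TRANSITIONS, find, "")
}

# Map model + arms to the free-parameter layout: a name for every
# (arm, transition) log-rate cell, covariate-coefficient cells, and tau.
.param_map <- function(model, arms) {
  stopifnot(inherits(model, "model_spec"), length(arms) >= 1L)
  rep_of <- .constraint_rep(model$constraints)
  lg <- matrix("", nrow = length(arms), ncol = 4L,
               dimnames = list(arms, .TRANSITIONS))
  for (a in arms) for (tr in .TRANSITIONS) {
    r <- rep_of[[tr]]
    lg[a, tr] <- if (r %in% model$shared) paste0("l", r)
                 else paste0("l", r, ".", a)
  }
  b <- matrix(NA_character_, nrow = length(arms), ncol = 4L,
              dimnames = list(arms, .TRANSITIONS))
  cov_of <- matrix(NA_character_, nrow = length(arms), ncol = 4L,
                   dimnames = list(arms, .TRANSITIONS))
  if (length(model$covariates)) {
    brep <- stats::setNames(.TRANSITIONS, .TRANSITIONS)
    for (grp in model$b_groups)
      for (tr in grp) brep[[tr]] <- grp[1]
    for (a in arms) for (tr in names(model$covariates)) {
      cov_of[a, tr] <- model$covariates[[tr]]
      b[a, tr] <- if (model$b_shared_across_arms) paste0("b_", brep[[tr]])
                  else paste0("b_", brep[[tr]], ".", a)
    }
  }
  tau <- character(0)
  tau_of <- stats::setNames(rep(NA_character_, 4L), .TRANSITIONS)
  if (length(model$random_effects)) {
    if (model$common_tau) {
      tau <- "tau"
      tau_of[model$random_effects] <- "tau"
    } else {
      tau <- paste0("tau_", model$random_effects)
      tau_of[model$random_effects] <- tau
    }
  }
  free <- c(unique(as.vector(lg)),
            unique(stats::na.omit(as.vector(b))), unique(tau))
  types <- c(rep("lgamma", length(unique(as.vector(lg)))),
             rep("b", length(unique(stats::na.omit(as.vector(b))))),
             rep("tau", length(unique(tau))))
  list(lgamma = lg, b = b, cov_of = cov_of, tau_of = tau_of,
       free = free, type = stats::setNames(types, free), arms = arms)
}

# theta (named vector over pm$free) -> list of per-arm structures.
.expand_theta <- function(theta, pm) {
  lr <- matrix(theta[pm$lgamma], nrow = nrow(pm$lgamma),
               dimnames = dimnames(pm$lgamma))
  bm <- matrix(0, nrow = nrow(pm$lgamma), ncol = 4L,
               dimnames = dimnames(pm$lgamma))
  has_b <- !is.na(pm$b)
  if (any(has_b)) bm[has_b] <- theta[pm$b[has_b]]
  tau <- stats::setNames(rep(0, 4L), .TRANSITIONS)
  has_tau <- !is.na(pm$tau_of)
  if (any(has_tau)) tau[has_tau] <- theta[pm$tau_of[has_tau]]
  list(log_rates = lr, b = bm, tau = tau)
}
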