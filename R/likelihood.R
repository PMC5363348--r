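#' Multinomial transition log-likelihood
#'
#' Each consecutive pair of observed states in a record is one multinomial
#' draw over the three destinations, with cell probabilities given by the row
#' of the transition probability matrix for the elapsed time between the two
#' observations. The dataset log-likelihood is the sum of the log
#' probabilities of all observed transitions across patients (the Markov
#' property makes the per-transition terms independent given the rates).
#'
#' @param dataset a [study_dataset()].
#' @param rates_by_arm named list, one [transition_rates3()] per arm label
#'   appearing in the dataset.
#' @param patient_effects optional numeric matrix of per-patient log-rate
#'   offsets, `length(dataset) x 4` with columns `gamma12, gamma13, gamma21,
#'   gamma23` — the sum of any covariate effect and random effect on the log
#'   scale. Patient `i`'s rates are `rates_by_arm[[arm_i]] *
#'   exp(patient_effects[i, ])`.
#' @return The log-likelihood; `-Inf` when any observed transition has
#'   probability zero.
#' @export
log_likelihood <- function(dataset, rates_by_arm, patient_effects = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  tab <- .transition_table(dataset)
  if (nrow(tab) == 0L) return(0)
  miss <- setdiff(unique(tab$arm), names(rates_by_arm))
  if (length(miss))
    stop("no rates supplied for arm(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  R <- t(vapply(rates_by_arm, function(r) unclass(.assert_rates3(r)),
                numeric(4)))
  colnames(R) <- .TRANSITIONS
  arm_idx <- match(tab$arm, names(rates_by_arm))
  rr <- R[arm_idx, , drop = FALSE]
  if (!is.null(patient_effects)) {
    if (!is.matrix(patient_effects) ||
        nrow(patient_effects) != length(dataset$records) ||
        ncol(patient_effects) != 4L)
      stop("patient_effects must be a (n patients) x 4 matrix", call. = FALSE)
    rr <- rr * exp(patient_effects[tab$patient, , drop = FALSE])
  }
  p <- .pi_entry(rr[, 1], rr[, 2], rr[, 3], rr[, 4],
                 tab$from, tab$to, tab$dt)
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

# Fast log-likelihood over aggregated (arm, from, to, dt) counts at
# arm-level rates only. `agg` from .aggregate_transitions(); `R` a
# (n arms x 4) rate matrix with rownames = arm labels. Returns the per-arm
# contributions so samplers can update one arm at a time.
.loglik_agg_by_arm <- function(agg, R) {
  out <- stats::setNames(rep(0, nrow(R)), rownames(R))
  if (nrow(agg) == 0L) return(out)
  idx <- match(agg$arm, rownames(R))
  rr <- R[idx, , drop = FALSE]
  p <- .pi_entry(rr[, 1], rr[, 2], rr[, 3], rr[, 4],
                 agg$from, agg$to, agg$dt)
  ll <- ifelse(p > 0, agg$n * log(p), -Inf)
  for (a in rownames(R)) out[a] <- sum(ll[agg$arm == a])
  out
}

# Per-patient log-likelihood at patient-specific rates. `tab` the long
# transition table; `rates_rows` an nrow(tab) x 4 matrix of the rates
# applying to each transition row. Returns a vector indexed by patient id
# over 1..n_patients.
.loglik_by_patient <- function(tab, rates_rows, n_patients) {
  out <- rep(0, n_patients)
  if (nrow(tab) == 0L) return(out)
  p <- .pi_entry(rates_rows[, 1], rates_rows[, 2], rates_rows[, 3],
                 rates_rows[, 4], tab$from, tab$to, tab$dt)
  lp <- ifelse(p > 0, log(p), -Inf)
  sums <- rowsum(lp, tab$patient)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

# Covariate values per patient for the covariate names a model uses;
# errors when a needed covariate is missing for some patient.
.covariate_matrix <- function(dataset, cov_names) {
  if (length(cov_names) == 0L)
    return(matrix(0, nrow = length(dataset$records), ncol = 0L))
  C <- matrix(NA_real_, nrow = length(dataset$records),
              ncol = length(cov_names), dimnames = list(NULL, cov_names))
  for (i in seq_along(dataset$records)) {
    cv <- dataset$records[[i]]$covariates
    for (cn in cov_names)
      if (!is.null(cv) && cn %in% names(cv)) C[i, cn] <- cv[[cn]]
  }
  if (any(is.na(C)))
    stop("covariate(s) missing for some patients: ",
         paste(cov_names[colSums(is.na(C)) > 0], collapse = ", "),
         call. = FALSE)
  C
}

# nrow(tab) x 4 matrix of patient-specific rates implied by theta
# (+ optional latent offsets u, an n_patients x 4 matrix).
.rates_rows <- function(tab, ex, pm, C, u = NULL) {
  arm_i <- match(tab$arm, pm$arms)
  lr <- ex$log_rates[arm_i, , drop = FALSE]
  if (ncol(C) > 0L) {
    for (tr in seq_len(4L)) {
      cn <- pm$cov_of[cbind(arm_i, tr)]
      has <- !is.na(cn)
      if (any(has))
        lr[has, tr] <- lr[has, tr] +
          ex$b[cbind(arm_i[has], tr)] *
            C[cbind(tab$patient[has], match(cn[has], colnames(C)))]
    }
  }
  if (!is.null(u)) lr <- lr + u[tab$patient, , drop = FALSE]
  exp(lr)
}
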