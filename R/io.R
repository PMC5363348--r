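#' Read a long-format study dataset from CSV
#'
#' One row per patient-visit with header columns `patient_id`, `arm`,
#' `time`, `state` (1/2/3 or empty for a missed visit); any further numeric
#' columns are taken as patient-level covariates (constant within patient).
#' A row at time 0 with state 1 is accepted and folded into the implicit
#' baseline. Validation failures name the offending data row.
#'
#' @param path CSV file path.
#' @return A [study_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "time", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(study_dataset(list()))
  df$state <- suppressWarnings(as.integer(df$state))
  df$time <- as.numeric(df$time)
  bad <- which(!is.na(df$state) & !(df$state %in% 1:3))
  if (length(bad))
    stop("invalid state at data row ", bad[1], ": must be 1, 2, 3 or empty",
         call. = FALSE)
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad))
    stop("invalid time at data row ", bad[1], call. = FALSE)
  key <- paste(df$patient_id, df$time)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, time) at data row ",
         which(duplicated(key))[1], call. = FALSE)
  at0 <- df$time == 0
  if (any(at0)) {
    bad <- which(at0 & !is.na(df$state) & df$state != 1L)
    if (length(bad))
      stop("state at time 0 must be 1 (all patients start in nonresponse); ",
           "data row ", bad[1], call. = FALSE)
    df <- df[!at0, , drop = FALSE]
  }
  cov_cols <- setdiff(names(df), need)
  records <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    cov <- NULL
    if (length(cov_cols)) {
      cov <- vapply(cov_cols, function(cn) as.numeric(d[[cn]][1]), 0)
      if (all(is.na(cov))) cov <- NULL else names(cov) <- cov_cols
    }
    patient_record(d$patient_id[1], d$arm[1], d$time, d$state,
                   covariates = cov)
  })
  study_dataset(unname(records))
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_dataset()]: writing then reading reproduces the dataset
#' in canonical form (records sorted by patient id).
#'
#' @param dataset a [study_dataset()].
#' @param path output CSV path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  df <- as.data.frame(dataset)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Recode trailing missed visits as dropout
#'
#' The preprocessing rule of the motivating trial: a patient who misses a
#' visit and every subsequent one is coded as having dropped out from the
#' first visit of that trailing run onward. Interior missing runs followed
#' by an observed state are left untouched (the likelihood handles them by
#' lengthening the elapsed time).
#'
#' @param dataset a [study_dataset()].
#' @return A new [study_dataset()].
#' @export
recode_missing_as_dropout <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  records <- lapply(dataset$records, function(r) {
    st <- r$states
    n <- length(st)
    if (n && is.na(st[n])) {
      i <- n
      while (i > 1L && is.na(st[i - 1L])) i <- i - 1L
      st[i:n] <- 3L
    }
    patient_record(r$patient_id, r$arm, r$times, st, covariates = r$covariates)
  })
  study_dataset(records, schedule = dataset$schedule)
}

#' State-occupancy curves from nonresponse
#'
#' Tabulates `pi_{1,state}(t)` per arm on a time grid — the model-based
#' occupancy curves that can be overlaid on the observed proportions from
#' [aggregate_counts()].
#'
#' @param fit a `"markov_fit"` or named list of [transition_rates3()].
#' @param times numeric grid of elapsed times.
#' @return Data frame with columns `arm`, `time`, `p_state1`, `p_state2`,
#'   `p_state3` (rows sum to 1).
#' @export
occupancy_curves <- function(fit, times) {
  src <- .rates_source(fit)
  rows <- list()
  for (a in names(src$point)) {
    r <- src$point[[a]]
    for (t in times) {
      P <- transition_probs(r, t)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = a, time = t, p_state1 = P[1, 1],
                   p_state2 = P[1, 2], p_state3 = P[1, 3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
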