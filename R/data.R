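#' A single patient's visit history
#'
#' One record per randomized patient: an ordered sequence of visit times and
#' observed states. Every patient implicitly starts in state 1 (nonresponse)
#' at time 0; that baseline observation is not stored. A missing state (`NA`)
#' marks a skipped visit: the patient was still in the study but not
#' observed, so the flanking observed states simply span a longer elapsed
#' time. Once state 3 (dropout) is observed every later observed state must
#' be 3.
#'
#' @param patient_id character scalar identifier.
#' @param arm treatment-arm label (character or integer-like scalar).
#' @param times strictly increasing positive visit times.
#' @param states integer states in `{1, 2, 3}` or `NA` for a skipped visit;
#'   same length as `times`.
#' @param covariates optional named numeric vector of patient-level
#'   covariates.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, arm, times, states, covariates = NULL) {
  patient_id <- as.character(patient_id)[1]
  arm <- as.character(arm)[1]
  times <- as.numeric(times)
  if (length(times) != length(states))
    stop("times and states must have equal length", call. = FALSE)
  if (length(times) == 0L)
    stop("a patient record needs at least one visit", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("visit times must be finite and > 0 (time 0 is the implicit ",
         "nonresponse baseline)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("visit times must be strictly increasing for patient ",
         patient_id, call. = FALSE)
  states <- as.integer(states)
  obs <- states[!is.na(states)]
  if (any(!(obs %in% 1:3)))
    stop("states must be 1, 2, 3 or NA (patient ", patient_id, ")",
         call. = FALSE)
  so <- states[!is.na(states)]
  if (length(so) > 1L) {
    first3 <- match(3L, so)
    if (!is.na(first3) && first3 < length(so) && any(so[(first3 + 1):length(so)] != 3L))
      stop("dropout is absorbing: patient ", patient_id,
           " has a non-dropout state after an observed dropout", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- unlist(covariates)
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      stop("covariates must be named", call. = FALSE)
  }
  structure(list(patient_id = patient_id, arm = arm, times = times,
                 states = states, covariates = covariates),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("Patient", x$patient_id, "(arm ", x$arm, "):\n", sep = "")
  print(data.frame(time = c(0, x$times), state = c(1L, x$states)),
        row.names = FALSE)
  invisible(x)
}

#' A study dataset of patient records
#'
#' @param records a list of [patient_record()] objects.
#' @param schedule optional common visit schedule (strictly increasing
#'   positive times) used for tabulation; inferred as the union of observed
#'   visit times when omitted.
#' @return An object of class `"study_dataset"` with elements `records`,
#'   `arms` (sorted unique arm labels) and `schedule`.
#' @export
study_dataset <- function(records, schedule = NULL) {
  if (!is.list(records) || !all(vapply(records, inherits, TRUE, "patient_record")))
    stop("records must be a list of patient_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  arms <- sort(unique(vapply(records, `[[`, "", "arm")))
  if (is.null(schedule) && length(records))
    schedule <- sort(unique(unlist(lapply(records, `[[`, "times"))))
  structure(list(records = records, arms = arms, schedule = schedule),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study dataset:", length(x$records), "patients in",
      length(x$arms), "arm(s)",
      if (length(x$arms)) paste0("(", paste(x$arms, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' @export
length.study_dataset <- function(x) length(x$records)

#' Observed transitions of a patient record
#'
#' Pairs consecutive non-missing observations (including the implicit state-1
#' baseline at time 0) into `(from, to, dt)` triples — the unit of
#' information of the multinomial transition likelihood. A skipped visit
#' contributes no pair of its own; it lengthens the elapsed time between its
#' flanking observed states. Pairs that would start in the absorbing dropout
#' state carry probability one and are omitted.
#'
#' @param record a [patient_record()].
#' @return A data frame with columns `from`, `to` (integer states) and `dt`.
#' @examples
#' rec <- patient_record("k", "A", times = c(1, 2, 4), states = c(2, 1, 3))
#' transitions_from_record(rec)
#' @export
transitions_from_record <- function(record) {
  if (!inherits(record, "patient_record"))
    stop("expected a patient_record", call. = FALSE)
  t <- c(0, record$times)
  s <- c(1L, record$states)
  keep <- !is.na(s)
  t <- t[keep]; s <- s[keep]
  n <- length(s)
  if (n < 2L)
    return(data.frame(from = integer(), to = integer(), dt = numeric()))
  out <- data.frame(from = s[-n], to = s[-1], dt = diff(t))
  out[out$from != 3L, , drop = FALSE]
}

# Long table of every observed transition in the dataset, with patient and
# arm indices attached; the likelihood engines work from this.
.transition_table <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  pieces <- lapply(seq_along(dataset$records), function(i) {
    tr <- transitions_from_record(dataset$records[[i]])
    if (nrow(tr) == 0L) return(NULL)
    tr$patient <- i
    tr$arm <- dataset$records[[i]]$arm
    tr
  })
  tab <- do.call(rbind, pieces)
  if (is.null(tab))
    tab <- data.frame(from = integer(), to = integer(), dt = numeric(),
                      patient = integer(), arm = character())
  rownames(tab) <- NULL
  tab
}

# Collapse a transition table to (arm, from, to, dt) counts; valid when all
# patients in an arm share the same rates.
.aggregate_transitions <- function(tab) {
  if (nrow(tab) == 0L)
    return(data.frame(arm = character(), from = integer(), to = integer(),
                      dt = numeric(), n = integer()))
  key <- paste(tab$arm, tab$from, tab$to, tab$dt, sep = "\r")
  agg <- tab[!duplicated(key), c("arm", "from", "to", "dt")]
  agg$n <- as.integer(table(key)[paste(agg$arm, agg$from, agg$to, agg$dt,
                                       sep = "\r")])
  rownames(agg) <- NULL
  agg
}

#' Coerce a study dataset to a long-format data frame
#'
#' @param x a [study_dataset()].
#' @param row.names,optional,... passed for method compatibility; unused.
#' @return A data frame with columns `patient_id`, `arm`, `time`, `state`
#'   plus one column per covariate.
#' @export
as.data.frame.study_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  cov_names <- unique(unlist(lapply(x$records, function(r) names(r$covariates))))
  rows <- lapply(x$records, function(r) {
    d <- data.frame(patient_id = r$patient_id, arm = r$arm,
                    time = r$times, state = r$states,
                    stringsAsFactors = FALSE)
    for (cn in cov_names)
      d[[cn]] <- if (!is.null(r$covariates) && cn %in% names(r$covariates))
        r$covariates[[cn]] else NA_real_
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
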