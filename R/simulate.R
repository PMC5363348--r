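# Exact continuous-time path of one patient under generator Q, from state 1
# at time 0 until t_end. Uses the current RNG stream. Returns the jump
# chain: times (starting at 0) and states (integer row indices of Q).
.sim_path_scalar <- function(Q, t_end) {
  exit <- -diag(Q)
  K <- nrow(Q)
  times <- 0
  states <- 1L
  s <- 1L
  t <- 0
  while (exit[s] > 0) {
    t <- t + stats::rexp(1, exit[s])
    if (t >= t_end) break
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(K, 1L, prob = p)
    times <- c(times, t)
    states <- c(states, s)
  }
  list(times = times, states = states)
}

.state_at <- function(path, t) {
  path$states[findInterval(t, path$times)]
}

#' Simulate one patient trajectory under the three-state model
#'
#' Exact event-driven simulation of the continuous-time chain: holding
#' times are exponential with the total exit rate of the current state and
#' the destination is chosen with probabilities proportional to the
#' outgoing rates. The continuous path is then observed only at the
#' scheduled visit times, mirroring panel observation; the absorbing
#' dropout state persists.
#'
#' @param rates a [transition_rates3()].
#' @param schedule strictly increasing positive visit times.
#' @param patient_id,arm labels for the returned record.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return A [patient_record()] with an attribute `"path"` holding the full
#'   continuous jump chain.
#' @export
simulate_trajectory <- function(rates, schedule = c(1, 2, 4, 6, 8),
                                patient_id = "1", arm = "1", seed = NULL) {
  r <- .assert_rates3(rates)
  if (any(diff(c(0, schedule)) <= 0))
    stop("schedule must be strictly increasing and positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  path <- .sim_path_scalar(build_generator(r), max(schedule))
  rec <- patient_record(patient_id, arm, schedule, .state_at(path, schedule))
  attr(rec, "path") <- path
  rec
}

#' Configuration of a synthetic two-arm trial
#'
#' Emulates the design of the motivating schizophrenia trial: a fixed visit
#' schedule at weeks 1, 2, 4, 6 and 8, all patients starting in
#' nonresponse, arm-specific transition rates, optional patient-level
#' log-normal random effects and a normal covariate, and an optional
#' missed-visit process that is independent of everything (a missed visit
#' is recorded as missing, never converted to dropout).
#'
#' @param rates named list of [transition_rates3()], one per arm.
#' @param n_per_arm integer vector (recycled) of patients per arm.
#' @param schedule visit times.
#' @param tau random-effects SD of the log rates: a scalar applied to all
#'   four transitions or a named vector (names among the `gammaXY`); 0
#'   disables.
#' @param covariate_coefs optional named list mapping transition names to a
#'   coefficient on a standard-normal patient covariate `"c1"`.
#' @param miss_prob probability that a visit of a still-in-study patient is
#'   missed.
#' @param seed master seed; each patient draws from an own substream so
#'   records are reproducible under reordering.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(rates, n_per_arm, schedule = c(1, 2, 4, 6, 8),
                       tau = 0, covariate_coefs = NULL, miss_prob = 0,
                       seed = 1) {
  if (!is.list(rates) || is.null(names(rates)))
    stop("rates must be a named list (one element per arm)", call. = FALSE)
  rates <- lapply(rates, .assert_rates3)
  if (any(diff(c(0, schedule)) <= 0))
    stop("schedule must be strictly increasing and positive", call. = FALSE)
  if (miss_prob < 0 || miss_prob > 1)
    stop("miss_prob must be in [0, 1]", call. = FALSE)
  tau_vec <- stats::setNames(rep(0, 4L), .TRANSITIONS)
  if (length(tau) == 1L && is.null(names(tau))) {
    tau_vec[] <- tau
  } else {
    bad <- setdiff(names(tau), .TRANSITIONS)
    if (length(bad)) stop("unknown transition in tau: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tau_vec[names(tau)] <- tau
  }
  if (any(tau_vec < 0)) stop("tau must be >= 0", call. = FALSE)
  structure(list(rates = rates, n_per_arm = rep_len(n_per_arm, length(rates)),
                 schedule = schedule, tau = tau_vec,
                 covariate_coefs = covariate_coefs, miss_prob = miss_prob,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a full study dataset
#'
#' Per patient: draw the covariate and the log-rate random effects, build
#' the patient-specific rates, simulate an exact trajectory, observe it at
#' the schedule, and independently blank still-in-study visits with the
#' missed-visit probability. Deterministic given the config seed; each
#' patient uses a seed derived from the master seed and their global index.
#'
#' @param config a [sim_config()].
#' @return A [study_dataset()]. The matrix of realized per-patient log-rate
#'   offsets (random effect plus covariate term) is attached as attribute
#'   `"offsets"` for generator checks.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arms <- names(config$rates)
  n_tot <- sum(config$n_per_arm)
  records <- vector("list", n_tot)
  offsets <- matrix(0, nrow = n_tot, ncol = 4L,
                    dimnames = list(NULL, .TRANSITIONS))
  idx <- 0L
  has_re <- any(config$tau > 0)
  has_cov <- length(config$covariate_coefs) > 0L
  # per-patient substreams: seeds drawn once from the master stream, so the
  # i-th patient's record is reproducible independently of the others
  set.seed(config$seed)
  patient_seeds <- sample.int(.Machine$integer.max, n_tot)
  for (a in seq_along(arms)) {
    base <- unclass(config$rates[[a]])
    for (i in seq_len(config$n_per_arm[a])) {
      idx <- idx + 1L
      set.seed(patient_seeds[idx])
      cov <- NULL
      off <- stats::setNames(rep(0, 4L), .TRANSITIONS)
      if (has_cov) {
        cval <- stats::rnorm(1)
        cov <- c(c1 = cval)
        for (tr in names(config$covariate_coefs))
          off[tr] <- off[tr] + config$covariate_coefs[[tr]] * cval
      }
      if (has_re)
        off <- off + stats::rnorm(4L, 0, config$tau)
      offsets[idx, ] <- off
      pr <- unname(base * exp(off))
      path <- .sim_path_scalar(
        build_generator(transition_rates3(pr[1], pr[2], pr[3], pr[4])),
        max(config$schedule))
      st <- .state_at(path, config$schedule)
      if (config$miss_prob > 0) {
        miss <- stats::runif(length(st)) < config$miss_prob & st %in% 1:2
        st[miss] <- NA_integer_
      }
      records[[idx]] <- patient_record(
        paste0(arms[a], "-", i), arms[a], config$schedule, st,
        covariates = cov)
    }
  }
  out <- study_dataset(records, schedule = config$schedule)
  attr(out, "offsets") <- offsets
  out
}

# Vectorised exact simulation of n paths under generator Q from state 1,
# tracking the per-path summary the oracles need. `block` = indices of the
# dropout block (states that cannot be left except within the block).
.sim_paths <- function(Q, t_end, n, block = integer(0)) {
  K <- nrow(Q)
  labels <- rownames(Q)
  if (is.null(labels)) labels <- as.character(seq_len(K))
  exit <- -diag(Q)
  state <- rep(1L, n)
  time <- rep(0, n)
  visited <- matrix(FALSE, nrow = n, ncol = K)
  visited[, 1] <- TRUE
  drop_from <- rep(NA_integer_, n)
  drop_time <- rep(NA_real_, n)
  active <- rep(exit[1] > 0, n)
  while (any(active)) {
    idx <- which(active)
    dtv <- stats::rexp(length(idx), exit[state[idx]])
    newt <- time[idx] + dtv
    stopping <- newt >= t_end
    active[idx[stopping]] <- FALSE
    jump <- idx[!stopping]
    if (length(jump)) {
      time[jump] <- newt[!stopping]
      old <- state[jump]
      dest <- integer(length(jump))
      u <- stats::runif(length(jump))
      for (s in unique(old)) {
        rows <- old == s
        p <- Q[s, ]
        p[s] <- 0
        cp <- cumsum(p / sum(p))
        dest[rows] <- findInterval(u[rows], cp, left.open = TRUE) + 1L
      }
      state[jump] <- dest
      visited[cbind(jump, dest)] <- TRUE
      entering <- !(old %in% block) & (dest %in% block)
      if (any(entering)) {
        drop_from[jump[entering]] <- old[entering]
        drop_time[jump[entering]] <- time[jump[entering]]
      }
      active[jump] <- exit[dest] > 0
    }
  }
  out <- data.frame(final = as.integer(labels[state]))
  for (k in seq_len(K))
    out[[paste0("visited_", labels[k])]] <- visited[, k]
  out$dropout_from <- ifelse(is.na(drop_from), NA_integer_,
                             as.integer(labels[drop_from]))
  out$dropout_time <- drop_time
  out
}

#' Monte-Carlo probability of a path event
#'
#' Simulates exact continuous trajectories from state 1 and estimates the
#' probability that a path-level predicate holds at time `dt`, with a
#' binomial standard error. This is the correctness oracle for the analytic
#' dropout-path probabilities and the four-state scenario probabilities.
#'
#' The predicate receives a data frame with one row per path and columns
#' `final` (state label at `dt`), `visited_<label>` (logical, ever visited),
#' `dropout_from` (state label from which the dropout state/block was
#' entered, `NA` if never) and `dropout_time`, and must return a logical
#' vector.
#'
#' @param rates a [transition_rates3()] or [four_state_rates()].
#' @param dt horizon.
#' @param predicate function of the path-summary data frame.
#' @param n_paths number of simulated paths (a warning is issued below
#'   1000).
#' @param seed RNG seed.
#' @return A list with `estimate`, `se` and `n`.
#' @examples
#' ami <- transition_rates3(0.189, 0.052, 0.076, 0.024)
#' monte_carlo_path_probability(ami, 8,
#'   function(p) p$final == 3 & !p$visited_2, n_paths = 2000)
#' @export
monte_carlo_path_probability <- function(rates, dt, predicate,
                                         n_paths = 1e5, seed = 1) {
  if (n_paths < 1000)
    warning("fewer than 1000 paths: the Monte-Carlo error will be large")
  if (inherits(rates, "four_state_rates")) {
    Q <- four_state_generator(rates)
    block <- 3:4
  } else {
    Q <- build_generator(.assert_rates3(rates))
    block <- 3L
  }
  set.seed(seed)
  feats <- .sim_paths(Q, dt, n_paths, block = block)
  hit <- predicate(feats)
  if (!is.logical(hit) || length(hit) != n_paths)
    stop("predicate must return one logical per path", call. = FALSE)
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / n_paths), n = n_paths)
}

#' Aggregated state counts by arm and visit time
#'
#' Counts patients observed in each state (plus missed visits) at every
#' scheduled time, per arm — the aggregate view of the dataset. The baseline
#' time 0 is included, where by construction everyone is in nonresponse.
#' Counts in each row sum to the arm size.
#'
#' @param dataset a [study_dataset()].
#' @param schedule visit times to tabulate; defaults to the dataset
#'   schedule.
#' @return A data frame with columns `arm`, `time`, `n_state1`, `n_state2`,
#'   `n_state3`, `n_missing`.
#' @export
aggregate_counts <- function(dataset, schedule = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(schedule)) schedule <- dataset$schedule
  if (length(dataset$records) == 0L || length(schedule) == 0L)
    return(data.frame(arm = character(), time = numeric(),
                      n_state1 = integer(), n_state2 = integer(),
                      n_state3 = integer(), n_missing = integer()))
  rows <- list()
  for (a in dataset$arms) {
    recs <- Filter(function(r) r$arm == a, dataset$records)
    for (t in c(0, schedule)) {
      cnt <- c(0L, 0L, 0L, 0L)
      for (r in recs) {
        s <- if (t == 0) 1L else {
          i <- which(abs(r$times - t) < 1e-8)
          if (length(i) == 1L) r$states[i] else NA_integer_
        }
        if (is.na(s)) cnt[4] <- cnt[4] + 1L else cnt[s] <- cnt[s] + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.frame(arm = a, time = t, n_state1 = cnt[1], n_state2 = cnt[2],
                   n_state3 = cnt[3], n_missing = cnt[4])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
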