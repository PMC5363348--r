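#' Transition rates for the three-state model
#'
#' Constructs the parameter object of the three-state continuous-time Markov
#' model: nonresponse (state 1) and response (state 2) communicate in both
#' directions, and both feed the absorbing dropout state (state 3). The four
#' rates are instantaneous hazards in units of inverse time (per week when
#' visit times are in weeks).
#'
#' @param gamma12 rate of the nonresponse-to-response transition (1 -> 2).
#' @param gamma13 rate of dropout from nonresponse (1 -> 3).
#' @param gamma21 relapse rate, response back to nonresponse (2 -> 1).
#' @param gamma23 rate of dropout from response (2 -> 3).
#' @return An object of class `"transition_rates3"`: a named numeric vector
#'   with elements `gamma12`, `gamma13`, `gamma21`, `gamma23`.
#' @examples
#' transition_rates3(0.189, 0.052, 0.076, 0.024)
#' @export
transition_rates3 <- function(gamma12, gamma13, gamma21, gamma23) {
  x <- c(gamma12 = gamma12, gamma13 = gamma13,
         gamma21 = gamma21, gamma23 = gamma23)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("rate '", nm, "' must be nonnegative, got ", v, call. = FALSE)
  }
  structure(x, class = "transition_rates3")
}

#' @export
print.transition_rates3 <- function(x, ...) {
  cat("3-state transition rates (per unit time):\n")
  print(unclass(x), ...)
  invisible(x)
}

.assert_rates3 <- function(rates) {
  if (!inherits(rates, "transition_rates3")) {
    if (is.numeric(rates) && length(rates) == 4L)
      return(transition_rates3(rates[[1]], rates[[2]], rates[[3]], rates[[4]]))
    stop("expected a 'transition_rates3' object", call. = FALSE)
  }
  rates
}

#' Generator (intensity) matrix of the three-state model
#'
#' Row q holds the rates out of state q; the diagonal is minus the total exit
#' rate so every row sums to zero. The dropout row is identically zero because
#' state 3 is absorbing.
#'
#' @param rates a [transition_rates3()] object.
#' @return A 3 x 3 numeric matrix with zero row sums.
#' @export
build_generator <- function(rates) {
  r <- .assert_rates3(rates)
  G <- matrix(c(-(r[["gamma12"]] + r[["gamma13"]]), r[["gamma12"]], r[["gamma13"]],
                r[["gamma21"]], -(r[["gamma21"]] + r[["gamma23"]]), r[["gamma23"]],
                0, 0, 0),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  G
}

.validate_generator <- function(G, tol = 1e-12) {
  if (!is.matrix(G) || nrow(G) != ncol(G) || !is.numeric(G))
    stop("generator must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(G)))
    stop("generator contains non-finite entries", call. = FALSE)
  off <- G
  diag(off) <- 0
  if (any(off < -tol))
    stop("generator has negative off-diagonal entries", call. = FALSE)
  if (any(diag(G) > tol))
    stop("generator has positive diagonal entries", call. = FALSE)
  rs <- rowSums(G)
  if (any(abs(rs) > 1e-9))
    stop("generator rows must sum to 0 (max |row sum| = ",
         format(max(abs(rs))), ")", call. = FALSE)
  invisible(G)
}

#' Exit rates and the discriminant of the closed-form solution
#'
#' `lambda1 = gamma12 + gamma13` and `lambda2 = gamma21 + gamma23` are the
#' total exit rates from states 1 and 2. The discriminant
#' `h = sqrt((lambda1 - lambda2)^2 + 4 gamma12 gamma21)` governs the two
#' exponential decay modes of the transient block.
#'
#' @param rates a [transition_rates3()] object.
#' @return A list with elements `lambda1`, `lambda2`, `h`.
#' @export
exit_rates <- function(rates) {
  r <- .assert_rates3(rates)
  l1 <- r[["gamma12"]] + r[["gamma13"]]
  l2 <- r[["gamma21"]] + r[["gamma23"]]
  list(lambda1 = l1, lambda2 = l2,
       h = sqrt((l1 - l2)^2 + 4 * r[["gamma12"]] * r[["gamma21"]]))
}

.new_tpm <- function(M, dt, labels) {
  dimnames(M) <- list(labels, labels)
  # distinguish float round-off from real defects before clipping
  if (any(M < -1e-10) || any(M > 1 + 1e-10) || any(abs(rowSums(M) - 1) > 1e-9))
    stop("internal error: transition probability matrix violates ",
         "stochasticity beyond round-off", call. = FALSE)
  M[M < 0] <- 0
  M[M > 1] <- 1
  M <- M / rowSums(M)
  structure(M, dt = dt, class = c("tpm", "matrix", "array"))
}

#' @export
print.tpm <- function(x, digits = 6, ...) {
  cat("Transition probabilities over dt =", attr(x, "dt"), "\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(round(y, digits), ...)
  invisible(x)
}

#' Closed-form transition probabilities of the three-state model
#'
#' Evaluates the analytic solution of the Kolmogorov forward equation for the
#' illness-death structure: the transient 2x2 block decays as a mixture of
#' `exp(-(lambda1+lambda2-h)t/2)` and `exp(-(lambda1+lambda2+h)t/2)`, and the
#' dropout column is the complement. When the analytic expressions are
#' degenerate (`h` near zero, or `gamma21` near zero in the direct form of
#' pi_12) the computation transparently falls back to the matrix exponential.
#'
#' @param rates a [transition_rates3()] object.
#' @param dt elapsed time, same unit as the rates; must be >= 0.
#' @param method `"auto"` (default: closed form with expm fallback),
#'   `"closed"` (error if degenerate), or `"expm"`.
#' @return A 3 x 3 row-stochastic matrix of class `"tpm"` with the elapsed
#'   time attached as attribute `dt`.
#' @examples
#' ami <- transition_rates3(0.189, 0.052, 0.076, 0.024)
#' transition_probs(ami, dt = 8)
#' @export
transition_probs <- function(rates, dt, method = c("auto", "closed", "expm")) {
  method <- match.arg(method)
  r <- .assert_rates3(rates)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a single nonnegative number", call. = FALSE)
  if (method == "expm")
    return(transition_probs_expm(build_generator(r), dt))
  ex <- exit_rates(r)
  degenerate <- ex$h < 1e-10 || r[["gamma21"]] < 1e-12
  if (degenerate) {
    if (method == "closed")
      stop("closed form is degenerate for these rates (h or gamma21 ~ 0); ",
           "use method = 'auto' or 'expm'", call. = FALSE)
    return(transition_probs_expm(build_generator(r), dt))
  }
  l1 <- ex$lambda1; l2 <- ex$lambda2; h <- ex$h
  e1 <- exp(-0.5 * (l1 + l2 - h) * dt)
  e2 <- exp(-0.5 * (l1 + l2 + h) * dt)
  p11 <- ((-l1 + l2 + h) * e1 + (l1 - l2 + h) * e2) / (2 * h)
  p12 <- ((-l1 + l2 + h) * (l1 - l2 + h) * (e1 - e2)) / (4 * h * r[["gamma21"]])
  p21 <- r[["gamma21"]] * (e1 - e2) / h
  p22 <- ((l1 - l2 + h) * e1 + (-l1 + l2 + h) * e2) / (2 * h)
  M <- matrix(c(p11, p12, 1 - p11 - p12,
                p21, p22, 1 - p21 - p22,
                0, 0, 1), nrow = 3L, byrow = TRUE)
  .new_tpm(M, dt, c("1", "2", "3"))
}

#' Transition probabilities by matrix exponential
#'
#' Computes `exp(dt * G)` for an arbitrary finite generator matrix via
#' scaling-and-squaring (the [Matrix::expm()] engine). This is the general
#' solution of the Kolmogorov forward equation and works for any state count;
#' the four-state hidden-state model uses it directly.
#'
#' @param generator a square generator matrix (zero row sums, nonnegative
#'   off-diagonals).
#' @param dt elapsed time >= 0.
#' @return A row-stochastic matrix of class `"tpm"`.
#' @export
transition_probs_expm <- function(generator, dt) {
  .validate_generator(generator)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a single nonnegative number", call. = FALSE)
  labels <- rownames(generator)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(generator)))
  M <- as.matrix(Matrix::expm(dt * generator))
  .new_tpm(M, dt, labels)
}

# Vectorised single-entry transition probabilities pi_{from,to}(dt) for the
# 3-state model; all arguments recycled to common length. Used by the
# likelihood engines where per-patient rates differ. Uses the symmetric form
# pi12 = gamma12 (e1 - e2) / h (identical to the direct expression when
# gamma21 > 0, and well defined when gamma21 = 0); rows with h ~ 0 fall back
# to the matrix exponential.
.pi_entry <- function(g12, g13, g21, g23, from, to, dt) {
  n <- max(length(g12), length(g13), length(g21), length(g23),
           length(from), length(to), length(dt))
  g12 <- rep_len(g12, n); g13 <- rep_len(g13, n)
  g21 <- rep_len(g21, n); g23 <- rep_len(g23, n)
  from <- rep_len(from, n); to <- rep_len(to, n); dt <- rep_len(dt, n)
  l1 <- g12 + g13
  l2 <- g21 + g23
  h <- sqrt((l1 - l2)^2 + 4 * g12 * g21)
  out <- numeric(n)
  deg <- h < 1e-10 & from != 3L
  ok <- !deg
  if (any(ok)) {
    e1 <- exp(-0.5 * (l1 + l2 - h) * dt)
    e2 <- exp(-0.5 * (l1 + l2 + h) * dt)
    p11 <- ((-l1 + l2 + h) * e1 + (l1 - l2 + h) * e2) / (2 * h)
    p12 <- g12 * (e1 - e2) / h
    p21 <- g21 * (e1 - e2) / h
    p22 <- ((l1 - l2 + h) * e1 + (-l1 + l2 + h) * e2) / (2 * h)
    v <- ifelse(from == 1L,
                ifelse(to == 1L, p11, ifelse(to == 2L, p12, 1 - p11 - p12)),
         ifelse(from == 2L,
                ifelse(to == 1L, p21, ifelse(to == 2L, p22, 1 - p21 - p22)),
                as.numeric(to == 3L)))
    out[ok] <- v[ok]
  }
  if (any(deg)) {
    for (i in which(deg)) {
      P <- transition_probs(transition_rates3(g12[i], g13[i], g21[i], g23[i]),
                            dt[i], method = "expm")
      out[i] <- P[from[i], to[i]]
    }
  }
  pmin(pmax(out, 0), 1)
}
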