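#' IKr Markov-chain transition rates
#'
#' Generator matrix of the seven-state IKr channel model at a fixed voltage
#' and drug concentration.  The drug-free wing is a closed/open x
#' non-inactivated/inactivated ladder (states \code{c}, \code{o}, \code{i},
#' \code{ci}) whose open occupancy reproduces the base model's
#' Hodgkin-Huxley IKr gating: activation moves horizontally with the
#' steady-state/time-constant pair of the base formulation, and
#' rectification-type inactivation is a fast vertical process.  Drug at
#' concentration D binds the open and inactivated conformations only, at
#' rate \eqn{K_b = K_{max} K_u D^n / (D^n + halfmax)} (use-dependent
#' block).  Bound channels keep gating: \code{ob} deactivates into the
#' closed-bound state \code{cb} with the activation rates and
#' inactivates/recovers against \code{ib} with the rectification rates.
#' Unbinding occurs at \eqn{K_u} from \code{ob}/\code{ib}; escape from
#' \code{cb} is additionally voltage gated with midpoint \code{Vhalf}, so
#' drugs with a depolarized \code{Vhalf} are trapped in the closed channel
#' at diastolic potentials.
#'
#' @param V membrane voltage (mV).
#' @param drug_conc drug concentration (nM); 0 gives the drug-free gating
#'   matrix (all binding columns/rows zero).
#' @param binding [ikr_binding_params()] (may be \code{NULL} when
#'   \code{drug_conc == 0}).
#' @return A 7x7 generator matrix \code{Q} with rows/columns named
#'   \code{c, o, i, ci, ob, ib, cb}; \code{Q[j, k]} is the rate from state
#'   \code{k} into state \code{j}, diagonal entries make every column sum
#'   to zero, so \code{d occupancy/dt = Q \%*\% occupancy}.
#' @export
markov_transition_rates <- function(V, drug_conc = 0, binding = NULL) {
  if (drug_conc < 0) stop("drug_conc must be >= 0", call. = FALSE)
  if (drug_conc > 0 && is.null(binding))
    stop("drug_conc > 0 requires binding parameters", call. = FALSE)

  xrss <- 1 / (1 + exp(-(V + 8.337) / 6.789))
  txrf <- 12.98 + 1 / (0.3652 * exp((V - 31.66) / 3.869) +
                         4.123e-5 * exp(-(V - 47.78) / 20.38))
  txrs <- 1.865 + 1 / (0.06629 * exp((V - 34.70) / 7.355) +
                         1.128e-5 * exp(-(V - 29.74) / 25.94))
  Axrf <- 1 / (1 + exp((V + 54.81) / 38.21))
  txr <- Axrf * txrf + (1 - Axrf) * txrs
  act_a <- xrss / txr          # closed -> open
  act_b <- (1 - xrss) / txr    # open -> closed
  rkr <- 1 / ((1 + exp((V + 55) / 75)) * (1 + exp((V - 10) / 30)))
  tauI <- 2.0
  inact_f <- (1 - rkr) / tauI  # -> inactivated
  inact_b <- rkr / tauI        # -> conducting

  Kb <- 0
  Ku <- 0
  if (drug_conc > 0) {
    binding <- ikr_binding_params(binding)
    Dn <- drug_conc^binding$n
    Kb <- binding$Kmax * binding$Ku * Dn / (Dn + binding$halfmax)
    Ku <- binding$Ku
  } else if (!is.null(binding)) {
    binding <- ikr_binding_params(binding)
    Ku <- binding$Ku
  }
  Vh <- if (is.null(binding)) 0 else binding$Vhalf
  untrap <- Ku / (1 + exp(-(V - Vh) / 6.789))

  st <- c("c", "o", "i", "ci", "ob", "ib", "cb")
  Q <- matrix(0, 7, 7, dimnames = list(st, st))
  # drug-free ladder
  Q["o", "c"] <- act_a;  Q["c", "o"] <- act_b
  Q["i", "o"] <- inact_f; Q["o", "i"] <- inact_b
  Q["ci", "c"] <- inact_f; Q["c", "ci"] <- inact_b
  Q["i", "ci"] <- act_a;  Q["ci", "i"] <- act_b
  # binding / unbinding
  Q["ob", "o"] <- Kb; Q["o", "ob"] <- Ku
  Q["ib", "i"] <- Kb; Q["i", "ib"] <- Ku
  # bound-wing gating and voltage-gated escape from the trapped state
  Q["cb", "ob"] <- act_b; Q["ob", "cb"] <- act_a
  Q["ib", "ob"] <- inact_f; Q["ob", "ib"] <- inact_b
  Q["c", "cb"] <- untrap
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  Q
}

#' IKr current from a Markov occupancy vector
#'
#' \eqn{I_{Kr} = 0.046 \, s_{IKr} \sqrt{[K]_o / 5.4} \; O \; (V - E_K)}
#' where O is the occupancy of the conducting (drug-free open) state.  Drug
#' binding reduces O but never alters the conductance scaler.
#'
#' @param markov named occupancy vector with elements
#'   \code{c, o, i, ci, ob, ib, cb} (order-free if named; otherwise taken
#'   in that order).
#' @param V membrane voltage (mV).
#' @param E_K potassium reversal potential (mV).
#' @param s_IKr IKr conductance scaler.
#' @param ko extracellular potassium (mM).
#' @param tol allowed deviation of the occupancy sum from 1.
#' @return Current in uA/uF (outward positive).
#' @export
ikr_current <- function(markov, V, E_K, s_IKr = 1, ko = 5.4, tol = 1e-6) {
  st <- c("c", "o", "i", "ci", "ob", "ib", "cb")
  if (!is.null(names(markov))) {
    if (!all(st %in% names(markov)))
      stop("occupancy vector must name states ", paste(st, collapse = ", "),
           call. = FALSE)
    markov <- markov[st]
  } else if (length(markov) != 7) {
    stop("occupancy vector must have 7 elements", call. = FALSE)
  }
  if (any(markov < -tol) || abs(sum(markov) - 1) > tol)
    stop("corrupt Markov state: occupancies must be >= 0 and sum to 1",
         call. = FALSE)
  o <- unname(markov[2])
  0.046 * s_IKr * sqrt(ko / 5.4) * o * (V - E_K)
}

#' Stationary occupancy of the IKr chain at fixed voltage
#'
#' Null-space solution of the generator matrix (the eigenvector of
#' eigenvalue 0, normalized to sum 1).  Serves as a linear-algebra oracle
#' for long-time voltage-clamp relaxation of the integrated chain.
#'
#' @inheritParams markov_transition_rates
#' @return Named occupancy vector summing to 1.
#' @export
markov_stationary <- function(V, drug_conc = 0, binding = NULL) {
  Q <- markov_transition_rates(V, drug_conc, binding)
  # replace one balance equation by the conservation constraint
  A <- rbind(Q[-1, ], rep(1, 7))
  b <- c(rep(0, 6), 1)
  x <- solve(A, b)
  stats::setNames(pmax(x, 0) / sum(pmax(x, 0)), colnames(Q))
}

#' Relax the IKr chain at clamped voltage
#'
#' Integrates only the seven Markov occupancies at a fixed voltage (and
#' fixed drug concentration) for \code{t_end} ms.  Used for voltage-clamp
#' style tests of binding/unbinding kinetics, e.g. diastolic-hold trapping.
#'
#' @param occupancy starting occupancy (named or 7-vector, see
#'   [ikr_current()]).
#' @param V clamp voltage (mV).
#' @param t_end duration (ms).
#' @param drug_conc drug concentration (nM).
#' @param binding [ikr_binding_params()] or \code{NULL}.
#' @return Occupancy vector after \code{t_end} ms.
#' @export
markov_relax <- function(occupancy, V, t_end, drug_conc = 0, binding = NULL) {
  Q <- markov_transition_rates(V, drug_conc, binding)
  st <- colnames(Q)
  y0 <- if (!is.null(names(occupancy))) occupancy[st] else
    stats::setNames(occupancy, st)
  rhs <- function(t, y, p) list(as.vector(Q %*% y))
  out <- deSolve::lsoda(y0, c(0, t_end), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  stats::setNames(out[nrow(out), -1], st)
}
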