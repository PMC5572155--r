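#' Pacing protocol
#'
#' Square current-pulse pacing: a stimulus of \code{amplitude} uA/uF lasting
#' \code{duration} ms is delivered at the start of each cycle.  Defaults are
#' the base model's protocol (-80 uA/uF for 0.5 ms).
#'
#' @param cl cycle length (ms); 1000, 2000 and 4000 ms are the typical
#'   settings.
#' @param n_beats number of beats to integrate.
#' @param amplitude stimulus amplitude (uA/uF), negative = depolarizing.
#' @param duration stimulus duration (ms), must be shorter than \code{cl}.
#' @return A list of class \code{"pacing_protocol"}.
#' @export
pacing_protocol <- function(cl = 1000, n_beats = 1000,
                            amplitude = -80, duration = 0.5) {
  if (cl <= duration) stop("cycle length must exceed stimulus duration",
                           call. = FALSE)
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  structure(list(cl = cl, n_beats = n_beats, amplitude = amplitude,
                 duration = duration),
            class = "pacing_protocol")
}

## default solver tolerances (stiff lsoda, as in the published protocol)
.default_rtol <- 1e-6
.default_atol <- 1e-6

## recording grid: 0.01-ms resolution through the upstroke window so that
## dV/dt_max is grid-stable, 1-ms resolution for the rest of the beat
.record_times <- function(cl, duration, fine_until = 20) {
  sort(unique(c(seq(0, fine_until, by = 0.01),
                seq(ceiling(fine_until), cl, by = 1), duration, cl)))
}

## integrate one beat: stimulus segment then free-running segment.
## `times` must contain 0 and cl; rows are returned at those times.
.integrate_beat <- function(state, params, cl, duration, amplitude, times,
                            rtol = .default_rtol, atol = .default_atol) {
  t_stim <- times[times <= duration]
  if (!length(t_stim) || t_stim[1] > 0) t_stim <- c(0, t_stim)
  if (t_stim[length(t_stim)] < duration) t_stim <- c(t_stim, duration)
  t_free <- times[times >= duration]
  if (t_free[1] > duration) t_free <- c(duration, t_free)

  on_pars <- .param_vector(params, istim = amplitude)
  off_pars <- .param_vector(params, istim = 0)
  out1 <- deSolve::lsoda(state, t_stim, func = "ord_derivs",
                         parms = on_pars, dllname = "cipaord",
                         initfunc = "ord_init", nout = 16,
                         outnames = .current_names,
                         rtol = rtol, atol = atol, maxsteps = 50000)
  s_mid <- out1[nrow(out1), 1 + seq_along(.state_names)]
  out2 <- deSolve::lsoda(s_mid, t_free, func = "ord_derivs",
                         parms = off_pars, dllname = "cipaord",
                         initfunc = "ord_init", nout = 16,
                         outnames = .current_names,
                         rtol = rtol, atol = atol, maxsteps = 500000)
  if (attr(out2, "istate")[1] < 0 || attr(out1, "istate")[1] < 0)
    stop("solver failure within beat", call. = FALSE)
  full <- rbind(out1[-nrow(out1), , drop = FALSE], out2)
  full[full[, "time"] %in% times, , drop = FALSE]
}

#' One recorded beat
#'
#' Integrates a single cycle from \code{state} and returns a beat record:
#' time grid (0 = stimulus onset), membrane voltage, intracellular calcium,
#' all reported ionic currents and the end-of-beat state.  Occupancy of the
#' IKr Markov chain is checked for conservation and renormalized (with a
#' warning) if numerical drift exceeds 1e-8.
#'
#' @param state starting state vector.
#' @param params an [ord_params()] object.
#' @param protocol a [pacing_protocol()]; only its cycle length and stimulus
#'   settings are used.
#' @param rtol,atol solver tolerances.
#' @return An object of class \code{"beat_record"}: a list with \code{time},
#'   \code{V}, \code{Cai}, \code{currents} (matrix with one column per
#'   reported current), \code{cl} and \code{end_state}.
#' @export
record_beat <- function(state, params, protocol = pacing_protocol(),
                        rtol = .default_rtol, atol = .default_atol) {
  times <- .record_times(protocol$cl, protocol$duration)
  out <- .integrate_beat(state, params, protocol$cl, protocol$duration,
                         protocol$amplitude, times, rtol, atol)
  ns <- length(.state_names)
  end_state <- out[nrow(out), 1 + seq_len(ns)]
  names(end_state) <- .state_names
  end_state <- .renormalize_markov(end_state)
  structure(list(
    time = out[, "time"],
    V = out[, "V"],
    Cai = out[, "cai"],
    currents = out[, .current_names, drop = FALSE],
    cl = protocol$cl,
    end_state = end_state), class = "beat_record")
}

## conservation guard for the 7 IKr Markov occupancies
.markov_idx <- 40:46
.renormalize_markov <- function(state, tol = 1e-8) {
  tot <- sum(state[.markov_idx])
  if (abs(tot - 1) > tol) {
    warning(sprintf("IKr Markov occupancy drift %.3g renormalized", tot - 1),
            call. = FALSE)
    state[.markov_idx] <- state[.markov_idx] / tot
  }
  state
}

#' Pace to steady state
#'
#' Integrates \code{protocol$n_beats} consecutive cycles and returns the
#' terminal state plus the final two beats recorded on the fine grid, for
#' alternans and afterdepolarization inspection.
#'
#' @inheritParams record_beat
#' @param protocol a [pacing_protocol()].
#' @return A list of class \code{"pacing_result"}: \code{state} (terminal
#'   state), \code{beats} (list of the last two [record_beat()] records,
#'   or one if \code{n_beats == 1}), \code{protocol}.
#' @export
pace_to_steady_state <- function(state, params, protocol,
                                 rtol = .default_rtol, atol = .default_atol) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  n <- protocol$n_beats
  n_fast <- max(0L, n - 2L)
  times <- c(0, protocol$cl)
  if (n_fast > 0) {
    for (b in seq_len(n_fast)) {
      out <- tryCatch(
        .integrate_beat(state, params, protocol$cl, protocol$duration,
                        protocol$amplitude, times, rtol, atol),
        error = function(e) stop(sprintf("solver failure at beat %d: %s",
                                         b, conditionMessage(e)),
                                 call. = FALSE))
      state <- out[nrow(out), 1 + seq_along(.state_names)]
      names(state) <- .state_names
      state <- .renormalize_markov(state)
    }
  }
  beats <- vector("list", min(2L, n))
  for (k in seq_along(beats)) {
    beats[[k]] <- record_beat(state, params, protocol, rtol, atol)
    state <- beats[[k]]$end_state
  }
  structure(list(state = state, beats = beats, protocol = protocol),
            class = "pacing_result")
}

#' Detect early afterdepolarizations in a beat
#'
#' An EAD is flagged when the voltage derivative becomes positive after the
#' action-potential peak, inside the configured window, sustained over at
#' least two consecutive grid points (guarding against solver-grid noise).
#' The \code{"plateau"} window restricts the search to the APD30-APD90
#' repolarization interval (the criterion used by the robustness assay);
#' \code{"repolarization"} searches from the peak to APD90.
#'
#' @param beat a [record_beat()] record.
#' @param window \code{"repolarization"} or \code{"plateau"}.
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when the beat contains no
#'   elicited action potential (peak voltage below 0 mV), which is distinct
#'   from "no EAD".
#' @export
detect_ead <- function(beat, window = c("plateau", "repolarization")) {
  window <- match.arg(window)
  stopifnot(inherits(beat, "beat_record"))
  v <- beat$V
  tt <- beat$time
  if (max(v) <= 0) return(NA)
  i_peak <- which.max(v)
  t_lo <- if (window == "plateau") apd(beat, 0.30) else tt[i_peak]
  t_hi <- apd(beat, 0.90)
  if (is.na(t_hi)) t_hi <- tt[length(tt)]
  if (is.na(t_lo)) t_lo <- tt[i_peak]
  upstroke <- .upstroke_time(beat)
  sel <- which(tt > upstroke + t_lo & tt <= upstroke + t_hi)
  sel <- sel[sel > i_peak]
  if (length(sel) < 3) return(FALSE)
  dv <- diff(v[sel]) / diff(tt[sel])
  pos <- dv > 0
  any(pos[-length(pos)] & pos[-1])
}

#' Detect APD alternans between two consecutive beats
#'
#' Beats alternate when their APD90 values differ by more than
#' \code{tolerance} (default 5 ms).
#'
#' @param beat_a,beat_b two consecutive [record_beat()] records at the same
#'   cycle length.
#' @param tolerance APD90 difference (ms) below which beats count as equal.
#' @return Logical.
#' @export
detect_alternans <- function(beat_a, beat_b, tolerance = 5) {
  stopifnot(inherits(beat_a, "beat_record"), inherits(beat_b, "beat_record"))
  if (beat_a$cl != beat_b$cl)
    stop("alternans check requires equal cycle lengths", call. = FALSE)
  a1 <- apd(beat_a, 0.9)
  a2 <- apd(beat_b, 0.9)
  if (is.na(a1) || is.na(a2)) return(TRUE)   # failed repolarization alternates
  abs(a1 - a2) > tolerance
}
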