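## time of maximal upstroke velocity (reference point for APD measurement)
.upstroke_time <- function(beat) {
  dv <- diff(beat$V) / diff(beat$time)
  beat$time[which.max(dv)]
}

#' Action potential duration
#'
#' Time from the maximal-upstroke-velocity point to the downward crossing of
#' \code{peak - fraction * amplitude}, where amplitude = peak voltage minus
#' resting voltage; the crossing is located by linear interpolation between
#' grid points.
#'
#' @param beat a [record_beat()] record.
#' @param fraction repolarization fraction, e.g. 0.9 for APD90.
#' @return Duration in ms, or \code{NA} if the beat never repolarizes to the
#'   threshold level within the cycle.
#' @export
apd <- function(beat, fraction = 0.9) {
  stopifnot(inherits(beat, "beat_record"), fraction > 0, fraction < 1)
  v <- beat$V
  tt <- beat$time
  v_rest <- v[1]
  i_peak <- which.max(v)
  v_peak <- v[i_peak]
  if (v_peak <= 0) return(NA_real_)
  level <- v_peak - fraction * (v_peak - v_rest)
  t0 <- .upstroke_time(beat)
  below <- which(v < level & tt > tt[i_peak])
  if (!length(below)) return(NA_real_)
  k <- below[1]
  # linear interpolation on the segment that crosses the level
  t_cross <- tt[k - 1] + (level - v[k - 1]) * (tt[k] - tt[k - 1]) /
    (v[k] - v[k - 1])
  t_cross - t0
}

## duration measured on the calcium transient, analogous to apd()
.cad <- function(beat, fraction) {
  ca <- beat$Cai
  tt <- beat$time
  ca_rest <- ca[1]
  i_peak <- which.max(ca)
  ca_peak <- ca[i_peak]
  if (ca_peak <= ca_rest) return(NA_real_)
  level <- ca_peak - fraction * (ca_peak - ca_rest)
  i_up <- which(ca > ca_rest + 0.1 * (ca_peak - ca_rest))[1]
  below <- which(ca < level & tt > tt[i_peak])
  if (!length(below) || is.na(i_up)) return(NA_real_)
  k <- below[1]
  t_cross <- tt[k - 1] + (level - ca[k - 1]) * (tt[k] - tt[k - 1]) /
    (ca[k] - ca[k - 1])
  t_cross - tt[i_up]
}

#' Net repolarizing current
#'
#' Pointwise sum of the six plateau currents
#' \eqn{I_{net} = I_{CaL} + I_{NaL} + I_{Kr} + I_{Ks} + I_{K1} + I_{to}}
#' (outward positive; the stimulus current is excluded).
#'
#' @param beat a [record_beat()] record.
#' @return Numeric vector, one value per grid point (uA/uF).
#' @export
net_current <- function(beat) {
  stopifnot(inherits(beat, "beat_record"))
  cur <- beat$currents
  cur[, "ICaL"] + cur[, "INaL"] + cur[, "IKr"] + cur[, "IKs"] +
    cur[, "IK1"] + cur[, "Ito"]
}

## trapezoidal integral of a trace over the beat, in uC/uF
.charge <- function(tt, x) {
  sum(diff(tt) * (x[-1] + x[-length(x)]) / 2) / 1000
}

#' Net charge over one beat (qNet)
#'
#' Trapezoidal integral of the net current from the beginning to the end of
#' the beat, reported in uC/uF.
#'
#' @param beat a [record_beat()] record.
#' @return qNet in uC/uF.
#' @export
qnet <- function(beat) {
  .charge(beat$time, net_current(beat))
}

#' Charge carried by a single current over one beat
#'
#' @param beat a [record_beat()] record.
#' @param current one of the reported current names, e.g. \code{"IKr"} or
#'   \code{"INaL"}.
#' @return Charge in uC/uF (signed; inward currents give negative values).
#' @export
per_current_charge <- function(beat, current) {
  stopifnot(inherits(beat, "beat_record"),
            current %in% colnames(beat$currents))
  .charge(beat$time, beat$currents[, current])
}

#' Normalized change in inward charge (cqInward)
#'
#' Drug-induced change in the charge carried by the two inward plateau
#' currents, each normalized to its drug-free value and averaged:
#' \deqn{cqInward = \frac{1}{2}\left(\frac{qNaL_{drug}}{qNaL_{ctrl}} +
#'   \frac{qCaL_{drug}}{qCaL_{ctrl}}\right)}
#' Values above 1 indicate a net increase of inward charge under drug.
#'
#' @param beat drugged steady-state beat.
#' @param control_beat drug-free steady-state beat at the same cycle length.
#' @return Dimensionless ratio (1 when drug equals control).
#' @export
cq_inward <- function(beat, control_beat) {
  if (beat$cl != control_beat$cl)
    stop("beats must share the cycle length", call. = FALSE)
  0.5 * (per_current_charge(beat, "INaL") /
           per_current_charge(control_beat, "INaL") +
         per_current_charge(beat, "ICaL") /
           per_current_charge(control_beat, "ICaL"))
}

#' Full metric panel for one steady-state beat
#'
#' Computes every candidate proarrhythmia metric from a steady-state beat:
#' voltage morphology (resting Vm, dV/dt max, peak Vm, APD50, APD90,
#' triangulation), calcium-transient morphology (diastolic and peak calcium,
#' CaD50, CaD90, triangulation), per-current charges, qNet and cqInward.
#' When the beat carries an EAD (or alternates against \code{prev_beat}) the
#' panel is marked invalid; downstream classification uses the last valid
#' dose instead.
#'
#' @param beat steady-state [record_beat()] record.
#' @param control_beat drug-free beat at the same cycle length (for
#'   cqInward); pass the beat itself for control conditions.
#' @param prev_beat optional preceding beat for the alternans check.
#' @return A one-row \code{data.frame} with class \code{"metric_panel"}.
#' @export
metric_panel <- function(beat, control_beat = beat, prev_beat = NULL) {
  stopifnot(inherits(beat, "beat_record"))
  dv <- diff(beat$V) / diff(beat$time)
  apd50 <- apd(beat, 0.5)
  apd90 <- apd(beat, 0.9)
  ead <- detect_ead(beat, "repolarization")
  alt <- if (!is.null(prev_beat)) detect_alternans(prev_beat, beat) else FALSE
  valid <- !is.na(apd90) && !isTRUE(ead) && !alt && !is.na(ead)
  out <- data.frame(
    resting_Vm = beat$V[1],
    dVdt_max = max(dv),
    peak_Vm = max(beat$V),
    APD50 = apd50,
    APD90 = apd90,
    APDtri = apd90 - apd50,
    diastolic_Ca = min(beat$Cai),
    peak_Ca = max(beat$Cai),
    CaD50 = .cad(beat, 0.5),
    CaD90 = .cad(beat, 0.9),
    Catri = .cad(beat, 0.9) - .cad(beat, 0.5),
    qNet = qnet(beat),
    qKr = per_current_charge(beat, "IKr"),
    qNaL = per_current_charge(beat, "INaL"),
    qCaL = per_current_charge(beat, "ICaL"),
    qKs = per_current_charge(beat, "IKs"),
    qK1 = per_current_charge(beat, "IK1"),
    qto = per_current_charge(beat, "Ito"),
    cqInward = cq_inward(beat, control_beat),
    ead = isTRUE(ead),
    alternans = alt,
    valid = valid)
  class(out) <- c("metric_panel", "data.frame")
  out
}
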