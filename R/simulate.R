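#' Control steady state at a given cycle length
#'
#' Returns the drug-free optimized model's paced steady state.  For the
#' three standard cycle lengths the package ships a precomputed 1000-beat
#' terminal state (regenerable with \code{tools/make_steady_fixtures.R});
#' by default that snapshot is topped up with \code{n_topup} fresh beats.
#' For non-standard cycle lengths or parameter sets, pass
#' \code{use_snapshot = FALSE} and a full \code{n_beats}.
#'
#' @param cl cycle length (ms).
#' @param params an [ord_params()] object; the snapshot is only used for the
#'   default optimized control parameters.
#' @param n_beats beats to pace when not using the snapshot.
#' @param n_topup beats paced on top of the snapshot.
#' @param use_snapshot load the bundled precomputed state when available.
#' @return A [pace_to_steady_state()] result.
#' @export
control_steady_state <- function(cl = 2000, params = ord_params(),
                                 n_beats = 1000, n_topup = 2,
                                 use_snapshot = TRUE) {
  is_default <- identical(unclass(params$scaling),
                          unclass(scaling_optimized())) &&
    all(params$block == 0) && params$drug_conc == 0 &&
    params$ikr_reduction == 0
  snap <- system.file("extdata",
                      sprintf("steady_state_cl%d.csv", as.integer(cl)),
                      package = "cipaord")
  if (use_snapshot && is_default && nzchar(snap)) {
    df <- utils::read.csv(snap, stringsAsFactors = FALSE)
    state <- stats::setNames(as.numeric(df$value), df$state)[.state_names]
    pace_to_steady_state(state, params,
                         pacing_protocol(cl = cl,
                                         n_beats = max(2L, n_topup)))
  } else {
    pace_to_steady_state(ord_initial_state(), params,
                         pacing_protocol(cl = cl, n_beats = n_beats))
  }
}

#' Simulate one drug condition and compute its metric panel
#'
#' Paces the drugged model for \code{n_beats} starting from the drug-free
#' steady state (new steady-state distributions of the bound channel are
#' reached under pacing), then evaluates the full metric panel on the final
#' beat, using the control beat at the same cycle length for the cqInward
#' normalization.
#'
#' @param drug a [drug_profile()].
#' @param conc_multiple dose as a multiple of the drug's Cmax.
#' @param cl cycle length (ms).
#' @param control a [control_steady_state()] result at the same cycle
#'   length (computed if \code{NULL}).
#' @param n_beats drugged beats to pace.
#' @param params baseline parameters (optimized control model by default).
#' @param static_ikr use the static pore-block IKr variant instead of
#'   dynamic binding.
#' @return A [metric_panel()] one-row data frame, with the drug name, dose
#'   and cycle length prepended as columns.
#' @export
simulate_drug_condition <- function(drug, conc_multiple, cl = 2000,
                                    control = NULL, n_beats = 1000,
                                    params = ord_params(),
                                    static_ikr = FALSE) {
  stopifnot(inherits(drug, "drug_profile"))
  if (is.null(control)) control <- control_steady_state(cl, params)
  drugged <- if (static_ikr)
    apply_drug_static_ikr(params, drug, conc_multiple)
  else apply_drug(params, drug, conc_multiple)
  res <- pace_to_steady_state(control$state, drugged,
                              pacing_protocol(cl = cl, n_beats = n_beats))
  ctrl_beat <- control$beats[[length(control$beats)]]
  nb <- length(res$beats)
  panel <- metric_panel(res$beats[[nb]], control_beat = ctrl_beat,
                        prev_beat = if (nb > 1) res$beats[[nb - 1]])
  cbind(data.frame(drug = drug$name, conc_multiple = conc_multiple,
                   cl = cl, stringsAsFactors = FALSE), panel)
}

#' Dose grid of the torsade metric analysis
#'
#' The standard concentration multiples (times Cmax) at which each drug is
#' evaluated.
#'
#' @return Numeric vector.
#' @export
standard_dose_grid <- function() c(0.5, 1, 2, 3, 4, 5, 7.5, 10, 15, 20, 25)

#' Metric panels across drugs and doses
#'
#' Runs [simulate_drug_condition()] for each (drug, dose) pair and binds the
#' panels into a long table; a control row (\code{conc_multiple = 0}) is
#' included once.  For doses where the beat carries an EAD or alternans the
#' row is retained but flagged \code{valid = FALSE}; downstream consumers
#' substitute the highest valid lower dose.
#'
#' @param drugs named list of [drug_profile()]s.
#' @param doses concentration multiples.
#' @param cl cycle length (ms).
#' @param n_beats drugged beats per condition.
#' @param params baseline parameters.
#' @param static_ikr use the static pore-block IKr variant.
#' @param quiet suppress progress messages.
#' @return \code{data.frame}, one row per condition.
#' @export
metric_panel_table <- function(drugs, doses = standard_dose_grid(),
                               cl = 2000, n_beats = 1000,
                               params = ord_params(), static_ikr = FALSE,
                               quiet = TRUE) {
  control <- control_steady_state(cl, params)
  ctrl_beat <- control$beats[[length(control$beats)]]
  ctrl_row <- cbind(data.frame(drug = "control", conc_multiple = 0, cl = cl,
                               stringsAsFactors = FALSE),
                    metric_panel(ctrl_beat, ctrl_beat,
                                 prev_beat = control$beats[[1]]))
  rows <- list(ctrl_row)
  for (dn in names(drugs)) {
    for (dose in doses) {
      if (!quiet) message(dn, " @ ", dose, "x")
      rows[[length(rows) + 1]] <-
        simulate_drug_condition(drugs[[dn]], dose, cl = cl,
                                control = control, n_beats = n_beats,
                                params = params, static_ikr = static_ikr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Substitute invalid doses by the last valid lower dose
#'
#' Conditions whose steady-state beat shows an EAD, alternans or failed
#' repolarization carry no meaningful metric value; following the analysis
#' convention, each such row's metric columns are replaced by those of the
#' same drug's highest valid lower dose (or the control row when no lower
#' dose is valid).
#'
#' @param panel_table output of [metric_panel_table()].
#' @return The table with invalid rows substituted; a column
#'   \code{substituted} marks them.
#' @export
substitute_invalid_doses <- function(panel_table) {
  metric_cols <- setdiff(names(panel_table),
                         c("drug", "conc_multiple", "cl", "ead",
                           "alternans", "valid"))
  out <- panel_table
  out$substituted <- FALSE
  ctrl <- panel_table[panel_table$conc_multiple == 0, ][1, ]
  for (dn in unique(out$drug)) {
    idx <- which(out$drug == dn)
    idx <- idx[order(out$conc_multiple[idx])]
    last_valid <- ctrl
    for (i in idx) {
      if (isTRUE(out$valid[i])) {
        last_valid <- out[i, ]
      } else {
        out[i, metric_cols] <- last_valid[, metric_cols]
        out$substituted[i] <- TRUE
      }
    }
  }
  out
}
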