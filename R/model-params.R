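#' Conductance scaling factors
#'
#' Dimensionless multipliers applied to the maximal conductances or
#' permeabilities of the five plateau currents that were recalibrated when
#' the dynamic-IKr myocyte model was fitted to action-potential-duration
#' rate-dependence data: IKr, IKs, IK1, ICaL and INaL.  All other model
#' parameters keep their base values.
#'
#' @param IKr,IKs,IK1,ICaL,INaL positive multipliers (1 = base model value).
#' @return An object of class \code{"conductance_scaling"}: a named numeric
#'   vector with elements \code{IKr}, \code{IKs}, \code{IK1}, \code{ICaL},
#'   \code{INaL}.
#' @seealso [scaling_optimized()], [scaling_original()],
#'   [apply_conductance_scaling()]
#' @export
conductance_scaling <- function(IKr = 1, IKs = 1, IK1 = 1, ICaL = 1, INaL = 1) {
  s <- c(IKr = IKr, IKs = IKs, IK1 = IK1, ICaL = ICaL, INaL = INaL)
  if (!is.numeric(s) || anyNA(s) || any(s <= 0))
    stop("conductance scalers must be positive numbers", call. = FALSE)
  structure(s, class = "conductance_scaling")
}

#' Published scaling-factor sets
#'
#' `scaling_optimized()` returns the conductance multipliers of the optimized
#' dynamic-IKr model (IKr 1.013, IKs 1.870, IK1 1.698, ICaL 1.007,
#' INaL 2.661); `scaling_original()` the multipliers of the unoptimized
#' dynamic-IKr model (IKr 0.9, all others 1).
#'
#' @return A [conductance_scaling()] object.
#' @export
scaling_optimized <- function() {
  conductance_scaling(IKr = 1.013, IKs = 1.870, IK1 = 1.698,
                      ICaL = 1.007, INaL = 2.661)
}

#' @rdname scaling_optimized
#' @export
scaling_original <- function() {
  conductance_scaling(IKr = 0.9)
}

#' Model parameter set
#'
#' Bundles everything the myocyte right-hand side needs beyond its hard-wired
#' base constants: the five conductance scalers, per-channel Hill block
#' multipliers for the six pore-block channels, the drug concentration seen
#' by the IKr binding scheme with its kinetic parameters, and an extra
#' multiplicative IKr conductance reduction used by the robustness assay.
#'
#' @param scaling a [conductance_scaling()] object.
#' @param block named numeric vector of fractional conductance block in
#'   \[0, 1) for any of \code{INa}, \code{INaL}, \code{ICaL}, \code{IK1},
#'   \code{IKs}, \code{Ito}.  Channels not named are unblocked.
#' @param drug_conc drug concentration (nM) driving IKr binding.
#' @param binding a list with elements \code{Kmax}, \code{Ku}, \code{n},
#'   \code{halfmax}, \code{Vhalf} (see [ikr_binding_params()]), or
#'   \code{NULL} for no IKr binding.
#' @param ikr_reduction fractional reduction of maximal IKr conductance in
#'   \[0, 1), applied multiplicatively on top of \code{scaling["IKr"]}
#'   (the pro-EAD perturbation; drug binding never changes the conductance).
#' @return An object of class \code{"ord_params"}.
#' @export
ord_params <- function(scaling = scaling_optimized(),
                       block = NULL,
                       drug_conc = 0,
                       binding = NULL,
                       ikr_reduction = 0) {
  if (!inherits(scaling, "conductance_scaling"))
    scaling <- do.call(conductance_scaling, as.list(scaling))
  blk <- c(INa = 0, INaL = 0, ICaL = 0, IK1 = 0, IKs = 0, Ito = 0)
  if (length(block)) {
    if (is.null(names(block)) || !all(names(block) %in% names(blk)))
      stop("block must be named with channels among: ",
           paste(names(blk), collapse = ", "), call. = FALSE)
    if (any(block < 0 | block >= 1))
      stop("block fractions must lie in [0, 1)", call. = FALSE)
    blk[names(block)] <- block
  }
  if (drug_conc < 0) stop("drug_conc must be >= 0", call. = FALSE)
  if (drug_conc > 0 && is.null(binding))
    stop("drug_conc > 0 requires IKr binding parameters", call. = FALSE)
  if (!is.null(binding)) binding <- ikr_binding_params(binding)
  if (ikr_reduction < 0 || ikr_reduction >= 1)
    stop("ikr_reduction must lie in [0, 1)", call. = FALSE)
  structure(list(scaling = scaling, block = blk, drug_conc = drug_conc,
                 binding = binding, ikr_reduction = ikr_reduction),
            class = "ord_params")
}

#' IKr binding kinetic parameters
#'
#' Per-drug parameters of the state-dependent IKr binding scheme:
#' \code{Kmax} (dimensionless maximal bound/free ratio), \code{Ku}
#' (unbinding rate, 1/ms), \code{n} (concentration-dependence exponent),
#' \code{halfmax} (half-maximal binding concentration term, nM^n) and
#' \code{Vhalf} (mV, midpoint of the voltage-dependent escape from the
#' trapped closed-bound state).  The binding rate at concentration D (nM) is
#' \code{Kmax * Ku * D^n / (D^n + halfmax)}.
#'
#' @param x a list or named vector with the five elements above.
#' @return A validated list of class \code{"ikr_binding_params"}.
#' @export
ikr_binding_params <- function(x) {
  if (inherits(x, "ikr_binding_params")) return(x)
  x <- as.list(x)
  need <- c("Kmax", "Ku", "n", "halfmax", "Vhalf")
  if (!all(need %in% names(x)))
    stop("binding parameters need elements: ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- lapply(x[need], as.numeric)
  if (x$Kmax < 0 || x$Ku < 0) stop("binding rates must be >= 0", call. = FALSE)
  if (x$halfmax <= 0) stop("halfmax must be > 0", call. = FALSE)
  if (x$n <= 0) stop("Hill-type exponent n must be > 0", call. = FALSE)
  structure(x, class = "ikr_binding_params")
}

#' Rescale the five calibrated conductances of a parameter set
#'
#' Multiplies the current scaling factors by \code{scaling}; scaling is
#' multiplicative, so applying \{INaL: 2\} then \{INaL: 1.3305\} equals
#' applying \{INaL: 2.661\} once.
#'
#' @param params an [ord_params()] object.
#' @param scaling a [conductance_scaling()] object.
#' @return The modified \code{ord_params} object.
#' @export
apply_conductance_scaling <- function(params, scaling) {
  stopifnot(inherits(params, "ord_params"))
  if (!inherits(scaling, "conductance_scaling"))
    scaling <- do.call(conductance_scaling, as.list(scaling))
  params$scaling <- conductance_scaling(
    IKr  = params$scaling[["IKr"]]  * scaling[["IKr"]],
    IKs  = params$scaling[["IKs"]]  * scaling[["IKs"]],
    IK1  = params$scaling[["IK1"]]  * scaling[["IK1"]],
    ICaL = params$scaling[["ICaL"]] * scaling[["ICaL"]],
    INaL = params$scaling[["INaL"]] * scaling[["INaL"]])
  params
}

## names of the 46 state variables, in solver order
.state_names <- c(
  "V", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
  "kr_c", "kr_o", "kr_i", "kr_ci", "kr_ob", "kr_ib", "kr_cb")

.current_names <- c("INa", "INaL", "Ito", "ICaL", "IKr", "IKs", "IK1",
                    "ICaNa", "ICaK", "INaCa_i", "INaCa_ss", "INaK",
                    "INab", "ICab", "IpCa", "IKb")

#' Resting initial state
#'
#' The base model's resting state (endocardial variant), with the IKr Markov
#' occupancies initialised at their drug-free resting distribution.  The
#' operative steady state is defined by pacing, not by these values; any
#' state in the resting basin converges to the same paced limit cycle.
#'
#' @return Named numeric vector of the 46 state variables.
#' @export
ord_initial_state <- function() {
  y <- c(
    V = -87.5, nai = 7.268, nass = 7.268, ki = 144.65, kss = 144.65,
    cai = 8.6e-5, cass = 8.49e-5, cansr = 1.61, cajsr = 1.56,
    m = 0.00744, hf = 0.695, hs = 0.695, j = 0.695, hsp = 0.449, jp = 0.695,
    mL = 0.000194, hL = 0.496, hLp = 0.266,
    a = 0.00101, iF = 0.9996, iS = 0.5896, ap = 0.000516,
    iFp = 0.9996, iSp = 0.6419,
    d = 2.43e-9, ff = 1, fs = 0.911, fcaf = 1, fcas = 0.9998,
    jca = 0.99997, nca = 0.00267, ffp = 1, fcafp = 1,
    xs1 = 0.2707, xs2 = 0.000193, xk1 = 0.9968,
    Jrelnp = 2.5e-5, Jrelp = 3.12e-7, CaMKt = 0.0124,
    kr_c = 0.586, kr_o = 0, kr_i = 0, kr_ci = 0.414,
    kr_ob = 0, kr_ib = 0, kr_cb = 0)
  names(y) <- .state_names
  y
}

## flatten an ord_params object into the 18-element vector the C code reads
.param_vector <- function(params, istim = 0) {
  stopifnot(inherits(params, "ord_params"))
  s <- params$scaling
  b <- params$block
  bind <- params$binding
  if (is.null(bind))
    bind <- list(Kmax = 0, Ku = 1e-3, n = 1, halfmax = 1, Vhalf = 0)
  c(s[["IKr"]] * (1 - params$ikr_reduction),
    s[["IKs"]], s[["IK1"]], s[["ICaL"]], s[["INaL"]],
    1 - b[["INa"]], 1 - b[["INaL"]], 1 - b[["ICaL"]],
    1 - b[["IK1"]], 1 - b[["IKs"]], 1 - b[["Ito"]],
    params$drug_conc,
    bind$Kmax, bind$Ku, bind$n, bind$halfmax, bind$Vhalf,
    istim)
}

#' Evaluate the model right-hand side once
#'
#' Computes the time-derivative of every state variable together with the
#' individual ionic currents at a given state, without integrating.  Used
#' for diagnostics and for derivative-level testing.
#'
#' @param state named state vector as returned by [ord_initial_state()].
#' @param params an [ord_params()] object.
#' @param stim stimulus current (uA/uF), 0 when the stimulus is off.
#' @return A list with \code{derivatives} (named vector) and
#'   \code{currents} (named vector, uA/uF, outward positive).
#' @export
ord_derivatives <- function(state, params, stim = 0) {
  stopifnot(length(state) == length(.state_names))
  out <- .C("ord_rhs_call",
            t = as.double(0),
            y = as.double(state),
            pars = as.double(.param_vector(params, istim = stim)),
            ydot = double(length(.state_names)),
            currents = double(length(.current_names)),
            PACKAGE = "cipaord")
  d <- out$ydot
  names(d) <- .state_names
  cur <- out$currents
  names(cur) <- .current_names
  if (any(!is.finite(d))) {
    bad <- .state_names[!is.finite(d)]
    stop("non-finite derivative for state component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(derivatives = d, currents = cur)
}

#' Write and read flat parameter files
#'
#' Key/value text representation of an [ord_params()] object for
#' checkpointing runs.
#'
#' @param params an [ord_params()] object.
#' @param path file path.
#' @return \code{read_ord_params} returns an \code{ord_params} object;
#'   \code{write_ord_params} returns \code{path} invisibly.
#' @export
write_ord_params <- function(params, path) {
  stopifnot(inherits(params, "ord_params"))
  v <- c(stats::setNames(as.numeric(params$scaling),
                         paste0("scale_", names(params$scaling))),
         stats::setNames(params$block, paste0("block_", names(params$block))),
         drug_conc = params$drug_conc,
         ikr_reduction = params$ikr_reduction)
  if (!is.null(params$binding))
    v <- c(v, stats::setNames(unlist(params$binding),
                              paste0("bind_", names(params$binding))))
  writeLines(sprintf("%s\t%.17g", names(v), v), path)
  invisible(path)
}

#' @rdname write_ord_params
#' @export
read_ord_params <- function(path) {
  kv <- utils::read.table(path, sep = "\t", col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  val <- stats::setNames(kv$value, kv$key)
  pick <- function(prefix) {
    k <- grep(paste0("^", prefix), names(val), value = TRUE)
    stats::setNames(val[k], sub(paste0("^", prefix), "", k))
  }
  binding <- NULL
  if (any(grepl("^bind_", names(val)))) binding <- as.list(pick("bind_"))
  ord_params(scaling = do.call(conductance_scaling, as.list(pick("scale_"))),
             block = pick("block_")[c("INa", "INaL", "ICaL", "IK1", "IKs", "Ito")],
             drug_conc = unname(val[["drug_conc"]]),
             binding = binding,
             ikr_reduction = unname(val[["ikr_reduction"]]))
}
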