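#' Fractional block from the Hill equation
#'
#' Simple pore-block model used for the six non-IKr channels:
#' \eqn{b = 1 / (1 + (IC50 / D)^h)}.  The fraction is 0 at zero
#' concentration, 0.5 at \code{conc == ic50} for any Hill coefficient, and
#' approaches (but never reaches) 1 for finite concentrations.
#'
#' @param conc drug concentration (nM), \code{>= 0}.
#' @param ic50 half-maximal blocking concentration (nM), \code{> 0}.
#' @param h Hill coefficient, \code{> 0}.
#' @return Block fraction in \[0, 1).
#' @export
hill_block_fraction <- function(conc, ic50, h = 1) {
  if (any(ic50 <= 0) || any(h <= 0))
    stop("ic50 and Hill coefficient must be > 0", call. = FALSE)
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  ifelse(conc == 0, 0, 1 / (1 + (ic50 / conc)^h))
}

#' Safety margin
#'
#' Ratio of a drug's IKr half-block concentration to its free therapeutic
#' plasma concentration, \code{ic50 / cmax}.
#'
#' @param ic50_ikr IKr IC50 (nM), \code{> 0}.
#' @param cmax free Cmax (nM), \code{> 0}.
#' @return Dimensionless ratio.
#' @export
safety_margin <- function(ic50_ikr, cmax) {
  if (any(ic50_ikr <= 0) || any(cmax <= 0))
    stop("ic50 and cmax must be > 0", call. = FALSE)
  ic50_ikr / cmax
}

#' Drug profile
#'
#' One drug's multichannel pharmacology: free Cmax, per-channel Hill
#' parameters for the six pore-block channels, IKr binding kinetics and the
#' known torsade risk category (1 low, 2 intermediate, 3 high).  Channels
#' without an entry are treated as showing no measurable block.
#'
#' @param name drug name.
#' @param cmax free maximal therapeutic plasma concentration (nM).
#' @param hill \code{data.frame} with columns \code{channel} (among INa,
#'   INaL, ICaL, IK1, IKs, Ito), \code{ic50_nM}, \code{hill}; may be empty.
#' @param binding [ikr_binding_params()] or \code{NULL} for no IKr binding.
#' @param risk_category 1, 2, 3 or \code{NA}.
#' @param ikr_ic50_nM optional IKr IC50 (nM) used by the static pore-block
#'   model variant and by [safety_margin()].
#' @return An object of class \code{"drug_profile"}.
#' @export
drug_profile <- function(name, cmax, hill = NULL, binding = NULL,
                         risk_category = NA, ikr_ic50_nM = NA) {
  if (cmax <= 0) stop("cmax must be > 0", call. = FALSE)
  chans <- c("INa", "INaL", "ICaL", "IK1", "IKs", "Ito")
  if (is.null(hill)) {
    hill <- data.frame(channel = character(), ic50_nM = numeric(),
                       hill = numeric())
  } else {
    if (!all(hill$channel %in% chans))
      stop("unknown channel in Hill table: ",
           paste(setdiff(hill$channel, chans), collapse = ", "),
           call. = FALSE)
    if (any(hill$ic50_nM <= 0) || any(hill$hill <= 0))
      stop("Hill table needs positive ic50 and coefficient", call. = FALSE)
  }
  if (!is.null(binding)) binding <- ikr_binding_params(binding)
  if (!is.na(risk_category) && !risk_category %in% 1:3)
    stop("risk_category must be 1, 2 or 3", call. = FALSE)
  structure(list(name = name, cmax = cmax, hill = hill, binding = binding,
                 risk_category = risk_category, ikr_ic50_nM = ikr_ic50_nM),
            class = "drug_profile")
}

#' Apply a drug to a model parameter set
#'
#' Builds drugged model parameters at \code{conc_multiple} times the drug's
#' free Cmax: each Hill channel's maximal conductance is multiplied by
#' \code{1 - block fraction} at that concentration, and the IKr binding
#' scheme is driven by the same concentration.  The IKr conductance itself
#' is never changed by the drug.  The construction is stateless: applying at
#' dose d always equals building fresh parameters at dose d.
#'
#' @param params baseline [ord_params()] (typically the optimized control
#'   model).
#' @param drug a [drug_profile()].
#' @param conc_multiple dose as a multiple of Cmax, \code{>= 0}.
#' @return A new \code{ord_params} object.
#' @export
apply_drug <- function(params, drug, conc_multiple) {
  stopifnot(inherits(params, "ord_params"), inherits(drug, "drug_profile"))
  if (conc_multiple < 0) stop("conc_multiple must be >= 0", call. = FALSE)
  conc <- conc_multiple * drug$cmax
  block <- params$block
  if (nrow(drug$hill) && conc > 0) {
    for (k in seq_len(nrow(drug$hill))) {
      ch <- drug$hill$channel[k]
      b <- hill_block_fraction(conc, drug$hill$ic50_nM[k], drug$hill$hill[k])
      # compose with any pre-existing block multiplicatively
      block[ch] <- 1 - (1 - block[ch]) * (1 - b)
    }
  }
  ord_params(scaling = params$scaling,
             block = block,
             drug_conc = if (is.null(drug$binding)) 0 else conc,
             binding = drug$binding,
             ikr_reduction = params$ikr_reduction)
}

#' Apply a drug under the static pore-block IKr representation
#'
#' Model variant in which IKr block is represented by a Hill equation on the
#' IKr conductance (using the drug's IKr IC50) instead of dynamic binding.
#' Used to compare the dynamic and static representations.
#'
#' @inheritParams apply_drug
#' @param ikr_hill Hill coefficient for the IKr block (default 1).
#' @return A new \code{ord_params} object with a reduced IKr scaler and no
#'   binding.
#' @export
apply_drug_static_ikr <- function(params, drug, conc_multiple, ikr_hill = 1) {
  stopifnot(inherits(drug, "drug_profile"))
  if (is.na(drug$ikr_ic50_nM))
    stop("static IKr variant needs an IKr IC50 in the drug profile",
         call. = FALSE)
  p <- apply_drug(params, drug, conc_multiple)
  p$drug_conc <- 0
  p$binding <- NULL
  b <- hill_block_fraction(conc_multiple * drug$cmax, drug$ikr_ic50_nM,
                           ikr_hill)
  p$scaling <- conductance_scaling(
    IKr = p$scaling[["IKr"]] * (1 - b), IKs = p$scaling[["IKs"]],
    IK1 = p$scaling[["IK1"]], ICaL = p$scaling[["ICaL"]],
    INaL = p$scaling[["INaL"]])
  p
}

#' Read a drug panel from CSV tables
#'
#' Reads the long-format Hill table (columns \code{drug}, \code{channel},
#' \code{ic50_nM}, \code{hill}, \code{cmax_nM}), the IKr binding table
#' (columns \code{drug}, \code{Kmax}, \code{Ku}, \code{n}, \code{halfmax},
#' \code{Vhalf}, \code{ikr_ic50_nM}) and the risk-category table (columns
#' \code{drug}, \code{risk_category}) into a named list of
#' [drug_profile()]s.  Channels missing from the Hill table are treated as
#' unblocked.
#'
#' @param hill_csv,binding_csv,risk_csv file paths; the defaults load the
#'   synthetic fixture panel bundled with the package (see
#'   [fixture_drug_panel()]).
#' @return Named list of \code{drug_profile} objects.
#' @export
read_drug_table <- function(hill_csv, binding_csv, risk_csv = NULL) {
  hill <- utils::read.csv(hill_csv, stringsAsFactors = FALSE)
  need <- c("drug", "channel", "ic50_nM", "hill", "cmax_nM")
  if (!all(need %in% names(hill)))
    stop("Hill CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bind <- utils::read.csv(binding_csv, stringsAsFactors = FALSE)
  risk <- if (!is.null(risk_csv))
    utils::read.csv(risk_csv, stringsAsFactors = FALSE) else NULL
  drugs <- union(unique(hill$drug), unique(bind$drug))
  out <- lapply(drugs, function(dn) {
    h <- hill[hill$drug == dn, c("channel", "ic50_nM", "hill")]
    b <- bind[bind$drug == dn, , drop = FALSE]
    cmax <- unique(hill$cmax_nM[hill$drug == dn])
    if (length(cmax) == 0 && nrow(b)) cmax <- b$cmax_nM[1]
    if (length(cmax) != 1 || is.na(cmax))
      stop("ambiguous or missing cmax for drug ", dn, call. = FALSE)
    binding <- NULL
    ikr_ic50 <- NA
    if (nrow(b)) {
      binding <- ikr_binding_params(b[1, c("Kmax", "Ku", "n", "halfmax",
                                           "Vhalf")])
      if ("ikr_ic50_nM" %in% names(b)) ikr_ic50 <- b$ikr_ic50_nM[1]
    }
    rc <- NA
    if (!is.null(risk) && dn %in% risk$drug)
      rc <- risk$risk_category[risk$drug == dn]
    drug_profile(dn, cmax = cmax, hill = h, binding = binding,
                 risk_category = rc, ikr_ic50_nM = ikr_ic50)
  })
  stats::setNames(out, drugs)
}

#' The bundled synthetic 12-drug fixture panel
#'
#' A stand-in panel for the 12 training compounds of the CiPA paradigm
#' (4 high-, 4 intermediate-, 4 low-risk drugs).  IC50/Cmax values are
#' anchored where possible to figures quoted in the primary literature
#' (e.g. dofetilide IKr IC50 4.87 nM at Cmax 2 nM, cisapride 10.1 nM at
#' 2.6 nM) and otherwise set to literature-plausible magnitudes; the IKr
#' binding kinetics are synthetic parameterizations expressing each drug's
#' qualitative unbinding/trapping class.  They are fixtures for development
#' and testing, not measured data.
#'
#' @return Named list of [drug_profile()]s.
#' @export
fixture_drug_panel <- function() {
  ext <- system.file("extdata", package = "cipaord")
  read_drug_table(file.path(ext, "fixture_drug_hill.csv"),
                  file.path(ext, "fixture_drug_ikr_binding.csv"),
                  file.path(ext, "fixture_drug_risk.csv"))
}

#' Fixed-fraction channel block conditions
#'
#' Conductance block applied as fixed fractions rather than through Hill
#' curves; used for the calibration experiments that mimic classical
#' channel-blocker assays (e.g. E-4031 as 70% IKr block).  For IKr the
#' fraction is applied to the conductance scaler directly (these calibration
#' compounds are represented as pure conductance block).
#'
#' @param params baseline [ord_params()].
#' @param fractions named fractional block in \[0, 1\]; names among
#'   \code{IKr}, \code{IKs}, \code{IK1}, \code{ICaL}, \code{INaL},
#'   \code{INa}, \code{Ito}.
#' @return A new \code{ord_params} object.
#' @export
apply_block_condition <- function(params, fractions) {
  stopifnot(inherits(params, "ord_params"))
  if (any(fractions < 0 | fractions > 1))
    stop("block fractions must lie in [0, 1]", call. = FALSE)
  s <- as.list(params$scaling)
  blk <- params$block
  for (ch in names(fractions)) {
    if (ch == "IKr") {
      s$IKr <- s$IKr * (1 - fractions[[ch]])
    } else if (ch %in% names(blk)) {
      blk[ch] <- 1 - (1 - blk[ch]) * (1 - fractions[[ch]])
    } else stop("unknown channel: ", ch, call. = FALSE)
  }
  ord_params(scaling = do.call(conductance_scaling, s), block = blk,
             drug_conc = params$drug_conc, binding = params$binding,
             ikr_reduction = params$ikr_reduction)
}

#' Calibration block conditions
#'
#' The five classical channel-blocker conditions used for conductance
#' calibration, as fixed block fractions: 1 uM E-4031 (70% IKr), 1 uM
#' HMR-1556 (90% IKs), 1 uM nisoldipine (90% ICaL), 100 uM BaCl2 (90% IK1)
#' and 10 uM mexiletine (54% INaL, 9% IKr, 20% ICaL).
#'
#' @return Named list of named block-fraction vectors.
#' @export
calibration_block_conditions <- function() {
  list(
    control    = c(),
    e4031      = c(IKr = 0.70),
    hmr1556    = c(IKs = 0.90),
    nisoldipine = c(ICaL = 0.90),
    bacl2      = c(IK1 = 0.90),
    mexiletine = c(INaL = 0.54, IKr = 0.09, ICaL = 0.20))
}
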