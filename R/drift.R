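## Drift-tube transit simulation: mass-action kinetics of the ion ensemble
## against constant neutral reservoirs, integrated with a stiff-capable
## solver.  Neutral depletion within one transit is negligible (analyte
## vastly outnumbers the ions); the slow headspace dilution lives in the
## per-cycle schedule of simulatePIDK.

.KBOLTZ <- 1.380649e-23  # J/K

## E/N in Townsend: field (V/cm) over number density (cm^-3), in units of
## 1e-17 V cm^2.
.enTd <- function(voltage, pressure_mbar, temperature, length_cm) {
  n_cm3 <- (pressure_mbar * 100) / (.KBOLTZ * temperature) * 1e-6
  (voltage / length_cm) / n_cm3 / 1e-17
}

#' Drift-tube operating conditions
#'
#' @slot pressure drift pressure, mbar.
#' @slot temperature drift temperature, K.
#' @slot voltage drift voltage, V.
#' @slot length drift length, cm.
#' @slot reactionTime ion residence (reaction) time, s.
#' @slot numberDensity derived buffer number density, cm^-3.
#' @slot eOverN derived reduced field, Td.
#' @export
setClass("DriftConditions",
  representation(pressure = "numeric", temperature = "numeric",
    voltage = "numeric", length = "numeric", reactionTime = "numeric",
    numberDensity = "numeric", eOverN = "numeric"),
  validity = function(object) {
    vals <- c(object@pressure, object@temperature, object@voltage,
      object@length, object@reactionTime)
    if (any(vals <= 0)) return("all conditions must be positive")
    en <- .enTd(object@voltage, object@pressure, object@temperature,
      object@length)
    if (abs(en - object@eOverN) > 1e-12 * en)
      return("stored E/N inconsistent with U_D, p, T, L")
    TRUE
  })

#' Construct drift-tube conditions
#'
#' Number density and E/N are derived, never set directly.
#'
#' @param pressure drift pressure, mbar.
#' @param temperature drift temperature, K.
#' @param voltage drift voltage, V.
#' @param length drift length, cm (default 9.2, typical for the
#'   high-sensitivity instrument class).
#' @param reactionTime residence time, s (default 1e-4).
#' @return a \code{\linkS4class{DriftConditions}}.
#' @examples
#' driftConditions(2.1, 333.15, 600)
#' @export
driftConditions <- function(pressure, temperature, voltage, length = 9.2,
                            reactionTime = 1e-4) {
  n_cm3 <- (pressure * 100) / (.KBOLTZ * temperature) * 1e-6
  new("DriftConditions", pressure = pressure, temperature = temperature,
    voltage = voltage, length = length, reactionTime = reactionTime,
    numberDensity = n_cm3,
    eOverN = .enTd(voltage, pressure, temperature, length))
}

#' @describeIn driftConditions reduced field in Td.
#' @param object a \code{DriftConditions}.
#' @export
eOverN <- function(object) {
  stopifnot(is(object, "DriftConditions"))
  object@eOverN
}

#' @export
setMethod("show", "DriftConditions", function(object) {
  cat(sprintf(
    "DriftConditions: %.2f mbar, %.2f K, U_D = %.0f V, L = %.1f cm\n",
    object@pressure, object@temperature, object@voltage, object@length))
  cat(sprintf("  t_r = %.3g s, n = %.4g cm^-3, E/N = %.1f Td\n",
    object@reactionTime, object@numberDensity, object@eOverN))
})

#' Phenomenological soft-ionization (reduced internal energy) model
#'
#' Under deep depletion the primary ion reacts near the tube entrance,
#' before the drift field has heated it; protonation there behaves as at
#' low collision energy and fragments less.  This is modelled as a
#' fragment-branching scale rising linearly from \code{betaCold} at the
#' entrance to the nominal branching at fraction \code{zTh} of the tube,
#' flat afterwards.
#'
#' @slot zTh thermalization length as a fraction of the drift length,
#'   in (0, 1].
#' @slot betaCold fragment branching scale at the entrance, in [0, 1]
#'   (relative to nominal: 1 = no softening).
#' @export
setClass("SoftIonizationModel",
  representation(zTh = "numeric", betaCold = "numeric"),
  validity = function(object) {
    if (object@zTh <= 0 || object@zTh > 1)
      return("zTh must lie in (0, 1]")
    if (object@betaCold < 0 || object@betaCold > 1)
      return("betaCold must lie in [0, 1]")
    TRUE
  })

#' @describeIn SoftIonizationModel-class constructor.
#' @param zTh thermalization length, fraction of L.
#' @param betaCold entrance branching scale relative to nominal.
#' @export
softIonizationModel <- function(zTh = 0.5, betaCold = 0) {
  new("SoftIonizationModel", zTh = zTh, betaCold = betaCold)
}

## Precompute the flux machinery for one neutral environment.
## Returns NULL when nothing can fire.
.compileRates <- function(network, neutrals) {
  sp <- network@species
  ionNames <- sp$name[sp$ion]
  rx <- Filter(function(r) r$active, network@reactions)
  if (!length(rx)) return(NULL)
  nR <- length(rx)
  iidx <- integer(nR); pidx <- integer(nR); kneu <- numeric(nR)
  soft <- logical(nR); intact <- logical(nR); grp <- character(nR)
  brnom <- numeric(nR)
  isIon <- setNames(sp$ion, sp$name)
  for (j in seq_len(nR)) {
    r <- rx[[j]]
    ri <- names(r$reactants)[isIon[names(r$reactants)]]
    pi <- names(r$products)[isIon[names(r$products)]]
    iidx[j] <- match(ri, ionNames)
    pidx[j] <- match(pi, ionNames)
    fac <- r$k * (if (is.na(r$branching)) 1 else r$branching)
    for (s in names(r$reactants)) {
      if (!isIon[[s]]) {
        conc <- neutrals[[s]]
        if (is.null(conc) || is.na(conc))
          stop("missing neutral concentration for ", s, call. = FALSE)
        fac <- fac * conc^r$reactants[[s]]
      }
    }
    kneu[j] <- fac
    soft[j] <- r$soft; intact[j] <- r$intact; grp[j] <- r$group
    brnom[j] <- if (is.na(r$branching)) 1 else r$branching
  }
  ## incidence matrix ions x reactions
  M <- matrix(0, length(ionNames), nR)
  for (j in seq_len(nR)) {
    M[iidx[j], j] <- M[iidx[j], j] - 1
    M[pidx[j], j] <- M[pidx[j], j] + 1
  }
  list(ionNames = ionNames, iidx = iidx, pidx = pidx, kneu = kneu,
    M = M, soft = soft, intact = intact, group = grp, brnom = brnom,
    tags = vapply(rx, function(r)
      if (is.na(r$tag)) "" else r$tag, ""),
    labels = vapply(rx, function(r)
      paste(names(r$products)[isIon[names(r$products)]], collapse = "+"), ""))
}

.ionVector <- function(network, ions) {
  sp <- network@species
  ionNames <- sp$name[sp$ion]
  y0 <- setNames(numeric(length(ionNames)), ionNames)
  unknown <- setdiff(names(ions), sp$name)
  if (length(unknown))
    stop("unknown species in ion densities: ",
      paste(unknown, collapse = ", "), call. = FALSE)
  if (any(ions < 0)) stop("negative ion density", call. = FALSE)
  y0[intersect(names(ions), ionNames)] <-
    ions[intersect(names(ions), ionNames)]
  y0
}

#' Simulate one drift-tube transit
#'
#' Integrates the mass-action rate equations of the ion ensemble over the
#' reaction time, treating neutrals as constant reservoirs.  All reactions
#' carry exactly one ion on each side, so total ion density is conserved
#' (to integrator tolerance).
#'
#' @param network a \code{\linkS4class{ReactionNetwork}}.
#' @param ions named numeric vector of initial ion densities, cm^-3.
#' @param neutrals named numeric vector of neutral concentrations, cm^-3.
#' @param tr reaction time, s.
#' @param rtol,atol integrator tolerances (defaults 1e-9 relative,
#'   1e-6 cm^-3 absolute).  The final state is additionally projected
#'   back onto the conserved total ion density -- exact for this reaction
#'   class, where every reaction carries one ion on each side -- so charge
#'   conservation holds to floating-point accuracy.
#' @param yields also return time-integrated per-reaction fluxes.
#' @return named vector of final ion densities; with \code{yields = TRUE},
#'   a list \code{(densities, yields)}.
#' @examples
#' net <- buildNetwork(list(
#'   species = list(
#'     list(name = "H3O+", mz = 19, role = "primary-ion"),
#'     list(name = "M", mz = 0, role = "neutral"),
#'     list(name = "MH+", mz = 63, role = "product-ion"),
#'     list(name = "H2O", mz = 0, role = "neutral")),
#'   reactions = list(list(reactants = c("H3O+" = 1, "M" = 1),
#'     products = c("MH+" = 1, "H2O" = 1), k = 2e-9))))
#' simulateDrift(net, c("H3O+" = 1e4), c(M = 5e12, H2O = 0), 1e-4)
#' @export
simulateDrift <- function(network, ions, neutrals, tr,
                          rtol = 1e-9, atol = 1e-6, yields = FALSE) {
  stopifnot(is(network, "ReactionNetwork"), tr > 0)
  if (any(neutrals < 0)) stop("negative neutral concentration",
    call. = FALSE)
  y0 <- .ionVector(network, ions)
  cmp <- .compileRates(network, as.list(neutrals))
  if (is.null(cmp) || all(cmp$kneu == 0)) {
    if (yields)
      return(list(densities = y0,
        yields = setNames(numeric(length(cmp$kneu %||% numeric())),
          cmp$labels %||% character())))
    return(y0)
  }
  nIon <- length(y0); nR <- length(cmp$kneu)
  deriv <- if (yields) {
    function(t, y, parms) {
      flux <- cmp$kneu * y[cmp$iidx]
      list(c(as.vector(cmp$M %*% flux), flux))
    }
  } else {
    function(t, y, parms) {
      flux <- cmp$kneu * y[cmp$iidx]
      list(as.vector(cmp$M %*% flux))
    }
  }
  y0full <- if (yields) c(y0, numeric(nR)) else y0
  out <- lsoda(y0full, c(0, tr), deriv, parms = NULL,
    rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("drift integration failed (lsoda istate ",
      attr(out, "istate")[1], ")", call. = FALSE)
  fin <- out[nrow(out), -1]
  dens <- pmax(setNames(fin[seq_len(nIon)], names(y0)), 0)
  if (sum(dens) > 0) dens <- dens * (sum(y0) / sum(dens))
  if (!yields) return(dens)
  list(densities = dens,
    yields = setNames(fin[nIon + seq_len(nR)],
      paste0(cmp$labels, ifelse(nzchar(cmp$tags),
        paste0(":", cmp$tags), ""))))
}

#' Simulate a transit with position-dependent fragment branching
#'
#' Integrates along the tube axis (time mapped to position through the
#' constant drift velocity).  Protonation events at position z route to
#' channels flagged \code{soft} with branching scaled by the
#' \code{\linkS4class{SoftIonizationModel}} ramp; the complementary flux
#' goes to the channel flagged \code{intact} in the same group.  With a
#' flat ramp (\code{betaCold = 1}) this reproduces
#' \code{\link{simulateDrift}}.
#'
#' @inheritParams simulateDrift
#' @param soft a \code{\linkS4class{SoftIonizationModel}}.
#' @param steps evaluation grid size along z (default 200; the integrator
#'   subdivides further as needed).
#' @return list \code{(densities, yields)} as for
#'   \code{\link{simulateDrift}} with \code{yields = TRUE}.
#' @export
simulateDriftSpatial <- function(network, ions, neutrals, tr, soft,
                                 rtol = 1e-9, atol = 1e-6, steps = 200L) {
  stopifnot(is(network, "ReactionNetwork"), is(soft, "SoftIonizationModel"))
  y0 <- .ionVector(network, ions)
  cmp <- .compileRates(network, as.list(neutrals))
  if (is.null(cmp) || all(cmp$kneu == 0))
    return(list(densities = y0, yields = numeric()))
  nIon <- length(y0); nR <- length(cmp$kneu)
  softIdx <- which(cmp$soft)
  ## per soft channel, the intact partner in the same group
  partner <- vapply(softIdx, function(j) {
    i <- which(cmp$group == cmp$group[j] & cmp$intact)
    if (length(i) != 1L)
      stop("soft channel needs exactly one intact partner in its group",
        call. = FALSE)
    i
  }, 0L)
  betaScale <- function(z)
    soft@betaCold + (1 - soft@betaCold) * pmin(z / soft@zTh, 1)
  deriv <- function(z, y, parms) {
    kz <- cmp$kneu
    if (length(softIdx)) {
      sc <- betaScale(z)
      for (m in seq_along(softIdx)) {
        j <- softIdx[m]; i <- partner[m]
        moved <- cmp$kneu[j] * (1 - sc)   # flux redirected to intact
        kz[j] <- cmp$kneu[j] * sc
        kz[i] <- kz[i] + moved
      }
    }
    flux <- kz * y[cmp$iidx]
    list(c(as.vector(cmp$M %*% flux), flux) * tr)   # dz: t = z * tr
  }
  out <- lsoda(c(y0, numeric(nR)), seq(0, 1, length.out = steps + 1L),
    deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("spatial drift integration failed", call. = FALSE)
  fin <- out[nrow(out), -1]
  densS <- pmax(setNames(fin[seq_len(nIon)], names(y0)), 0)
  if (sum(densS) > 0) densS <- densS * (sum(y0) / sum(densS))
  list(densities = densS,
    yields = setNames(fin[nIon + seq_len(nR)],
      paste0(cmp$labels, ifelse(nzchar(cmp$tags),
        paste0(":", cmp$tags), ""))))
}

#' Simulate a primary ion depletion kinetics run
#'
#' One drift transit per measurement cycle while the analyte dilutes away
#' exponentially: \eqn{[M]_c = M_0 e^{-c/\tau}}.  The ion source output
#' (initial ion densities) is identical every cycle.  Output densities are
#' mapped to expected (noise-free) cps through a detector gain and an
#' optional transmission curve.  The run exhibits the two phases of the
#' method: (a) primary ion depleted and product plateau, then (b) primary
#' ion restored and product declining log-linearly with the dilution
#' constant.
#'
#' @param network a \code{\linkS4class{ReactionNetwork}}.
#' @param conditions a \code{\linkS4class{DriftConditions}} (supplies the
#'   reaction time).
#' @param dilution list with \code{M0} (initial analyte concentration,
#'   cm^-3) and \code{tau} (dilution constant, cycles).
#' @param nCycles number of cycles.
#' @param ions named initial ion densities (cm^-3), per cycle.
#' @param neutrals named neutral concentrations (cm^-3); the analyte entry
#'   named by \code{analyte} is overwritten by the dilution schedule.
#' @param analyte name of the analyte species (default \code{"M"}).
#' @param mechanism1 activate reactions tagged \code{"secondary"}
#'   (secondary proton transfer from fragment ions).
#' @param mechanism2 use the spatial soft-ionization ramp
#'   (\code{soft} must be given).
#' @param soft a \code{\linkS4class{SoftIonizationModel}} for
#'   \code{mechanism2}.
#' @param gain detector gain, cps per cm^-3 (default 300).
#' @param transmission transmission curve (data frame or function), or
#'   NULL for unit transmission.
#' @return a \code{\linkS4class{TraceSet}} of noise-free expected cps,
#'   one channel per ion species (monitored at its nominal m/z), with the
#'   per-cycle ion densities in \code{metadata(x)$densities} and the
#'   analyte schedule in \code{metadata(x)$analyte_cm3}.
#' @export
simulatePIDK <- function(network, conditions, dilution, nCycles = 200L,
                         ions, neutrals, analyte = "M",
                         mechanism1 = FALSE, mechanism2 = FALSE,
                         soft = NULL, gain = 300, transmission = NULL) {
  stopifnot(is(network, "ReactionNetwork"), is(conditions, "DriftConditions"))
  if (is.null(dilution$M0) || is.null(dilution$tau) || dilution$tau <= 0)
    stop("dilution needs M0 and tau > 0", call. = FALSE)
  if (!mechanism1 &&
      any(vapply(network@reactions, function(r)
        identical(r$tag, "secondary"), NA)))
    network <- setReactionActive(network, "secondary", FALSE)
  if (mechanism2 && is.null(soft))
    stop("mechanism2 requires a SoftIonizationModel", call. = FALSE)
  tr <- conditions@reactionTime
  sp <- network@species
  ionNames <- sp$name[sp$ion]
  mz <- sp$mz[sp$ion]
  dens <- matrix(0, length(ionNames), nCycles,
    dimnames = list(ionNames, NULL))
  Mc <- dilution$M0 * exp(-(seq_len(nCycles) - 1L) / dilution$tau)
  neu <- neutrals
  for (cyc in seq_len(nCycles)) {
    neu[analyte] <- Mc[cyc]
    dens[, cyc] <- if (mechanism2)
      simulateDriftSpatial(network, ions, neu, tr, soft)$densities
    else
      simulateDrift(network, ions, neu, tr)
  }
  tf <- if (is.null(transmission)) function(mz) rep(1, length(mz))
    else .transmissionFun(transmission)
  cps <- dens * gain * tf(mz)
  ts <- TraceSet(cps, monitoredMz = mz, cycleDuration = 1,
    provenance = "simulated",
    metadata = list(densities = dens, analyte_cm3 = Mc,
      conditions = conditions, gain = gain, species = ionNames))
  ts
}
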