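## Seeded generator of PIDK and stripping TraceSets with full ground truth.
##
## A scenario is a plain list (usually parsed from a YAML preset): reaction
## network, drift conditions, ion source output, dilution schedule, detector
## model (gain, dwell, transmission), backgrounds and overlap channels.
## Expected cps are assembled per monitored m/z by splitting each ion
## species across its isotopologue pattern; Poisson counting noise is drawn
## on integrated counts per dwell.

#' Load a scenario preset or YAML file
#'
#' Shipped presets: \code{"dms"}, \code{"des"}, \code{"dps"} (PIDK runs of
#' dimethyl, diethyl and dipropyl sulfide) and \code{"stripping_dps"}
#' (inert-gas stripping with stepped E/N).
#'
#' @param name preset name or path to a scenario YAML file.
#' @param overrides named list merged over the loaded scenario
#'   (\code{\link[utils]{modifyList}} semantics).
#' @return scenario list.
#' @export
loadScenario <- function(name, overrides = list()) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
      package = "pidkit")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario preset or file: ", name, call. = FALSE)
  sc <- yaml::read_yaml(path)
  if (!is.null(sc$extends)) {
    base <- loadScenario(sc$extends)
    sc$extends <- NULL
    sc <- modifyList(base, sc)
  }
  if (length(overrides)) sc <- modifyList(sc, overrides)
  sc
}

.scenarioConditions <- function(sc) {
  cn <- sc$conditions
  driftConditions(cn$pressure_mbar, cn$temperature_k, cn$voltage_v,
    cn$length_cm %||% 9.2, cn$reaction_time_s %||% 1e-4)
}

.scenarioNetwork <- function(sc) {
  buildNetwork(list(species = sc$species, reactions = sc$reactions))
}

.scenarioTransmission <- function(sc) {
  if (is.null(sc$transmission)) return(NULL)
  do.call(rbind, lapply(sc$transmission, function(p)
    data.frame(mz = p$mz, coefficient = p$coefficient)))
}

## Split per-species densities (species x cycles) into expected cps per
## monitored m/z, tracking every contribution for the ground truth.
.assembleChannels <- function(dens, network, monitor, gain, transmission,
                              backgrounds, overlaps) {
  sp <- network@species
  tf <- if (is.null(transmission)) function(mz) rep(1, length(mz))
    else .transmissionFun(transmission)
  nCyc <- ncol(dens)
  monitor <- sort(as.integer(monitor))
  expected <- matrix(0, length(monitor), nCyc,
    dimnames = list(paste0("mz", monitor), NULL))
  contrib <- lapply(monitor, function(m) list())
  names(contrib) <- paste0("mz", monitor)

  for (i in which(sp$ion)) {
    nm <- sp$name[i]
    if (!nm %in% rownames(dens)) next
    if (is.na(sp$formula[i])) {
      fracs <- setNames(1, "0")
    } else {
      fracs <- patternFractions(
        isotopePattern(chemFormula(sp$formula[i], charge = 1L)))
    }
    for (s in names(fracs)) {
      mzs <- sp$mz[i] + as.integer(s)
      j <- match(mzs, monitor)
      if (is.na(j)) next
      add <- dens[nm, ] * gain * fracs[[s]] * tf(mzs)
      expected[j, ] <- expected[j, ] + add
      contrib[[j]][[paste0(nm, "/+", s)]] <- add
    }
  }
  ## constant backgrounds
  for (m in seq_along(monitor)) {
    bg <- backgrounds[[as.character(monitor[m])]] %||%
      backgrounds[["default"]] %||% 0
    if (bg > 0) {
      add <- rep(as.numeric(bg), nCyc)
      expected[m, ] <- expected[m, ] + add
      contrib[[m]][["background"]] <- add
    }
  }
  ## overlap channels proportional to a source species' base channel
  for (ov in overlaps) {
    j <- match(as.integer(ov$mz), monitor)
    if (is.na(j)) next
    src <- dens[ov$source, ] * gain * tf(sp$mz[sp$name == ov$source])
    add <- as.numeric(ov$fraction) * src
    expected[j, ] <- expected[j, ] + add
    contrib[[j]][[paste0("overlap:", ov$source)]] <- add
  }
  list(expected = expected, contrib = contrib, monitor = monitor)
}

## Ground-truth class per monitored channel, from the network structure:
## heavy isotopologues (and constant-branching satellites) of the
## protonated parent run parallel; fragment ions drained by an active
## secondary proton transfer show a depletion minimum; adduct ions peak
## during replenishment.  Channels with mixed provenance get NA.
.truthClasses <- function(network, monitor, contrib, mechanism1,
                          parent = "MH+") {
  sp <- network@species
  secondaryDonors <- unique(unlist(lapply(network@reactions, function(r) {
    if (identical(r$tag, "secondary") && r$active)
      names(r$reactants)[sp$ion[match(names(r$reactants), sp$name)]]
  })))
  out <- setNames(rep(NA_character_, length(monitor)),
    paste0("mz", monitor))
  for (m in seq_along(monitor)) {
    srcs <- names(contrib[[m]])
    srcs <- srcs[srcs != "background"]
    if (!length(srcs)) next
    ## dominant source must carry essentially the whole channel, on
    ## every cycle where the channel is above the noise floor
    totals <- vapply(contrib[[m]][srcs], mean, 0.0)
    dom <- which.max(totals)
    tot_cyc <- Reduce(`+`, contrib[[m]][srcs])
    frac_cyc <- contrib[[m]][[srcs[dom]]] / pmax(tot_cyc, .Machine$double.eps)
    use <- tot_cyc >= 1
    if (totals[dom] < 0.95 * sum(totals) ||
        (any(use) && min(frac_cyc[use]) < 0.9)) next   # mixed: no clean truth
    srcs <- srcs[dom]
    if (grepl("^overlap:", srcs)) next
    spec <- sub("/\\+[0-9]+$", "", srcs)
    shift <- as.integer(sub("^.*/\\+", "", srcs))
    role <- sp$role[sp$name == spec]
    if (spec == parent && shift > 0) {
      out[m] <- "parallel-isotopologue"
    } else if (role == "adduct-ion") {
      out[m] <- "replenishment-peak"
    } else if (role == "fragment-ion") {
      out[m] <- if (mechanism1 && spec %in% secondaryDonors)
        "depletion-minimum" else "parallel-isotopologue"
    }
  }
  out
}

#' Generate a synthetic PIDK run with ground truth
#'
#' Runs \code{\link{simulatePIDK}} under the scenario's network and
#' dilution schedule, splits each ion species across its isotopologue
#' pattern, adds constant backgrounds and water-cluster overlap channels,
#' applies the transmission curve, and draws Poisson counts per cycle
#' (counts = cps x dwell, emitted as counts/dwell).  Identical scenario
#' and seed give bit-identical output.
#'
#' @param scenario scenario list (see \code{\link{loadScenario}}).
#' @param seed integer seed; mandatory, recorded in the output metadata.
#' @param noise draw Poisson counting noise (default TRUE).
#' @return list with \code{traces} (a \code{\linkS4class{TraceSet}}) and
#'   \code{truth} (per-cycle species densities, per-channel expected cps
#'   and contributions, phase boundaries, true classes and reaction
#'   orders, applied transmission and detector settings).
#' @export
generatePIDK <- function(scenario, seed, noise = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible generation", call. = FALSE)
  network <- .scenarioNetwork(scenario)
  conditions <- .scenarioConditions(scenario)
  mech1 <- isTRUE(scenario$mechanism1)
  mech2 <- isTRUE(scenario$mechanism2)
  soft <- if (mech2)
    softIonizationModel(scenario$soft$z_th %||% 0.5,
      scenario$soft$beta_cold %||% 0) else NULL
  dil <- list(M0 = scenario$dilution$m0_cm3,
    tau = scenario$dilution$tau_cycles)
  nCycles <- scenario$dilution$n_cycles
  gain <- scenario$gain_cps_per_cm3 %||% 300
  dwell <- scenario$dwell_s %||% 0.5
  if (dwell <= 0) stop("dwell must be > 0", call. = FALSE)
  ions <- unlist(scenario$ions_cm3)
  neutrals <- unlist(scenario$neutrals_cm3)

  sim <- simulatePIDK(network, conditions, dil, nCycles, ions, neutrals,
    analyte = scenario$analyte %||% "M",
    mechanism1 = mech1, mechanism2 = mech2, soft = soft,
    gain = gain, transmission = NULL)
  dens <- metadata(sim)$densities

  asm <- .assembleChannels(dens, network, scenario$monitor, gain,
    .scenarioTransmission(scenario), scenario$background_cps %||% list(),
    scenario$overlaps %||% list())

  cps <- asm$expected
  if (noise) {
    set.seed(as.integer(seed))
    cps <- matrix(rpois(length(cps), lambda = cps * dwell) / dwell,
      nrow(cps), ncol(cps), dimnames = dimnames(cps))
  }
  ts <- TraceSet(cps, monitoredMz = asm$monitor, cycleDuration = dwell,
    provenance = "simulated",
    metadata = list(seed = as.integer(seed), scenario = scenario$name,
      conditions = conditions))

  ## phase boundaries from the noise-free monitored primary-ion channel
  primMz <- scenario$primary_mz %||% 21L
  prim <- asm$expected[paste0("mz", primMz), ]
  phases <- tryCatch(segmentPhases(prim), error = function(e) NULL)

  if (!mech1) {
    netEff <- if (any(vapply(network@reactions, function(r)
      identical(r$tag, "secondary"), NA)))
      setReactionActive(network, "secondary", FALSE) else network
  } else netEff <- network
  classes <- .truthClasses(netEff, asm$monitor, asm$contrib, mech1,
    parent = scenario$parent_species %||% "MH+")
  orders <- setNames(rep(NA_real_, length(asm$monitor)),
    paste0("mz", asm$monitor))
  sp <- network@species
  for (m in seq_along(asm$monitor)) {
    srcs <- setdiff(names(asm$contrib[[m]]), "background")
    totals <- vapply(asm$contrib[[m]][srcs], mean, 0.0)
    if (!length(srcs) || max(totals) < 0.95 * sum(totals)) next
    srcs <- srcs[which.max(totals)]
    if (grepl("^overlap:", srcs)) next
    spec <- sub("/\\+[0-9]+$", "", srcs)
    orders[m] <- if (sp$role[sp$name == spec] == "adduct-ion") 2 else 1
  }

  truth <- list(densities = dens,
    analyte_cm3 = metadata(sim)$analyte_cm3,
    expected_cps = asm$expected, contributions = asm$contrib,
    phases = phases, classes = classes, orders = orders,
    transmission = .scenarioTransmission(scenario),
    gain = gain, dwell = dwell, seed = as.integer(seed),
    mechanism1 = mech1, mechanism2 = mech2)
  list(traces = ts, truth = truth)
}

## set the branching of tagged channels and rebalance the intact channel
## of the same group so fractions still sum to 1.
.setBranching <- function(network, tag, value) {
  rx <- network@reactions
  for (i in seq_along(rx)) {
    if (identical(rx[[i]]$tag, tag)) {
      grp <- rx[[i]]$group
      old <- rx[[i]]$branching
      rx[[i]]$branching <- value
      j <- which(vapply(rx, function(r)
        identical(r$group, grp) && isTRUE(r$intact), NA))
      if (length(j) == 1L)
        rx[[j]]$branching <- rx[[j]]$branching + (old - value)
    }
  }
  network@reactions <- rx
  network
}

#' Generate a synthetic inert-gas-stripping run with stepped E/N
#'
#' The analyte concentration decays exponentially with the stripping
#' constant (optionally steepened by a flux boost on the final step, which
#' helps fragment identification); the drift voltage steps through the
#' configured schedule, and fragment branching may depend on E/N through a
#' configured monotone (linearly interpolated) table.  An optional
#' contaminant channel is fed by a constant source independent of the
#' analyte.
#'
#' @param scenario scenario list; in addition to the PIDK fields it needs
#'   \code{en_schedule} (\code{voltages_v}, \code{cycles_per_step}),
#'   \code{stripping} (\code{m0_cm3}, \code{tau_cycles}, optional
#'   \code{final_flux_boost}) and optionally \code{branching_en} (list of
#'   \code{tag}, \code{en_td}, \code{branching} tables) and
#'   \code{contaminant} (\code{mz}, \code{cps}).
#' @param seed integer seed (mandatory).
#' @param noise draw Poisson counting noise (default TRUE).
#' @return list with \code{traces} and \code{truth} as for
#'   \code{\link{generatePIDK}}; \code{truth} additionally records the
#'   per-cycle analyte concentration, E/N schedule, per-step branching and
#'   the contaminant channel.
#' @export
generateStripping <- function(scenario, seed, noise = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible generation", call. = FALSE)
  network <- .scenarioNetwork(scenario)
  if (!isTRUE(scenario$mechanism1) &&
      any(vapply(network@reactions, function(r)
        identical(r$tag, "secondary"), NA)))
    network <- setReactionActive(network, "secondary", FALSE)
  cn <- scenario$conditions
  sched <- scenario$en_schedule
  volts <- rep(unlist(sched$voltages_v),
    each = sched$cycles_per_step %||% 5L)
  nCycles <- length(volts)
  enPerCycle <- vapply(volts, function(v)
    enFromVoltage(v, cn$pressure_mbar, cn$temperature_k,
      cn$length_cm %||% 9.2), 0.0)
  strip <- scenario$stripping
  rate <- rep(1 / strip$tau_cycles, nCycles)
  if (!is.null(strip$final_flux_boost)) {
    lastStep <- seq.int(nCycles - (sched$cycles_per_step %||% 5L) + 1L,
      nCycles)
    rate[lastStep] <- rate[lastStep] * strip$final_flux_boost
  }
  Mc <- strip$m0_cm3 * exp(-cumsum(c(0, rate[-nCycles])))

  gain <- scenario$gain_cps_per_cm3 %||% 300
  dwell <- scenario$dwell_s %||% 0.5
  ions <- unlist(scenario$ions_cm3)
  neutrals <- unlist(scenario$neutrals_cm3)
  tr <- cn$reaction_time_s %||% 1e-4
  sp <- network@species
  ionNames <- sp$name[sp$ion]
  dens <- matrix(0, length(ionNames), nCycles,
    dimnames = list(ionNames, NULL))
  brTruth <- list()
  for (cyc in seq_len(nCycles)) {
    net <- network
    for (bt in scenario$branching_en %||% list()) {
      b <- approx(unlist(bt$en_td), unlist(bt$branching),
        xout = enPerCycle[cyc], rule = 2)$y
      net <- .setBranching(net, bt$tag, b)
      brTruth[[bt$tag]] <- c(brTruth[[bt$tag]], b)
    }
    neutrals[scenario$analyte %||% "M"] <- Mc[cyc]
    dens[, cyc] <- simulateDrift(net, ions, neutrals, tr)
  }

  asm <- .assembleChannels(dens, network, scenario$monitor, gain,
    .scenarioTransmission(scenario), scenario$background_cps %||% list(),
    scenario$overlaps %||% list())
  cps <- asm$expected
  contrib <- asm$contrib
  if (!is.null(scenario$contaminant)) {
    j <- match(as.integer(scenario$contaminant$mz), asm$monitor)
    if (!is.na(j)) {
      add <- rep(as.numeric(scenario$contaminant$cps), nCycles)
      cps[j, ] <- cps[j, ] + add
      contrib[[j]][["contaminant"]] <- add
    }
  }
  expected <- cps
  if (noise) {
    set.seed(as.integer(seed))
    cps <- matrix(rpois(length(cps), lambda = cps * dwell) / dwell,
      nrow(cps), ncol(cps), dimnames = dimnames(cps))
  }
  ts <- TraceSet(cps, monitoredMz = asm$monitor, cycleDuration = dwell,
    eOverN = enPerCycle, provenance = "simulated",
    metadata = list(seed = as.integer(seed), scenario = scenario$name))
  truth <- list(densities = dens, analyte_cm3 = Mc,
    expected_cps = expected, contributions = contrib,
    e_over_n_td = enPerCycle, stripping_rate = rate,
    branching = brTruth, contaminant = scenario$contaminant,
    gain = gain, dwell = dwell, seed = as.integer(seed))
  list(traces = ts, truth = truth)
}
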