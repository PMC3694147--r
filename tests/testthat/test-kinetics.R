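test_that("network building validates charge, elements, branching and PA gating", {
  net <- minimal_network()
  expect_length(networkReactions(net), 1L)
  expect_true(networkReactions(net)[[1]]$active)

  ## PA gate: donor above acceptor -> inactive
  cfg <- list(
    species = list(
      list(name = "F1H+", mz = 47, role = "fragment-ion"),
      list(name = "F1", mz = 0, role = "neutral", pa = 900),
      list(name = "M", mz = 0, role = "neutral", pa = 830.9),
      list(name = "MH+", mz = 63, role = "product-ion")),
    reactions = list(list(reactants = c("F1H+" = 1, "M" = 1),
      products = c("MH+" = 1, "F1" = 1), k = 2e-9, pa_gated = TRUE,
      pa_donor = "F1", pa_acceptor = "M")))
  expect_false(networkReactions(buildNetwork(cfg))[[1]]$active)

  ## charge imbalance
  bad <- list(
    species = list(
      list(name = "A+", mz = 10, role = "product-ion"),
      list(name = "B+", mz = 11, role = "product-ion"),
      list(name = "N", mz = 0, role = "neutral")),
    reactions = list(list(reactants = c("A+" = 1),
      products = c("A+" = 1, "B+" = 1), k = 1)))
  expect_error(buildNetwork(bad), "charge conservation")

  ## element imbalance (formulas supplied)
  bad2 <- list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion", formula = "H3O"),
      list(name = "M", mz = 0, role = "neutral", formula = "C2H6S"),
      list(name = "MH+", mz = 63, role = "product-ion",
        formula = "C2H7S")),
    reactions = list(list(reactants = c("H3O+" = 1, "M" = 1),
      products = c("MH+" = 1), k = 1)))
  expect_error(buildNetwork(bad2), "element balance")

  ## branching must close over a shared-reactant group
  bad3 <- list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion"),
      list(name = "M", mz = 0, role = "neutral"),
      list(name = "MH+", mz = 63, role = "product-ion"),
      list(name = "FH+", mz = 47, role = "fragment-ion"),
      list(name = "W", mz = 0, role = "neutral")),
    reactions = list(
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("MH+" = 1, "W" = 1), k = 1, branching = 0.9),
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("FH+" = 1, "W" = 1), k = 1, branching = 0.3)))
  expect_error(buildNetwork(bad3), "sum to 1")

  ## missing PA on a gated reaction
  bad4 <- cfg
  bad4$species[[2]]$pa <- NULL
  expect_error(buildNetwork(bad4), "missing proton affinity")
})

test_that("shipped presets build and the DPS preset carries the m/z 161 adduct channel", {
  for (nm in c("dms", "des", "dps")) {
    sc <- loadScenario(nm)
    net <- buildNetwork(list(species = sc$species,
      reactions = sc$reactions))
    expect_s4_class(net, "ReactionNetwork")
  }
  sc <- loadScenario("dps")
  net <- buildNetwork(list(species = sc$species, reactions = sc$reactions))
  sp <- networkSpecies(net)
  expect_true(161 %in% sp$mz[sp$role == "adduct-ion"])
  has161 <- any(vapply(networkReactions(net), function(r)
    "AH+" %in% names(r$products) && sum(r$reactants[["M"]]) == 2, NA))
  expect_true(has161)
})

test_that("drift simulation reproduces the pseudo-first-order limit and conserves charge", {
  net <- minimal_network(k = 2e-9)
  out <- simulateDrift(net, c("H3O+" = 1e4), c(M = 5e12, H2O = 0), 1e-4)
  expect_equal(out[["H3O+"]] / 1e4, exp(-1), tolerance = 1e-6)
  expect_equal(out[["MH+"]] / 1e4, 1 - exp(-1), tolerance = 1e-6)
  expect_equal(sum(out), 1e4, tolerance = 1e-9)

  ## no analyte: identity, exactly
  out0 <- simulateDrift(net, c("H3O+" = 1e4), c(M = 0, H2O = 0), 1e-4)
  expect_identical(unname(out0[["H3O+"]]), 1e4)
  expect_error(simulateDrift(net, c("H3O+" = -1), c(M = 0, H2O = 0), 1e-4),
    "negative")
  expect_error(simulateDrift(net, c("H3O+" = 1), c(M = -5, H2O = 0), 1e-4),
    "negative")
})

test_that("two-step secondary-protonation chain matches the RK4 oracle", {
  cfg <- list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion"),
      list(name = "M", mz = 0, role = "neutral", pa = 830.9),
      list(name = "MH+", mz = 63, role = "product-ion"),
      list(name = "FH+", mz = 47, role = "fragment-ion"),
      list(name = "F", mz = 0, role = "neutral", pa = 760),
      list(name = "W", mz = 0, role = "neutral")),
    reactions = list(
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("MH+" = 1, "W" = 1), k = 2e-9, branching = 0.9),
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("FH+" = 1, "W" = 1), k = 2e-9, branching = 0.1),
      list(reactants = c("FH+" = 1, "M" = 1),
        products = c("MH+" = 1, "F" = 1), k = 3e-9, pa_gated = TRUE,
        pa_donor = "F", pa_acceptor = "M")))
  net <- buildNetwork(cfg)
  ions <- c("H3O+" = 1e4, "MH+" = 0, "FH+" = 0)
  neutrals <- c(M = 5e12, F = 0, W = 0)
  got <- simulateDrift(net, ions, neutrals, 1e-4)

  oracle_rx <- list(
    list(reactants = c("H3O+" = 1, "M" = 1),
      products = c("MH+" = 1, "W" = 1), k = 2e-9 * 0.9),
    list(reactants = c("H3O+" = 1, "M" = 1),
      products = c("FH+" = 1, "W" = 1), k = 2e-9 * 0.1),
    list(reactants = c("FH+" = 1, "M" = 1),
      products = c("MH+" = 1, "F" = 1), k = 3e-9))
  want <- oracle_rk4_drift(oracle_rx, ions, as.list(neutrals), 1e-4,
    steps = 1000L)
  for (nm in names(ions))
    expect_equal(got[[nm]], want[[nm]], tolerance = 1e-6)
})

test_that("adduct yield is quadratic in analyte in the low-depletion limit", {
  sc <- loadScenario("dps")
  net <- buildNetwork(list(species = sc$species, reactions = sc$reactions))
  ions <- unlist(sc$ions_cm3)
  neu <- unlist(sc$neutrals_cm3)
  neu["M"] <- 1e10
  a1 <- simulateDrift(net, ions, neu, 1e-4)[["AH+"]]
  neu["M"] <- 2e10
  a2 <- simulateDrift(net, ions, neu, 1e-4)[["AH+"]]
  expect_equal(a2 / a1, 4.0, tolerance = 0.02)
})

test_that("reversible water-cluster pair relaxes to its closed-form equilibrium", {
  kf <- 1e-9; kr <- 5e3; H2O <- 1e12
  cfg <- list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion"),
      list(name = "W1H+", mz = 37, role = "parasitic-ion"),
      list(name = "H2O", mz = 0, role = "neutral")),
    reactions = list(
      list(reactants = c("H3O+" = 1, "H2O" = 1),
        products = c("W1H+" = 1), k = kf),
      list(reactants = c("W1H+" = 1),
        products = c("H3O+" = 1, "H2O" = 1), k = kr)))
  net <- buildNetwork(cfg)
  out <- simulateDrift(net, c("H3O+" = 1e4, "W1H+" = 0),
    c(H2O = H2O), 1e-2)
  expect_equal(out[["W1H+"]] / out[["H3O+"]], kf * H2O / kr,
    tolerance = 1e-6)
})

test_that("spatial integration reduces to the homogeneous simulator for a flat ramp", {
  net <- branched_network(beta = 0.1)
  ions <- c("H3O+" = 1e4)
  neu <- c(M = 2e12, H2O = 0)
  a <- simulateDrift(net, ions, neu, 1e-4)
  b <- simulateDriftSpatial(net, ions, neu, 1e-4,
    softIonizationModel(zTh = 0.5, betaCold = 1))$densities
  expect_equal(unname(b[names(a)]), unname(a), tolerance = 1e-8)
})

test_that("soft ionization suppresses fragments under extreme depletion", {
  net <- branched_network(beta = 0.1)
  ions <- c("H3O+" = 1e4)
  ## 99% of the reagent consumed within the first 5% of the tube
  M_extreme <- log(100) / 0.05 / (2e-9 * 1e-4)
  neu <- c(M = M_extreme, H2O = 0)
  flat <- simulateDriftSpatial(net, ions, neu, 1e-4,
    softIonizationModel(0.5, 1))$densities
  soft <- simulateDriftSpatial(net, ions, neu, 1e-4,
    softIonizationModel(0.5, 0))$densities
  expect_lt(soft[["FH+"]] / soft[["MH+"]], flat[["FH+"]] / flat[["MH+"]])
  expect_lt(soft[["FH+"]], 0.2 * flat[["FH+"]])
})

test_that("soft-model fragment fraction reaches the ramp average in the low-depletion limit", {
  net <- branched_network(beta = 0.1)
  ions <- c("H3O+" = 1e4)
  frac <- function(M) {
    d <- simulateDriftSpatial(net, ions, c(M = M, H2O = 0), 1e-4,
      softIonizationModel(zTh = 0.5, betaCold = 0))$densities
    d[["FH+"]] / (d[["FH+"]] + d[["MH+"]])
  }
  f1 <- frac(5e10)   # ~1% depletion
  f2 <- frac(2.5e10)
  expect_equal(f1, f2, tolerance = 0.02)
  ## uniform protonation: mean of the ramp = 1 - zTh/2 times nominal
  expect_equal(f1, 0.1 * 0.75, tolerance = 0.02)
})

test_that("depletion run shows a product plateau then log-linear dilution decay", {
  sc <- loadScenario("dms")
  net <- buildNetwork(list(species = sc$species, reactions = sc$reactions))
  cond <- driftConditions(2.1, 333.15, 600)
  ions <- unlist(sc$ions_cm3)
  neu <- unlist(sc$neutrals_cm3)

  ## no analyte at all: every cycle identical, primary undepleted
  sim0 <- simulatePIDK(net, cond, list(M0 = 0, tau = 15), 12L, ions, neu)
  d0 <- metadata(sim0)$densities
  expect_true(all(abs(d0 - d0[, 1]) < 1e-9 * max(d0)))
  expect_gt(d0["H3O+", 1], 0.8 * ions[["H3O+"]])

  ## fragment under secondary protonation: minimum inside depletion,
  ## monotone rise during replenishment
  sim1 <- simulatePIDK(net, cond, list(M0 = 5e14, tau = 15), 150L,
    ions, neu, mechanism1 = TRUE)
  d1 <- metadata(sim1)$densities
  h <- d1["H3O+", ]
  plateau <- median(h[113:150])
  depl <- which(h < 0.1 * plateau)
  repl <- which(h >= 0.1 * plateau & h <= 0.9 * plateau)
  f <- d1["F1H+", ]
  expect_true(which.min(f) %in% depl)
  expect_true(all(diff(f[repl]) > -1e-9))
  expect_gt(f[max(repl)], 5 * f[min(repl)])
})

test_that("drift conditions derive number density and reduced field consistently", {
  dc <- driftConditions(2.1, 333.15, 600, length = 9.2,
    reactionTime = 1e-4)
  expect_equal(eOverN(dc), 142.85, tolerance = 1e-3)
  expect_error(driftConditions(-1, 300, 600), "positive")
  expect_error(softIonizationModel(zTh = 0.5, betaCold = 2), "betaCold")
})
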