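test_that("phase segmentation recovers constructed thresholds exactly", {
  primary <- c(rep(0.05, 40), seq(0.1, 0.9, length.out = 40),
    rep(1, 40))
  seg <- segmentPhases(primary, smooth = 1L)
  expect_equal(seg@depletion, c(0L, 40L))
  expect_equal(seg@replenishment, c(40L, 80L))
  expect_equal(seg@normal, c(80L, 120L))
  expect_identical(phaseCycles(seg, "depletion"), 1:40)

  expect_error(segmentPhases(rep(1, 100)), "not a PIDK run")
  expect_error(segmentPhases(c(rep(0.01, 80), seq(0.01, 1, length.out = 20))),
    "plateau")
  expect_warning(segmentPhases(c(rep(0.01, 30),
    seq(0.01, 0.8, length.out = 15), rep(0.15, 6),
    seq(0.8, 1, length.out = 10), rep(1, 59))),
    "non-monotone")
})

test_that("segmentation of a noisy run lands within two cycles of ground truth", {
  sc <- loadScenario("dms")
  sc$dilution$n_cycles <- 150L
  g <- generatePIDK(sc, seed = 8)
  seg <- segmentPhases(getTrace(g$traces, 21))
  want <- g$truth$phases
  expect_s4_class(want, "PhaseSegmentation")
  expect_lte(abs(seg@depletion[2] - want@depletion[2]), 2L)
  expect_lte(abs(seg@normal[1] - want@normal[1]), 2L)
})

test_that("classification identifies the three fragment behaviours", {
  ## exact isotopologue multiple: the M+1 ratio of protonated DMS
  primary <- c(rep(0.05, 40), seq(0.05, 0.9, length.out = 40), rep(1, 40))
  seg <- segmentPhases(primary, smooth = 1L)
  parent <- c(rep(1000, 80), 1000 * exp(-(1:40) / 10))
  iso <- 0.0315 * parent
  expect_equal(fragmentLabel(classifyFragment(iso, parent, seg)),
    "parallel-isotopologue")
  ## scale invariance
  expect_equal(fragmentLabel(classifyFragment(7.3 * iso, parent, seg)),
    "parallel-isotopologue")

  expect_error(classifyFragment(iso[1:10], parent, seg), "length")
  expect_error(classifyFragment(0 * iso, parent, seg), "all-zero")
})

test_that("simulated runs classify fragments per their generating mechanism", {
  check <- list(
    dms = list(mz = c(47, 61, 65),
      want = c("depletion-minimum", "parallel-isotopologue",
        "parallel-isotopologue")),
    dps = list(mz = c(161, 120),
      want = c("replenishment-peak", "parallel-isotopologue")))
  for (nm in names(check)) {
    sc <- loadScenario(nm)
    sc$overlaps <- list()
    sc$dilution$n_cycles <- 135L
    sc$mechanism1 <- TRUE
    g <- generatePIDK(sc, seed = 42)
    seg <- segmentPhases(getTrace(g$traces, sc$primary_mz))
    parent <- getTrace(g$traces, sc$parent_mz)
    for (i in seq_along(check[[nm]]$mz)) {
      mz <- check[[nm]]$mz[i]
      expect_equal(g$truth$classes[[paste0("mz", mz)]],
        check[[nm]]$want[i])
      cl <- classifyFragment(getTrace(g$traces, mz), parent, seg)
      expect_equal(fragmentLabel(cl), check[[nm]]$want[i],
        label = sprintf("%s mz %d", nm, mz))
    }
  }
})

test_that("isotopologue deviation fits constructed families exactly", {
  set.seed(9)
  base <- 10^seq(5, 2, length.out = 60)
  ref <- base
  fam <- list(parent = 33 * base, m1 = 33 * 0.0315 * base,
    m2 = 33 * 0.0448 * base)
  dv <- suppressWarnings(isotopologueDeviation(ref, fam))
  expect_equal(dv$slope, rep(1, 3), tolerance = 1e-6)
  expect_equal(dv$offset,
    log10(c(33, 33 * 0.0315, 33 * 0.0448)), tolerance = 1e-6)
  expect_false(any(dv$deviation))

  ## extra drain proportional to parent^2 at high concentration:
  ## flagged on the parent, not on M+2
  drain <- 1 - 0.3 * (base / max(base))
  fam2 <- list(parent = 33 * base * drain, m2 = 33 * 0.0448 * base)
  dv2 <- isotopologueDeviation(ref, fam2)
  expect_true(dv2$deviation[dv2$trace == "parent"])
  expect_false(dv2$deviation[dv2$trace == "m2"])

  set.seed(11)
  jit <- exp(rnorm(61, 0, 0.01))
  expect_warning(isotopologueDeviation(c(0, base),
    list(parent = c(1, 33 * base) * jit)), "trimmed")
})

test_that("a quadratic analyte drain on the parent ion is flagged in simulated runs", {
  g_clean <- generatePIDK(dms_family_scenario(drain = FALSE), seed = 21,
    noise = FALSE)
  g_drain <- generatePIDK(dms_family_scenario(drain = TRUE), seed = 21,
    noise = FALSE)
  for (g in list(g_clean, g_drain)) {
    r <- getTrace(g$traces, 61)
    w <- which(r > 100)
    fam <- list(parent = getTrace(g$traces, 63),
      m64 = getTrace(g$traces, 64), m65 = getTrace(g$traces, 65))
    dv <- isotopologueDeviation(r, fam, window = w)
    if (identical(g, g_clean)) {
      expect_false(any(dv$deviation))
      expect_equal(dv$slope, rep(1, 3), tolerance = 0.01)
    } else {
      ## the drain acts on the parent ion before isotopologue splitting,
      ## so the whole family deviates at high concentration
      expect_true(dv$deviation[dv$trace == "parent"])
    }
  }
})

test_that("two-component decomposition recovers constructed mixtures exactly", {
  set.seed(10)
  n <- 120
  parasitic <- c(rep(2, 40), seq(2, 300, length.out = 40), rep(300, 40))
  ref <- c(rep(500, 80), 500 * exp(-(1:40) / 12))
  P <- 300
  target <- 0.7 * pmax(0, P - parasitic) + 0.3 * ref
  dec <- decomposeSignal(target, parasitic, ref, tailWindow = 100:120)
  expect_equal(dec@a, 0.7, tolerance = 1e-6)
  expect_equal(dec@b, 0.3, tolerance = 1e-6)
  expect_lt(dec@residualRMS, 1e-6)

  ## degenerate: satellite only
  t2 <- 0.25 * ref
  dec2 <- decomposeSignal(t2, parasitic, ref, tailWindow = 100:120)
  expect_equal(dec2@a, 0)
  expect_equal(dec2@b, 0.25, tolerance = 1e-9)
  expect_lt(dec2@residualRMS, 1e-9)

  expect_error(decomposeSignal(target, seq_len(n), ref,
    tailWindow = 10:40), "plateau")
})

test_that("reaction-order estimation is exact on power laws and unbiased", {
  parent <- 10^seq(4, 2, length.out = 40)
  ## exact power laws: lm warns about a perfect fit, which is the point
  expect_equal(suppressWarnings(
    estimateReactionOrder(0.3 * parent, parent, 1:40)$order), 1,
    tolerance = 1e-9)
  expect_equal(suppressWarnings(
    estimateReactionOrder(1e-4 * parent^2, parent, 1:40)$order),
    2, tolerance = 1e-9)
  for (ord in c(1, 1.5, 2, 3)) {
    est <- suppressWarnings(estimateReactionOrder(2 * parent^ord,
      parent, 1:40))
    expect_lt(abs(est$order - ord), 0.05)
  }
  expect_error(estimateReactionOrder(parent, parent, 1:5), "too short")
  expect_error(estimateReactionOrder(parent, parent, c(1:11, NA)),
    "invalid")
})
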