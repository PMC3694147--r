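## Seeded simulation studies validating the analysis pipeline end to end:
## classifier recovery over randomized scenarios, and calibration / power
## of the slope-equality test.  These are the package's own method-
## validation experiments, reusable from scripts and tests.

#' Classifier recovery sweep over randomized synthetic scenarios
#'
#' Generates seeded PIDK scenarios spanning the three fragment classes
#' (the three compound presets with secondary proton transfer active,
#' dilution constant and initial concentration randomized), runs the full
#' pipeline (phase segmentation on the monitored primary-ion channel,
#' then three-way classification of every channel with a clean ground
#' truth), and tabulates predicted against true classes.  Channels whose
#' plateau falls below \code{minPlateau} cps are skipped.
#'
#' @param n number of scenarios (default 200).
#' @param seed master seed; scenario i uses seed \code{seed * 1000 + i}.
#' @param minPlateau minimal channel plateau in cps (default 100).
#' @param nCycles cycles per scenario (default 135).
#' @return data frame with one row per classified channel:
#'   \code{scenario}, \code{preset}, \code{mz}, \code{truth},
#'   \code{predicted}, \code{correct}.
#' @export
classifierSweep <- function(n = 200L, seed = 1L, minPlateau = 100,
                            nCycles = 135L) {
  presets <- c("dms", "des", "dps")
  rows <- list()
  for (i in seq_len(n)) {
    iseed <- as.integer(seed) * 1000L + i
    set.seed(iseed)
    preset <- presets[(i - 1L) %% 3L + 1L]
    tau <- runif(1, 12.5, 15)
    m0scale <- runif(1, 0.8, 1.25)
    sc <- loadScenario(preset)
    sc$dilution$tau_cycles <- tau
    sc$dilution$m0_cm3 <- sc$dilution$m0_cm3 * m0scale
    sc$dilution$n_cycles <- as.integer(nCycles)
    sc$mechanism1 <- TRUE
    sc$overlaps <- list()   # clean channels: unambiguous ground truth
    g <- generatePIDK(sc, seed = iseed)
    seg <- tryCatch(segmentPhases(getTrace(g$traces, sc$primary_mz)),
      error = function(e) NULL)
    if (is.null(seg)) next
    parent <- getTrace(g$traces, sc$parent_mz)
    truth <- g$truth$classes[!is.na(g$truth$classes)]
    for (ch in names(truth)) {
      mz <- as.integer(sub("^mz", "", ch))
      exp_tr <- g$truth$expected_cps[ch, ]
      level <- max(mean(exp_tr[phaseCycles(seg, "depletion")]),
        mean(exp_tr[phaseCycles(seg, "replenishment")]),
        mean(exp_tr[phaseCycles(seg, "normal")]))
      if (!is.finite(level) || level < minPlateau) next
      pred <- fragmentLabel(classifyFragment(getTrace(g$traces, mz),
        parent, seg))
      rows[[length(rows) + 1L]] <- data.frame(scenario = i,
        preset = preset, mz = mz, truth = unname(truth[ch]),
        predicted = pred, correct = pred == truth[[ch]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Calibration and power of the slope-equality test
#'
#' Monte-Carlo study of \code{\link{confirmFragment}}: under the null,
#' both traces are Poisson realizations of the same decaying exponential;
#' under the alternative, the candidate decays with an additional slope
#' offset.  Reports the rejection rate.
#'
#' @param nRep replicates (default 1000).
#' @param seed master seed.
#' @param slopeOffset additional log10-slope of the candidate (0 = null).
#' @param plateau starting intensity, cps (default 1e4).
#' @param slope common log10 slope per cycle (default -0.01).
#' @param nCycles trace length (default 60).
#' @param dwell seconds per cycle for Poisson counts (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return list with \code{rejectionRate}, \code{n}, and the vector of
#'   p-values.
#' @export
slopeTestCalibration <- function(nRep = 1000L, seed = 1L, slopeOffset = 0,
                                 plateau = 1e4, slope = -0.01,
                                 nCycles = 60L, dwell = 0.5,
                                 alpha = 0.05) {
  set.seed(as.integer(seed))
  cyc <- seq_len(nCycles) - 1L
  pvals <- vapply(seq_len(nRep), function(r) {
    mu1 <- plateau * 10^(slope * cyc)
    mu2 <- plateau * 10^((slope + slopeOffset) * cyc)
    t1 <- rpois(nCycles, mu1 * dwell) / dwell
    t2 <- rpois(nCycles, mu2 * dwell) / dwell
    f1 <- fitLogSlope(t1)
    f2 <- fitLogSlope(t2)
    confirmFragment(f2, f1, alpha = alpha)$p
  }, 0.0)
  list(rejectionRate = mean(pvals < alpha), n = nRep, pvals = pvals)
}
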