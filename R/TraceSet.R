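## TraceSet: per-m/z ion-intensity time series (cps per measurement cycle),
## the lingua franca between simulator, generator, and analyses.

#' Ion-intensity trace container
#'
#' A \code{SummarizedExperiment} whose rows are monitored m/z channels and
#' whose columns are measurement cycles.  The single assay \code{"cps"}
#' holds counts per second.  \code{rowData} carries \code{monitored_mz}
#' (the m/z actually monitored) and \code{nominal_mz} (the ion it stands
#' for, e.g. hydronium at m/z 19 monitored via its heavy-oxygen
#' isotopologue at m/z 21); \code{colData} carries \code{cycle} and,
#' when the run steps the reduced field, \code{e_over_n_td}.
#'
#' Metadata fields: \code{cycle_duration} (s), \code{provenance}
#' (\code{"simulated"} or \code{"file"}), \code{transmission_corrected},
#' \code{background_corrected}.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"cps" %in% names(assays(object)))
      msg <- c(msg, "assay 'cps' is required")
    else {
      v <- assay(object, "cps")
      if (!is.numeric(v)) msg <- c(msg, "cps must be numeric")
      else if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "cps must be >= 0")
    }
    if (!"monitored_mz" %in% names(rowData(object)))
      msg <- c(msg, "rowData must carry monitored_mz")
    else if (anyDuplicated(rowData(object)$monitored_mz))
      msg <- c(msg, "duplicate monitored m/z channels")
    if (!"cycle" %in% names(colData(object)))
      msg <- c(msg, "colData must carry cycle")
    else {
      cy <- colData(object)$cycle
      if (length(cy) > 1L && any(diff(cy) <= 0))
        msg <- c(msg, "cycle index must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a TraceSet
#'
#' @param cps numeric matrix, rows = channels, columns = cycles.
#' @param monitoredMz integer vector of monitored m/z, one per row.
#' @param cycles cycle indices (default \code{0:(ncol-1)}).
#' @param cycleDuration cycle duration in seconds (default 1).
#' @param nominalMz nominal m/z per channel (default = monitored).
#' @param eOverN optional per-cycle reduced field in Td.
#' @param provenance \code{"simulated"} or \code{"file"}.
#' @param metadata extra metadata entries (list).
#' @return a \code{\linkS4class{TraceSet}}.
#' @examples
#' ts <- TraceSet(matrix(1:6, 2, 3, byrow = TRUE) * 10.0,
#'   monitoredMz = c(21L, 63L))
#' cpsMatrix(ts)
#' @export
TraceSet <- function(cps, monitoredMz, cycles = NULL, cycleDuration = 1,
                     nominalMz = NULL, eOverN = NULL,
                     provenance = "simulated", metadata = list()) {
  cps <- as.matrix(cps)
  if (is.null(cycles)) cycles <- seq_len(ncol(cps)) - 1L
  if (is.null(nominalMz)) nominalMz <- monitoredMz
  stopifnot(length(monitoredMz) == nrow(cps), length(cycles) == ncol(cps))
  cd <- DataFrame(cycle = as.integer(cycles))
  if (!is.null(eOverN)) cd$e_over_n_td <- as.numeric(eOverN)
  rownames(cps) <- paste0("mz", monitoredMz)
  colnames(cps) <- NULL
  md <- c(list(cycle_duration = cycleDuration, provenance = provenance,
    transmission_corrected = FALSE, background_corrected = FALSE),
    metadata)
  se <- SummarizedExperiment(assays = list(cps = cps),
    rowData = DataFrame(monitored_mz = as.integer(monitoredMz),
      nominal_mz = as.integer(nominalMz)),
    colData = cd, metadata = md)
  new("TraceSet", se)
}

#' @describeIn TraceSet the cps matrix (rows = channels named
#'   \code{mz<int>}, columns = cycles).
#' @param x a \code{TraceSet}.
#' @export
cpsMatrix <- function(x) {
  stopifnot(is(x, "TraceSet"))
  assay(x, "cps")
}

#' @describeIn TraceSet one channel's trace as a numeric vector.
#' @param mz monitored m/z of the channel.
#' @export
getTrace <- function(x, mz) {
  stopifnot(is(x, "TraceSet"))
  i <- match(as.integer(mz), rowData(x)$monitored_mz)
  if (is.na(i)) stop("no channel at monitored m/z ", mz, call. = FALSE)
  assay(x, "cps")[i, ]
}

#' @describeIn TraceSet monitored m/z of all channels.
#' @export
monitoredMz <- function(x) {
  stopifnot(is(x, "TraceSet"))
  rowData(x)$monitored_mz
}

#' @describeIn TraceSet cycle indices.
#' @export
cycleIndex <- function(x) {
  stopifnot(is(x, "TraceSet"))
  colData(x)$cycle
}

#' @describeIn TraceSet per-cycle reduced field (Td), or NULL.
#' @export
eOverNPerCycle <- function(x) {
  stopifnot(is(x, "TraceSet"))
  if ("e_over_n_td" %in% names(colData(x))) colData(x)$e_over_n_td else NULL
}

#' @describeIn TraceSet cycle duration in seconds.
#' @export
cycleDuration <- function(x) {
  stopifnot(is(x, "TraceSet"))
  metadata(x)$cycle_duration
}

#' @export
setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet: %d channels x %d cycles (%s%s)\n",
    nrow(object), ncol(object), metadata(object)$provenance,
    if (isTRUE(metadata(object)$transmission_corrected))
      ", transmission-corrected" else ""))
  cat("  m/z:", paste(rowData(object)$monitored_mz, collapse = " "), "\n")
  if ("e_over_n_td" %in% names(colData(object)))
    cat("  E/N stepped:",
      paste(unique(colData(object)$e_over_n_td), collapse = " "), "Td\n")
})
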