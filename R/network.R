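## Drift-tube ion-molecule reaction networks.
##
## A network holds a species table (ions, neutrals, buffer) and a list of
## elementary reactions.  Every reaction carries exactly one charged species
## on each side, so total ion density is conserved by construction; element
## balance is enforced at build time whenever formulas are supplied.

.SPECIES_ROLES <- c("primary-ion", "parasitic-ion", "neutral", "product-ion",
  "fragment-ion", "adduct-ion", "buffer")

#' Drift-tube reaction network
#'
#' Built by \code{\link{buildNetwork}}; consumed by
#' \code{\link{simulateDrift}} and relatives.
#'
#' @slot species data frame: \code{name}, \code{mz} (integer, 0 for
#'   neutrals), \code{role}, \code{pa} (proton affinity, kJ/mol, NA when
#'   unknown), \code{formula} (string, NA when unknown), \code{ion}
#'   (logical).
#' @slot reactions list of validated reaction records.
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "list"),
  validity = function(object) {
    msg <- character()
    sp <- object@species
    need <- c("name", "mz", "role", "pa", "formula", "ion")
    if (!all(need %in% names(sp)))
      msg <- c(msg, "species table incomplete")
    else {
      if (anyDuplicated(sp$name)) msg <- c(msg, "duplicate species names")
      if (!all(sp$role %in% .SPECIES_ROLES))
        msg <- c(msg, "unknown species role")
      if (any(sp$ion & sp$mz < 1L))
        msg <- c(msg, "ions must have m/z >= 1")
      if (any(!is.na(sp$pa) & sp$pa <= 0))
        msg <- c(msg, "proton affinities must be positive")
    }
    if (length(msg)) msg else TRUE
  })

.ionRoles <- c("primary-ion", "parasitic-ion", "product-ion", "fragment-ion",
  "adduct-ion")

.countsOf <- function(fstr) {
  f <- chemFormula(fstr)
  full <- setNames(integer(length(.PIDK_ELEMENTS)), .PIDK_ELEMENTS)
  full[names(f@counts)] <- f@counts
  full
}

## one reaction record from config; rate units follow molecularity:
## cm3 s-1 (ion + 1 neutral), cm6 s-1 (ion + 2 neutrals), s-1 (unimolecular).
.normalizeReaction <- function(r, sp, idx) {
  need <- c("reactants", "products", "k")
  if (!all(need %in% names(r)))
    stop("reaction ", idx, ": needs reactants, products, k", call. = FALSE)
  reac <- unlist(r$reactants)
  prod <- unlist(r$products)
  if (is.null(names(reac)) || is.null(names(prod)))
    stop("reaction ", idx, ": reactants/products must be named counts",
      call. = FALSE)
  unknown <- setdiff(c(names(reac), names(prod)), sp$name)
  if (length(unknown))
    stop("reaction ", idx, ": unknown species ",
      paste(unknown, collapse = ", "), call. = FALSE)
  isIon <- setNames(sp$ion, sp$name)
  nIonR <- sum(reac[isIon[names(reac)]])
  nIonP <- sum(prod[isIon[names(prod)]])
  if (nIonR != 1L || nIonP != 1L)
    stop("reaction ", idx, " violates charge conservation: ",
      paste(names(reac), collapse = " + "), " -> ",
      paste(names(prod), collapse = " + "), call. = FALSE)
  ## element balance when every participant carries a formula
  fml <- setNames(sp$formula, sp$name)
  part <- c(names(reac), names(prod))
  if (!anyNA(fml[part])) {
    bal <- setNames(numeric(length(.PIDK_ELEMENTS)), .PIDK_ELEMENTS)
    for (s in names(reac)) bal <- bal + reac[[s]] * .countsOf(fml[[s]])
    for (s in names(prod)) bal <- bal - prod[[s]] * .countsOf(fml[[s]])
    if (any(bal != 0))
      stop("reaction ", idx, " violates element balance: ",
        paste(names(reac), collapse = " + "), " -> ",
        paste(names(prod), collapse = " + "), call. = FALSE)
  }
  list(
    reactants = reac, products = prod, k = as.numeric(r$k),
    branching = if (is.null(r$branching)) NA_real_ else as.numeric(r$branching),
    pa_gated = isTRUE(r$pa_gated),
    pa_donor = r$pa_donor, pa_acceptor = r$pa_acceptor,
    soft = isTRUE(r$soft), intact = isTRUE(r$intact),
    tag = if (is.null(r$tag)) NA_character_ else as.character(r$tag),
    active = TRUE)
}

#' Build and validate a reaction network
#'
#' Validation enforces charge conservation (exactly one ion on each side of
#' every reaction), element balance whenever all participating species have
#' formulas, branching fractions summing to 1 across channels that share
#' identical reactants, and proton-affinity gating: a \code{pa_gated}
#' reaction names a \code{pa_donor} and \code{pa_acceptor} species and is
#' active only when \eqn{\Delta PA = PA(acceptor) - PA(donor) \ge 0}.
#'
#' Supported templates: proton transfer, PA-gated secondary proton transfer,
#' charge transfer, effective termolecular adduct formation (second order in
#' the neutral), dehydrogenation branching at protonation, and reversible
#' cluster association/dissociation (the dissociation written as a
#' unimolecular ion reaction with rate in s\eqn{^{-1}}).
#'
#' @param config a list with elements \code{species} (list of records with
#'   \code{name}, \code{mz}, \code{role}, optional \code{pa},
#'   \code{formula}) and \code{reactions} (list of records with named
#'   \code{reactants} and \code{products} counts, \code{k}, optional
#'   \code{branching}, \code{pa_gated}/\code{pa_donor}/\code{pa_acceptor},
#'   \code{soft}, \code{intact}, \code{tag}), e.g. parsed from a YAML
#'   preset (see \code{\link{loadScenario}}).
#' @return a \code{\linkS4class{ReactionNetwork}}.
#' @export
buildNetwork <- function(config) {
  if (is.null(config$species) || !length(config$species))
    stop("config must define species", call. = FALSE)
  sp <- do.call(rbind, lapply(config$species, function(s) {
    data.frame(name = s$name, mz = as.integer(s$mz %||% 0L),
      role = s$role,
      pa = as.numeric(s$pa %||% NA_real_),
      formula = as.character(s$formula %||% NA_character_),
      stringsAsFactors = FALSE)
  }))
  sp$ion <- sp$role %in% .ionRoles
  rx <- lapply(seq_along(config$reactions), function(i)
    .normalizeReaction(config$reactions[[i]], sp, i))

  ## branching closure over channel groups (identical reactant multisets)
  key <- vapply(rx, function(r)
    paste(sort(paste0(names(r$reactants), ":", r$reactants)), collapse = "|"),
    "")
  for (g in unique(key)) {
    i <- which(key == g)
    br <- vapply(rx[i], function(r) r$branching, 0.0)
    if (length(i) > 1L || any(!is.na(br))) {
      if (anyNA(br))
        stop("channels sharing reactants must all carry branching: group ",
          g, call. = FALSE)
      if (length(i) > 1L && abs(sum(br) - 1) > 1e-9)
        stop("branching fractions do not sum to 1 for reactants ", g,
          call. = FALSE)
    }
    for (j in i) rx[[j]]$group <- g
  }
  ## PA gating
  pa <- setNames(sp$pa, sp$name)
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    if (r$pa_gated) {
      if (is.null(r$pa_donor) || is.null(r$pa_acceptor))
        stop("pa_gated reaction ", i, " must name pa_donor and pa_acceptor",
          call. = FALSE)
      if (is.na(pa[r$pa_donor]) || is.na(pa[r$pa_acceptor]))
        stop("pa_gated reaction ", i, ": missing proton affinity for ",
          r$pa_donor, " or ", r$pa_acceptor, call. = FALSE)
      rx[[i]]$active <- unname(pa[r$pa_acceptor] - pa[r$pa_donor]) >= 0
    }
  }
  new("ReactionNetwork", species = sp, reactions = rx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn buildNetwork species table of a network.
#' @param network a \code{ReactionNetwork}.
#' @export
networkSpecies <- function(network) {
  stopifnot(is(network, "ReactionNetwork"))
  network@species
}

#' @describeIn buildNetwork reaction list of a network.
#' @export
networkReactions <- function(network) {
  stopifnot(is(network, "ReactionNetwork"))
  network@reactions
}

#' @describeIn buildNetwork activate/deactivate reactions carrying a tag
#'   (used for mechanism switches, e.g. tag \code{"secondary"}).
#' @param tag reaction tag.
#' @param active logical.
#' @export
setReactionActive <- function(network, tag, active) {
  stopifnot(is(network, "ReactionNetwork"))
  hit <- FALSE
  for (i in seq_along(network@reactions)) {
    if (identical(network@reactions[[i]]$tag, tag)) {
      network@reactions[[i]]$active <- active
      hit <- TRUE
    }
  }
  if (!hit) warning("no reaction carries tag '", tag, "'")
  network
}

#' @export
setMethod("show", "ReactionNetwork", function(object) {
  sp <- object@species
  cat(sprintf("ReactionNetwork: %d species (%d ions), %d reactions\n",
    nrow(sp), sum(sp$ion), length(object@reactions)))
  for (r in object@reactions) {
    cat(sprintf("  %s -> %s  k=%.3g%s%s\n",
      paste(rep(names(r$reactants), r$reactants), collapse = " + "),
      paste(rep(names(r$products), r$products), collapse = " + "),
      r$k,
      if (!is.na(r$branching)) sprintf(" br=%.3g", r$branching) else "",
      if (!r$active) "  [inactive]" else ""))
  }
})
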