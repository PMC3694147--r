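## Independent oracles, deliberately implemented by different routes than
## the package code paths they check.

## Exhaustive isotopologue enumeration: for each element, enumerate all
## isotope compositions of its n atoms (multinomial weights via dmultinom),
## cross-combine elements, bin probability mass by integer mass shift.
oracle_isotope_pattern <- function(counts, table) {
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L, 1L))
    out <- NULL
    for (i in 0:n) {
      sub <- compositions(n - i, k - 1L)
      out <- rbind(out, cbind(i, sub))
    }
    out
  }
  dist <- c(`0` = 1.0)
  for (el in names(counts)) {
    if (counts[[el]] == 0L) next
    sub <- table[table$element == el, , drop = FALSE]
    sub <- sub[order(sub$isotope), , drop = FALSE]
    base <- sub$isotope[which.max(sub$abundance)]
    shifts <- sub$isotope - base
    comps <- compositions(counts[[el]], nrow(sub))
    edist <- numeric(max(shifts) * counts[[el]] + 1L)
    for (r in seq_len(nrow(comps))) {
      kvec <- comps[r, ]
      s <- sum(kvec * shifts)
      edist[s + 1L] <- edist[s + 1L] +
        dmultinom(kvec, prob = sub$abundance)
    }
    newdist <- numeric(length(dist) + length(edist) - 1L)
    for (i in seq_along(dist))
      for (j in seq_along(edist))
        newdist[i + j - 1L] <- newdist[i + j - 1L] + dist[i] * edist[j]
    dist <- newdist
  }
  100 * dist / dist[1L]
}

## Brute-force composition search: plain nested loops.
oracle_candidate_formulas <- function(mass, bounds) {
  hits <- character()
  for (C in bounds$C[1]:bounds$C[2])
    for (H in bounds$H[1]:bounds$H[2])
      for (S in bounds$S[1]:bounds$S[2])
        for (O in bounds$O[1]:bounds$O[2])
          for (N in bounds$N[1]:bounds$N[2]) {
            if (C + H + S + O + N == 0) next
            if (12 * C + H + 32 * S + 16 * O + 14 * N == mass)
              hits <- c(hits, sprintf("C%d.H%d.S%d.O%d.N%d", C, H, S, O, N))
          }
  sort(hits)
}

formula_key <- function(f) {
  cc <- elementCounts(f)
  n <- function(e) if (e %in% names(cc)) cc[[e]] else 0L
  sprintf("C%d.H%d.S%d.O%d.N%d", n("C"), n("H"), n("S"), n("O"), n("N"))
}

## Independent fixed-step RK4 integrator over a plain reaction list
## (named reactant/product counts, rate k; neutrals held constant).
oracle_rk4_drift <- function(reactions, ions, neutrals, tr, steps = 1000L) {
  rate_of <- function(y) {
    dy <- setNames(numeric(length(y)), names(y))
    for (r in reactions) {
      flux <- r$k
      for (nm in names(r$reactants)) {
        v <- if (nm %in% names(y)) y[[nm]] else neutrals[[nm]]
        flux <- flux * v^r$reactants[[nm]]
      }
      for (nm in names(r$reactants))
        if (nm %in% names(y)) dy[[nm]] <- dy[[nm]] - flux * r$reactants[[nm]]
      for (nm in names(r$products))
        if (nm %in% names(y)) dy[[nm]] <- dy[[nm]] + flux * r$products[[nm]]
    }
    dy
  }
  y <- ions
  h <- tr / steps
  for (s in seq_len(steps)) {
    k1 <- rate_of(y)
    k2 <- rate_of(y + h / 2 * k1)
    k3 <- rate_of(y + h / 2 * k2)
    k4 <- rate_of(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

## Minimal one-reaction protonation network (Eq-1 style).
minimal_network <- function(k = 2e-9) {
  buildNetwork(list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion", pa = 691,
        formula = "H3O"),
      list(name = "M", mz = 0, role = "neutral", pa = 830.9,
        formula = "C2H6S"),
      list(name = "MH+", mz = 63, role = "product-ion", formula = "C2H7S"),
      list(name = "H2O", mz = 0, role = "neutral", pa = 691,
        formula = "H2O")),
    reactions = list(list(reactants = c("H3O+" = 1, "M" = 1),
      products = c("MH+" = 1, "H2O" = 1), k = k))))
}

## Protonation with an intact/fragment branching pair, for the spatial
## soft-ionization checks.
branched_network <- function(k = 2e-9, beta = 0.1) {
  buildNetwork(list(
    species = list(
      list(name = "H3O+", mz = 19, role = "primary-ion"),
      list(name = "M", mz = 0, role = "neutral"),
      list(name = "MH+", mz = 63, role = "product-ion"),
      list(name = "FH+", mz = 47, role = "fragment-ion"),
      list(name = "H2O", mz = 0, role = "neutral")),
    reactions = list(
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("MH+" = 1, "H2O" = 1), k = k, branching = 1 - beta,
        intact = TRUE),
      list(reactants = c("H3O+" = 1, "M" = 1),
        products = c("FH+" = 1, "H2O" = 1), k = k, branching = beta,
        soft = TRUE))))
}

## DMS scenario with the isotopologue family channels clean (no overlap
## background) and an optional quadratic analyte drain on the parent ion.
dms_family_scenario <- function(drain = FALSE) {
  sc <- loadScenario("dms")
  sc$overlaps <- list()
  if (drain) {
    sc$species <- c(sc$species, list(list(name = "MMH+", mz = 125,
      role = "adduct-ion", formula = "C4H13S2")))
    sc$reactions <- c(sc$reactions, list(list(
      reactants = c("MH+" = 1, "M" = 2),
      products = c("MMH+" = 1, "M" = 1), k = 2.0e-26, tag = "drain")))
  }
  sc
}
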