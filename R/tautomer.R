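# Tautomer canonicalisation.
#
# All tautomers reachable by symmetric 1,3 proton shifts
# (H-X-Y=Z  <->  X=Y-Z-H, with X and Z drawn from C/N/O/S) are enumerated
# by breadth-first closure over the molecular graph, and one representative
# is selected by a deterministic stability score with a canonical-SMILES
# tie-break. Because the move set is its own inverse, the reachable set is
# an equivalence class: every member enumerates the same class and maps to
# the same representative, which makes the operation idempotent.
#
# Bonds of all-carbon aromatic rings (benzene-like) are frozen during
# enumeration: shifts there only manufacture unstable quinoid forms and
# blow up the closure on fused ring systems. Heteroaromatic and
# hetero-substituted rings (pyridones, the pyranone ring of warfarin, ...)
# do take part, and the representative is chosen aromaticity-first so an
# aromatic form is never traded for a non-aromatic one. Hydrogens are
# implicit throughout, so a shift is just a pair of bond-order changes
# (the valence model restores the hydrogen counts).

taut_shift_atoms <- c("C", "N", "O", "S")

# Stability score of a Kekule graph: prefer oxo/thioxo over enol forms,
# then imines over enamines, then C=C.
taut_score <- function(elements, bonds) {
  if (!nrow(bonds)) return(0)
  d <- bonds[bonds$order == 2L, , drop = FALSE]
  if (!nrow(d)) return(0)
  s <- 0
  for (k in seq_len(nrow(d))) {
    pair <- sort(c(elements[d$i[k]], elements[d$j[k]]))
    key <- paste(pair, collapse = "-")
    s <- s + switch(key,
                    "C-O" = 4, "C-S" = 4, "O-P" = 3, "O-S" = 3, "N-O" = 3,
                    "C-N" = 2, "C-C" = 1, 0)
  }
  s
}

# Smallest standard valence >= bond-order sum, adjusted for formal charge.
taut_valence <- function(el, chg) {
  base <- switch(el,
                 H = 1L, C = 4L, N = 3L, O = 2L, F = 1L,
                 P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L,
                 NA_integer_)
  if (anyNA(base)) return(NA_integer_)
  if (el %in% c("N", "O")) base <- base + chg
  base
}

taut_implicit_h <- function(elements, bonds, charges) {
  n <- length(elements)
  bsum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + bonds$order[k]
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + bonds$order[k]
    }
  }
  vapply(seq_len(n), function(a) {
    v <- taut_valence(elements[a], charges[a])
    if (anyNA(v)) return(0L)
    v <- v[v >= bsum[a]]
    if (!length(v)) return(0L)
    as.integer(min(v) - bsum[a])
  }, 0L)
}

# Enumerate single 1,3-shift neighbours of a graph state.
taut_moves <- function(state) {
  elements <- state$elements
  bonds <- state$bonds
  frozen <- state$frozen
  nb <- state$nH
  out <- list()
  nbonds <- nrow(bonds)
  if (!nbonds) return(out)
  # index bonds by shared atom
  for (b1 in seq_len(nbonds)) {
    if (bonds$order[b1] != 1L || frozen[b1]) next
    for (b2 in seq_len(nbonds)) {
      if (b2 == b1 || bonds$order[b2] != 2L || frozen[b2]) next
      common <- intersect(c(bonds$i[b1], bonds$j[b1]),
                          c(bonds$i[b2], bonds$j[b2]))
      if (length(common) != 1L) next
      y <- common
      x <- setdiff(c(bonds$i[b1], bonds$j[b1]), y)
      z <- setdiff(c(bonds$i[b2], bonds$j[b2]), y)
      if (x == z) next
      if (!(elements[x] %in% taut_shift_atoms)) next
      if (!(elements[z] %in% taut_shift_atoms)) next
      if (state$charges[x] != 0L || state$charges[z] != 0L) next
      if (nb[x] < 1L) next
      nbnd <- bonds
      nbnd$order[b1] <- 2L
      nbnd$order[b2] <- 1L
      ns <- state
      ns$bonds <- nbnd
      ns$nH <- taut_implicit_h(elements, nbnd, state$charges)
      out[[length(out) + 1L]] <- ns
    }
  }
  out
}

taut_state_key <- function(state) {
  paste(state$bonds$order, collapse = ",")
}

taut_state_smiles <- function(state) {
  mb <- write_molblock(state$elements, state$bonds, state$charges)
  out <- ob_convert("SDF", "CAN", mb)
  smi <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(smi)) NA_character_ else smi
}

#' Canonicalise the tautomeric form of a molecule
#'
#' Enumerates tautomers reachable by 1,3 proton shifts between C, N, O and
#' S atoms and returns a single canonical representative, so that all
#' tautomers of the same compound (keto/enol, amide/imidol, ...) map to one
#' identical SMILES. The representative maximises a deterministic stability
#' score (oxo forms preferred over enols, imines over enamines), with ties
#' broken by the lexicographically smallest canonical SMILES. Aromatic
#' bonds are left untouched.
#'
#' @param smiles SMILES of a single-fragment, normalised molecule.
#' @param max_tautomers Enumeration cap; the closure is abandoned (the
#'   input's canonical form is returned) if the class is larger.
#' @return Canonical SMILES of the representative tautomer.
#' @export
canonicalize_tautomer <- function(smiles, max_tautomers = 512L) {
  can0 <- ob_canonical(smiles)
  if (is.na(can0)) stop("canonicalize_tautomer() requires a parseable SMILES")
  sdf <- ob_convert("SMI", "SDF", can0)
  if (!nzchar(sdf)) return(can0)
  mb <- parse_molblock(split_sdf(sdf)[[1]])
  if (mb$n_atoms == 0L || !nrow(mb$bonds)) return(can0)

  m2 <- ob_convert("SMI", "MOL2", can0)
  frozen <- rep(FALSE, nrow(mb$bonds))
  if (nzchar(m2)) {
    ar <- parse_mol2(m2)$bonds
    ar <- ar[ar$type == "ar", , drop = FALSE]
    # freeze only carbon-carbon aromatic bonds
    ar <- ar[mb$elements[ar$i] == "C" & mb$elements[ar$j] == "C", , drop = FALSE]
    if (nrow(ar)) {
      key <- function(i, j) paste(pmin(i, j), pmax(i, j))
      frozen <- key(mb$bonds$i, mb$bonds$j) %in% key(ar$i, ar$j)
    }
  }

  elements <- mb$elements
  charges <- mb$charges
  start <- list(elements = elements, charges = charges, bonds = mb$bonds,
                frozen = frozen,
                nH = taut_implicit_h(elements, mb$bonds, charges))

  seen <- new.env(parent = emptyenv())
  assign(taut_state_key(start), TRUE, envir = seen)
  queue <- list(start)
  states <- list(start)
  while (length(queue)) {
    st <- queue[[1]]
    queue <- queue[-1]
    for (nxt in taut_moves(st)) {
      k <- taut_state_key(nxt)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        states[[length(states) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
        if (length(states) > max_tautomers) return(can0)
      }
    }
  }
  if (length(states) == 1L) return(can0)

  smis <- vapply(states, taut_state_smiles, "")
  ok <- !is.na(smis) & nzchar(smis)
  if (!any(ok)) return(can0)
  states <- states[ok]
  smis <- smis[ok]
  arom <- vapply(smis, count_aromatic_atoms, 0L, USE.NAMES = FALSE)
  scores <- vapply(states, function(s) taut_score(s$elements, s$bonds), 0)
  ord <- order(-arom, -scores, smis)
  smis[ord[1]]
}

# Number of aromatic atoms in a SMILES string (lowercase atom symbols,
# after masking the two-letter halogens whose second letter is lowercase).
count_aromatic_atoms <- function(smiles) {
  s <- gsub("Cl|Br", "", smiles)
  lengths(regmatches(s, gregexpr("[cnosp]", s)))
}
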