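# Thin wrappers around the OpenBabel toolkit (via ChemmineOB) and the
# obenergy CLI. Everything chemistry-perception related is delegated here;
# the rest of the package consumes the plain R structures these return.

ob_ops <- function(...) {
  v <- c(...)
  if (length(v) == 0L) return(data.frame(names = character(), args = character()))
  data.frame(names = names(v), args = unname(v), stringsAsFactors = FALSE)
}

# Convert between formats with OpenBabel transformation ops.
# `ops` is a named character vector, e.g. c(gen3D = "med", h = "").
# Returns the output text; "" signals a conversion failure.
ob_convert <- function(from, to, source, ops = NULL) {
  opts <- if (is.null(ops)) ob_ops() else ob_ops(ops)
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source, options = opts),
    error = function(e) ""
  )
  if (length(out) != 1L || is.na(out)) "" else out
}

# Canonical SMILES, or NA_character_ on parse failure.
ob_canonical <- function(smiles, ops = NULL) {
  out <- ob_convert("SMI", "CAN", smiles, ops)
  smi <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(smi)) NA_character_ else smi
}

is_valid_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(FALSE)
  }
  !is.na(ob_canonical(smiles))
}

split_sdf <- function(text) {
  if (!nzchar(text)) return(character())
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  recs
}

# Parse a single V2000 molblock into atoms/bonds tables.
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  # skip leading blank lines left by record splitting
  while (length(lines) && !nzchar(trimws(lines[1])) &&
         length(lines) > 4L && !grepl("V2000", lines[4])) {
    lines <- lines[-1]
  }
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms)) stop("malformed molblock counts line")
  title <- trimws(lines[1])

  coords <- matrix(NA_real_, n_atoms, 3)
  elements <- character(n_atoms)
  if (n_atoms > 0) {
    at <- lines[5:(4 + n_atoms)]
    coords[, 1] <- as.numeric(substr(at, 1, 10))
    coords[, 2] <- as.numeric(substr(at, 11, 20))
    coords[, 3] <- as.numeric(substr(at, 21, 30))
    elements <- trimws(substr(at, 32, 34))
  }
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  charges <- integer(n_atoms)
  radicals <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) charges[f[2 * k]] <- f[2 * k + 1]
  }
  for (ln in grep("^M  RAD", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  RAD", "", ln)), "[ ]+")[[1]])
    n <- f[1]
    # MDL spin codes: 1 singlet, 2 doublet (1 unpaired e-), 3 triplet (2)
    for (k in seq_len(n)) {
      radicals[f[2 * k]] <- c(0L, 1L, 2L)[f[2 * k + 1] + 1L][1]
    }
  }
  list(title = title, n_atoms = n_atoms, elements = elements, coords = coords,
       charges = charges, radicals = radicals, bonds = bonds)
}

# Write atoms/bonds back to a 0D molblock OpenBabel can re-read.
write_molblock <- function(elements, bonds, charges = NULL, title = "") {
  n <- length(elements)
  charges <- if (is.null(charges)) integer(n) else charges
  hdr <- c(title, "  molgraphnn", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, elements)
  bd <- if (nrow(bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j, bonds$order)
  } else character()
  chg <- character()
  idx <- which(charges != 0L)
  if (length(idx)) {
    chg <- vapply(idx, function(a) {
      sprintf("M  CHG  1 %3d %3d", a, charges[a])
    }, "")
  }
  paste(c(hdr, at, bd, chg, "M  END", ""), collapse = "\n")
}

# Parse a MOL2 block: SYBYL atom types, partial charges, bond types.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  b0 <- grep("^@<TRIPOS>BOND", lines)[1]
  stopifnot(!is.na(a0), !is.na(b0))
  ends <- grep("^@<TRIPOS>", lines)
  a1 <- min(c(ends[ends > a0], length(lines) + 1L)) - 1L
  b1 <- min(c(ends[ends > b0], length(lines) + 1L)) - 1L
  atom_lines <- lines[(a0 + 1L):a1]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[ \t]+")
  bond_lines <- lines[(b0 + 1L):b1]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  bf <- strsplit(trimws(bond_lines), "[ \t]+")
  list(
    sybyl = vapply(af, function(x) x[6], ""),
    charge = vapply(af, function(x) as.numeric(x[9]), 0),
    bonds = data.frame(
      i = vapply(bf, function(x) as.integer(x[2]), 0L),
      j = vapply(bf, function(x) as.integer(x[3]), 0L),
      type = vapply(bf, function(x) x[4], "")
    )
  )
}

# MMFF94 energies (kcal/mol) for every record of an SDF text, via obenergy.
ob_mmff_energy <- function(sdf_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  out <- suppressWarnings(
    system2("obenergy", c("-ff", "MMFF94", tf), stdout = TRUE, stderr = FALSE)
  )
  en <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (!length(en)) return(numeric())
  as.numeric(sub("^TOTAL ENERGY *= *([-0-9.eE+]+).*$", "\\1", en))
}

elements_of <- function(smiles) {
  sdf <- ob_convert("SMI", "SDF", smiles)
  if (!nzchar(sdf)) return(NULL)
  mb <- parse_molblock(split_sdf(sdf)[[1]])
  # bracket-atom hydrogens count too, and implicit hydrogens are always H
  unique(c(mb$elements, if (grepl("H", smiles, fixed = TRUE)) "H" else NULL))
}

heavy_atom_count <- function(smiles) {
  sdf <- ob_convert("SMI", "SDF", smiles)
  if (!nzchar(sdf)) return(NA_integer_)
  mb <- parse_molblock(split_sdf(sdf)[[1]])
  sum(mb$elements != "H")
}
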