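# 3D conformer generation, MMFF94 optimisation, bond-length measurement and
# the bond-length-change statistics. Embedding and minimisation are
# delegated to OpenBabel; this module owns the retry policy, validity
# checks, failure records, measurement and statistics.

#' Embed a 3D conformer
#'
#' Adds explicit hydrogens and generates one 3D conformation of the
#' molecule using the toolkit's 3D builder. The result is validity-checked
#' (finite coordinates, every bonded pair at 0.7 to 2.5 Angstrom) and the
#' builder is re-invoked until a valid geometry is produced or
#' `max_attempts` is exhausted, in which case a failure record
#' (`embedded = FALSE`) is returned rather than an error.
#'
#' The builder's internal random stream is time-seeded by the toolkit and
#' cannot be fixed through its API; `seed` is recorded in the result for
#' provenance, and reproducibility of downstream features rests on the
#' force-field minimisation, which drives bond lengths to the same minima
#' regardless of the starting geometry (see the methods vignette).
#'
#' @param smiles Standardised SMILES string.
#' @param max_attempts Maximum number of embedding attempts (default 5000).
#' @param seed Integer recorded in the result metadata.
#' @param method `"med"` (rule-based builder with force-field clean-up,
#'   default) or `"dist"` (distance geometry).
#' @return An object of class `conformer3d`: list with `atom_elements`,
#'   `coords` (n x 3, Angstrom), `bonds` (data frame i, j, order),
#'   `attempts_used`, `embedded`, `seed`, `sdf` (the molblock text).
#' @export
embed_conformer <- function(smiles, max_attempts = 5000L, seed = NULL,
                            method = c("med", "dist")) {
  method <- match.arg(method)
  fail <- function(attempts) {
    structure(list(atom_elements = character(), coords = matrix(0, 0, 3),
                   bonds = data.frame(i = integer(), j = integer(),
                                      order = integer()),
                   attempts_used = attempts, embedded = FALSE, seed = seed,
                   sdf = ""),
              class = "conformer3d")
  }
  if (!is_valid_smiles(smiles)) return(fail(0L))
  for (attempt in seq_len(max_attempts)) {
    sdf <- ob_convert("SMI", "SDF", smiles, c(h = "", gen3D = method))
    if (!nzchar(sdf)) next
    mb <- tryCatch(parse_molblock(split_sdf(sdf)[[1]]), error = function(e) NULL)
    if (is.null(mb) || mb$n_atoms == 0L) next
    if (conformer_geometry_valid(mb)) {
      return(structure(list(atom_elements = mb$elements, coords = mb$coords,
                            bonds = mb$bonds, attempts_used = attempt,
                            embedded = TRUE, seed = seed, sdf = sdf),
                       class = "conformer3d"))
    }
  }
  fail(max_attempts)
}

conformer_geometry_valid <- function(mb, lower = 0.7, upper = 2.5) {
  if (!all(is.finite(mb$coords))) return(FALSE)
  if (mb$n_atoms > 1L && all(abs(mb$coords) < 1e-8)) return(FALSE)
  if (!nrow(mb$bonds)) return(TRUE)
  d <- bond_distances(mb$coords, as.matrix(mb$bonds[, c("i", "j")]))
  all(d >= lower & d <= upper)
}

bond_distances <- function(coords, pairs) {
  if (!nrow(pairs)) return(numeric())
  dv <- coords[pairs[, 1], , drop = FALSE] - coords[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(dv * dv))
}

#' Minimise a conformer with the MMFF94 force field
#'
#' Relaxes an embedded conformer by force-field energy minimisation and
#' reports the total MMFF94 energy (kcal/mol) before and after. A missing
#' force-field parameterisation yields a failure record
#' (`converged = FALSE`, `NA` energies), not an error.
#'
#' @param conformer A `conformer3d` with `embedded = TRUE`.
#' @param steps Maximum minimiser iterations.
#' @param crit Energy convergence criterion.
#' @return An object of class `optimized_conformer`: list with `coords`,
#'   `converged`, `energy_before`, `energy_after`, `atom_elements`,
#'   `bonds`, `sdf`.
#' @export
mmff_optimize <- function(conformer, steps = 2000L, crit = 1e-6) {
  stopifnot(inherits(conformer, "conformer3d"))
  if (!conformer$embedded) stop("mmff_optimize() requires an embedded conformer")
  fail <- function() {
    structure(list(coords = conformer$coords, converged = FALSE,
                   energy_before = NA_real_, energy_after = NA_real_,
                   atom_elements = conformer$atom_elements,
                   bonds = conformer$bonds, sdf = conformer$sdf),
              class = "optimized_conformer")
  }
  opt <- ob_convert("SDF", "SDF", conformer$sdf,
                    c(minimize = "", ff = "MMFF94",
                      steps = as.character(steps), crit = format(crit)))
  if (!nzchar(opt)) return(fail())
  mb <- tryCatch(parse_molblock(split_sdf(opt)[[1]]), error = function(e) NULL)
  if (is.null(mb) || mb$n_atoms != length(conformer$atom_elements)) return(fail())
  e0 <- ob_mmff_energy(conformer$sdf)
  e1 <- ob_mmff_energy(opt)
  if (length(e0) != 1L || length(e1) != 1L) return(fail())
  structure(list(coords = mb$coords,
                 converged = is.finite(e1) && e1 <= e0 + 1e-6,
                 energy_before = e0, energy_after = e1,
                 atom_elements = conformer$atom_elements,
                 bonds = conformer$bonds, sdf = opt),
            class = "optimized_conformer")
}

#' Measure bond lengths in a conformer
#'
#' Euclidean distances, in Angstrom, between the 3D coordinates of the two
#' endpoint atoms of each requested bond.
#'
#' @param conformer A `conformer3d` or `optimized_conformer`.
#' @param bonds Two-column matrix (or data frame) of 1-based atom indices;
#'   defaults to every bond of the molecule.
#' @return Numeric vector of lengths, one per row of `bonds`.
#' @export
measure_bond_lengths <- function(conformer, bonds = NULL) {
  coords <- conformer$coords
  if (is.null(bonds)) bonds <- conformer$bonds[, c("i", "j")]
  bonds <- as.matrix(bonds)
  if (nrow(bonds) && (max(bonds) > nrow(coords) || min(bonds) < 1L)) {
    stop("bond atom index out of range")
  }
  bond_distances(coords, bonds)
}

#' Bond-length change statistics
#'
#' Per-bond absolute percent change `100 * |after - before| / before`
#' between two positionally matched length vectors, summarised by mean,
#' median, standard deviation and range.
#'
#' @param before,after Equal-length numeric vectors of bond lengths
#'   (Angstrom); `before` must be strictly positive.
#' @return List of class `bond_change_stats` with `per_bond_change`,
#'   `mean`, `median`, `std`, `min`, `max` (all in percent).
#' @export
bond_change_statistics <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 1L)
  if (any(before <= 0)) stop("bond lengths before optimisation must be positive")
  pct <- 100 * abs(after - before) / before
  structure(list(per_bond_change = pct,
                 mean = mean(pct), median = stats::median(pct),
                 std = if (length(pct) > 1L) stats::sd(pct) else 0,
                 min = min(pct), max = max(pct)),
            class = "bond_change_stats")
}

#' Paired t-test
#'
#' Two-sided paired t-test on positionally matched samples:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y`, and the p-value from
#' the Student-t distribution with `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `length >= 2`.
#' @return List with `t_stat`, `p_value`, `n_pairs`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: t statistic undefined")
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       n_pairs = n)
}

# Batch embed + optimise a vector of standardised SMILES. One toolkit call
# embeds all molecules, another minimises them; failures fall back to the
# per-molecule path. Returns a list of per-molecule records.
embed_and_optimize <- function(smiles, ids = NULL, method = "med",
                               steps = 2000L, crit = 1e-6) {
  n <- length(smiles)
  if (is.null(ids)) ids <- sprintf("m%04d", seq_len(n))
  src <- paste(paste(smiles, ids), collapse = "\n")
  sdf_all <- ob_convert("SMI", "SDF", src, c(h = "", gen3D = method))
  blocks <- split_sdf(sdf_all)
  titles <- vapply(blocks, function(b) {
    trimws(strsplit(b, "\n", fixed = TRUE)[[1]][1])
  }, "")
  out <- vector("list", n)
  names(out) <- ids
  for (k in seq_len(n)) {
    hit <- which(titles == ids[k])
    conf <- NULL
    if (length(hit) == 1L) {
      mb <- tryCatch(parse_molblock(blocks[[hit]]), error = function(e) NULL)
      if (!is.null(mb) && mb$n_atoms > 0L && conformer_geometry_valid(mb)) {
        conf <- structure(list(atom_elements = mb$elements, coords = mb$coords,
                               bonds = mb$bonds, attempts_used = 1L,
                               embedded = TRUE, seed = NULL,
                               sdf = paste0(blocks[[hit]], "$$$$\n")),
                          class = "conformer3d")
      }
    }
    if (is.null(conf)) {
      conf <- embed_conformer(smiles[k], max_attempts = 25L, method = method)
    }
    opt <- if (conf$embedded) mmff_optimize(conf, steps = steps, crit = crit)
           else NULL
    out[[k]] <- list(id = ids[k], smiles = smiles[k], conformer = conf,
                     optimized = opt)
  }
  out
}

#' Bond-length change report for a set of molecules
#'
#' Embeds and MMFF94-minimises each molecule, measures every bond before
#' and after minimisation and tabulates the per-bond percent changes.
#'
#' @param smiles Character vector of standardised SMILES.
#' @param ids Optional molecule identifiers.
#' @return List with `table` (data frame molecule_id, bond_index, atom_i,
#'   atom_j, length_before, length_after, pct_change), `stats` (a
#'   [bond_change_statistics()] summary over all bonds) and `failed`
#'   (identifiers of molecules that did not embed or optimise).
#' @export
bond_change_report <- function(smiles, ids = NULL) {
  res <- embed_and_optimize(smiles, ids)
  rows <- list()
  failed <- character()
  for (r in res) {
    if (is.null(r$optimized) || !r$optimized$converged) {
      failed <- c(failed, r$id)
      next
    }
    pairs <- as.matrix(r$conformer$bonds[, c("i", "j")])
    if (!nrow(pairs)) next
    b <- measure_bond_lengths(r$conformer, pairs)
    a <- measure_bond_lengths(r$optimized, pairs)
    rows[[length(rows) + 1L]] <-
      data.frame(molecule_id = r$id, bond_index = seq_len(nrow(pairs)),
                 atom_i = pairs[, 1], atom_j = pairs[, 2],
                 length_before = b, length_after = a,
                 pct_change = 100 * abs(a - b) / b)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(), bond_index = integer(),
               atom_i = integer(), atom_j = integer(),
               length_before = numeric(), length_after = numeric(),
               pct_change = numeric())
  stats <- if (nrow(tab)) {
    bond_change_statistics(tab$length_before, tab$length_after)
  } else {
    NULL
  }
  list(table = tab, stats = stats, failed = failed)
}
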