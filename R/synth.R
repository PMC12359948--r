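# Bundled toy molecule library and the synthetic labelled-dataset
# generator. Molecules are assembled from fragment templates over the ten
# allowed elements, which guarantees chemical validity without a filter
# loop; every template has been checked to parse, embed and minimise.

#' Toy compound library
#'
#' A fixed, curated list of about thirty compound records covering the
#' behaviours the standardisation pipeline must handle: common drugs
#' (aspirin, warfarin in two tautomeric forms, caffeine, ibuprofen),
#' simple organics, a zwitterion, multi-fragment salts, a quaternary
#' ammonium ion, one unparseable string, and arsenic- and boron-containing
#' records that must be rejected at element screening. Labels are
#' balanced and arbitrary.
#'
#' @return Data frame with columns `compound_id`, `name`, `smiles`,
#'   `label`.
#' @export
toy_library <- function() {
  rec <- function(name, smiles, label) {
    data.frame(name = name, smiles = smiles, label = label,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    rec("aspirin", "CC(=O)Oc1ccccc1C(=O)O", 0L),
    rec("warfarin_enol", "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O", 1L),
    rec("warfarin_keto", "CC(=O)CC(c1ccccc1)C1C(=O)c2ccccc2OC1=O", 1L),
    rec("benzene", "c1ccccc1", 0L),
    rec("ethanol", "CCO", 0L),
    rec("glycine_zwitterion", "[NH3+]CC(=O)[O-]", 1L),
    rec("acetone", "CC(C)=O", 0L),
    rec("propen_2_ol", "CC(O)=C", 0L),
    rec("paracetamol", "CC(=O)Nc1ccc(O)cc1", 1L),
    rec("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", 0L),
    rec("ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", 1L),
    rec("sodium_acetate", "CC(=O)[O-].[Na+]", 0L),
    rec("ethylamine_hydrochloride", "CCN.Cl", 1L),
    rec("para_nitrophenol", "O=[N+]([O-])c1ccc(O)cc1", 1L),
    rec("unparseable", "C1CC", 0L),
    rec("arsenous_acid", "O[As](O)O", 0L),
    rec("phenylboronic_acid", "OB(O)c1ccccc1", 1L),
    rec("phenol", "Oc1ccccc1", 0L),
    rec("pyridine", "c1ccncc1", 1L),
    rec("imidazole", "c1c[nH]cn1", 0L),
    rec("ethanolamine", "NCCO", 1L),
    rec("trifluoroacetic_acid", "OC(=O)C(F)(F)F", 0L),
    rec("chlorobenzene", "Clc1ccccc1", 1L),
    rec("bromoethane", "CCBr", 0L),
    rec("iodomethane", "CI", 1L),
    rec("thiophene", "c1ccsc1", 0L),
    rec("dimethyl_phosphate", "COP(=O)(O)OC", 1L),
    rec("citric_acid", "OC(=O)CC(O)(CC(=O)O)C(=O)O", 0L),
    rec("benzamidine", "NC(=N)c1ccccc1", 1L),
    rec("tetramethylammonium_chloride", "C[N+](C)(C)C.[Cl-]", 0L)
  )
  df$compound_id <- df$name
  df[, c("compound_id", "name", "smiles", "label")]
}

#' Synthetic dataset specification
#'
#' @param n_molecules Number of records to generate (`>= 20`).
#' @param signal `"substructure"` (planted nitro group) or
#'   `"charge_threshold"` (label carried by the maximum Gasteiger partial
#'   charge relative to a per-template threshold, planted via isomeric
#'   template pairs that share atom and bond-type composition).
#' @param pattern Substituent SMILES planted in positives of the
#'   substructure signal (default the nitro group).
#' @param label_noise Probability that a label is flipped, in \[0, 0.5).
#' @param class_balance Target positive fraction.
#' @param seed RNG seed; generation is reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 300L,
                           signal = c("substructure", "charge_threshold"),
                           pattern = "[N+](=O)[O-]",
                           label_noise = 0.05, class_balance = 0.5,
                           seed = 1L) {
  signal <- match.arg(signal)
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 20L) stop("n_molecules must be >= 20")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)")
  }
  if (class_balance <= 0.1 || class_balance >= 0.9) {
    stop("class_balance must be in (0.1, 0.9)")
  }
  structure(list(n_molecules = n_molecules, signal = signal,
                 pattern = pattern, label_noise = label_noise,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_scaffolds <- function() {
  # sprintf patterns with two slots: decoration then signal group
  c("c1cc(%s)ccc1%s",
    "CC(%s)CCC%s",
    "C1CCC(%s)CC1%s",
    "O=C(%s)Nc1ccc(%s)cc1",
    "CC(C)(%s)CC%s")
}

synth_decorations <- function() {
  c("C", "CC", "CCC", "F", "Cl", "Br", "O", "N", "OC", "CO")
}

synth_negative_groups <- function() {
  c("C", "O", "N", "CO", "C(C)C", "OC")
}

# Isomeric template pairs for the charge-threshold signal. Within a family
# the two members share elemental composition and bond-type multiset; the
# "near" member places the halogen adjacent to the polar anchor, raising
# the maximum Gasteiger charge above the family threshold tau (midpoint of
# the two members' statistics).
charge_templates <- function() {
  data.frame(
    family = c("fluoro_acid", "chloro_amide", "fluoro_alcohol"),
    near = c("OC(=O)C(F)CC%s", "NC(=O)C(Cl)C%s", "OCC(F)CC%s"),
    far = c("OC(=O)CC%sCF", "NC(=O)C%sCCl", "OCCC%sCF"),
    tau = c(0.381, 0.268, 0.205),
    stringsAsFactors = FALSE
  )
}

#' Maximum Gasteiger partial charge of a molecule
#'
#' The per-molecule statistic used by the charge-threshold synthetic
#' signal.
#'
#' @param smiles SMILES string.
#' @return Maximum atomic Gasteiger charge, or `NA` on failure.
#' @export
molecule_charge_stat <- function(smiles) {
  m2 <- ob_convert("SMI", "MOL2", smiles, c(partialcharge = "gasteiger"))
  if (!nzchar(m2)) return(NA_real_)
  ch <- parse_mol2(m2)$charge
  ch <- ch[is.finite(ch)]
  if (!length(ch)) NA_real_ else max(ch)
}

#' Generate a synthetic labelled molecule dataset
#'
#' Assembles drug-like SMILES from fragment templates over the ten allowed
#' elements. In `substructure` mode, positives carry the planted pattern
#' (a nitro group by default) on a random scaffold and negatives carry a
#' benign group instead; the label is the signal value XOR a noise flip.
#' In `charge_threshold` mode, molecules are drawn from isomeric template
#' pairs; the signal is whether the maximum Gasteiger partial charge
#' exceeds the family threshold, so the classes are separable in
#' custom-feature space (which carries the charge) while sharing atom and
#' bond-type composition.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame of compound records (`compound_id`, `name`,
#'   `smiles`, `label`) with attribute `"signal"` holding the noise-free
#'   signal values.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_molecules
  n_pos <- round(n * spec$class_balance)
  want_pos <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))

  if (spec$signal == "substructure") {
    sc <- synth_scaffolds()
    dec <- synth_decorations()
    neg <- synth_negative_groups()
    smiles <- character(n)
    signal <- logical(n)
    for (i in seq_len(n)) {
      s <- sample(sc, 1)
      d <- sample(dec, 1)
      g <- if (want_pos[i]) spec$pattern else sample(neg, 1)
      smiles[i] <- sprintf(s, d, g)
      signal[i] <- want_pos[i]
    }
  } else {
    tmpl <- charge_templates()
    ext <- c("", "C", "CC", "CCC")  # chain extension shared by both members
    smiles <- character(n)
    signal <- logical(n)
    for (i in seq_len(n)) {
      f <- sample(nrow(tmpl), 1)
      e <- sample(ext, 1)
      pat <- if (want_pos[i]) tmpl$near[f] else tmpl$far[f]
      smi <- sprintf(pat, e)
      stat <- molecule_charge_stat(smi)
      smiles[i] <- smi
      signal[i] <- isTRUE(stat > tmpl$tau[f])
    }
  }

  flip <- stats::runif(n) < spec$label_noise
  label <- as.integer(xor(signal, flip))
  ids <- sprintf("syn%04d", seq_len(n))
  out <- data.frame(compound_id = ids, name = ids, smiles = smiles,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "signal") <- as.integer(signal)
  out
}

#' Write a synthetic spec to JSON (and read it back)
#'
#' @param spec A `synthetic_spec`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, p)
}
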