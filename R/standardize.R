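#' Allowed chemical elements
#'
#' The ten elements common in stable drug-like organic molecules. Records
#' containing any other element (arsenic, boron, metals, ...) are rejected
#' during standardisation so that rare chemistries do not bias training.
#'
#' @return Character vector of element symbols.
#' @export
allowed_elements <- function() {
  c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
}

#' Screen a molecule for allowed elements
#'
#' Accepts a molecule only if every atom is one of the ten allowed elements
#' (see [allowed_elements()]).
#'
#' @param smiles A SMILES string that parses successfully.
#' @return A list with `accepted` (logical) and `offending` (character vector
#'   of disallowed element symbols, empty when accepted).
#' @export
screen_elements <- function(smiles) {
  els <- elements_of(smiles)
  if (is.null(els)) stop("screen_elements() requires a parseable SMILES")
  bad <- setdiff(els, allowed_elements())
  list(accepted = length(bad) == 0L, offending = sort(bad))
}

#' Normalise a molecule
#'
#' Folds explicit hydrogens into implicit hydrogen counts and neutralises
#' ionic charges where chemically possible (protonated amines, deprotonated
#' acids). Genuine zwitterionic groups that cannot be neutralised, such as
#' nitro groups, are left untouched. Idempotent.
#'
#' @param smiles SMILES string of a parsed molecule.
#' @return Canonical SMILES of the normalised molecule, or `NA_character_`
#'   if the toolkit fails to normalise.
#' @export
normalize_molecule <- function(smiles) {
  ob_canonical(smiles, c(neutralize = ""))
}

#' Select the parent fragment
#'
#' For multi-fragment records (salts, solvates) the parent molecule is the
#' fragment with the greatest heavy-atom count. Ties are broken by keeping
#' the fragment whose canonical SMILES sorts first lexicographically, which
#' is deterministic and invariant to input atom order.
#'
#' @param smiles SMILES string, possibly containing `.`-separated fragments.
#' @return Canonical SMILES of the parent fragment.
#' @export
select_parent_fragment <- function(smiles) {
  can <- ob_canonical(smiles)
  if (is.na(can)) stop("select_parent_fragment() requires a parseable SMILES")
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) stop("empty molecule has no parent fragment")
  if (length(frags) == 1L) return(ob_canonical(frags))
  cans <- vapply(frags, ob_canonical, "", USE.NAMES = FALSE)
  sizes <- vapply(cans, heavy_atom_count, 0L, USE.NAMES = FALSE)
  ord <- order(-sizes, cans)
  cans[ord[1]]
}

#' Standardise one compound record
#'
#' Runs the full standardisation pipeline: parse, element screening,
#' normalisation, parent-fragment selection, and tautomer canonicalisation,
#' in that order. The first failing stage is recorded; failures are results,
#' not errors.
#'
#' @param record A list or one-row data.frame with fields `compound_id`,
#'   `name`, `smiles` and `label`.
#' @param screen_after_parent If `TRUE`, element screening is applied to the
#'   parent fragment instead of the whole record, so metal counterions are
#'   stripped rather than causing rejection. Default `FALSE`: screening
#'   happens first, so any metal-containing record is rejected whole.
#' @return An object of class `std_outcome`: a list with `record`, `status`
#'   (`"accepted"`/`"rejected"`), `stage_failed` (`"parse"`,
#'   `"element_screen"`, `"normalize"`, `"parent"`, `"tautomer"` or
#'   `"none"`), `message`, and `standardized_smiles` (`NA` when rejected).
#' @export
standardize_record <- function(record, screen_after_parent = FALSE) {
  rec <- as.list(record)
  out <- function(status, stage, msg, smi = NA_character_) {
    structure(list(record = rec, status = status, stage_failed = stage,
                   message = msg, standardized_smiles = smi),
              class = "std_outcome")
  }
  smi <- rec$smiles
  if (is.null(smi) || is.na(smi) || !nzchar(trimws(smi))) {
    return(out("rejected", "parse", "missing SMILES string"))
  }
  can <- ob_canonical(smi)
  if (is.na(can)) {
    return(out("rejected", "parse", sprintf("SMILES failed to parse: '%s'", smi)))
  }

  screen <- function(s) {
    sc <- screen_elements(s)
    if (!sc$accepted) {
      out("rejected", "element_screen",
          sprintf("disallowed elements: %s", paste(sc$offending, collapse = ", ")))
    } else {
      NULL
    }
  }
  if (!screen_after_parent) {
    r <- screen(can)
    if (!is.null(r)) return(r)
  }

  norm <- normalize_molecule(can)
  if (is.na(norm)) {
    return(out("rejected", "normalize", "charge neutralisation failed"))
  }

  parent <- tryCatch(select_parent_fragment(norm), error = function(e) NA_character_)
  if (is.na(parent)) {
    return(out("rejected", "parent", "parent fragment selection failed"))
  }

  if (screen_after_parent) {
    r <- screen(parent)
    if (!is.null(r)) return(r)
  }

  taut <- tryCatch(canonicalize_tautomer(parent), error = function(e) NA_character_)
  if (is.na(taut)) {
    return(out("rejected", "tautomer", "tautomer canonicalisation failed"))
  }

  out("accepted", "none", "", taut)
}

#' Standardise a dataset of compound records
#'
#' Applies [standardize_record()] to every row and splits the results into
#' accepted records (with a `standardized_smiles` column) and a rejects
#' table carrying the failing stage and message for the error log.
#'
#' @param records Data frame with columns `name`, `smiles`, `label`
#'   (configurable via `cols`); an optional `compound_id` column is used as
#'   identifier, otherwise `name` is.
#' @param cols Named character vector mapping the expected roles to the
#'   column names present in `records`.
#' @param screen_after_parent Passed to [standardize_record()].
#' @return A list with data frames `accepted` (columns compound_id, name,
#'   smiles, label, standardized_smiles) and `rejected` (columns name,
#'   smiles, stage_failed, message).
#' @export
standardize_dataset <- function(records,
                                cols = c(name = "name", smiles = "smiles",
                                         label = "label"),
                                screen_after_parent = FALSE) {
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  n <- nrow(records)
  ids <- if ("compound_id" %in% names(records)) {
    as.character(records$compound_id)
  } else {
    as.character(records[[cols[["name"]]]])
  }
  acc <- vector("list", n)
  rej <- vector("list", n)
  for (k in seq_len(n)) {
    rec <- list(compound_id = ids[k],
                name = as.character(records[[cols[["name"]]]][k]),
                smiles = as.character(records[[cols[["smiles"]]]][k]),
                label = records[[cols[["label"]]]][k])
    o <- standardize_record(rec, screen_after_parent = screen_after_parent)
    if (o$status == "accepted") {
      acc[[k]] <- data.frame(compound_id = rec$compound_id, name = rec$name,
                             smiles = rec$smiles, label = rec$label,
                             standardized_smiles = o$standardized_smiles,
                             stringsAsFactors = FALSE)
    } else {
      rej[[k]] <- data.frame(name = rec$name, smiles = rec$smiles,
                             stage_failed = o$stage_failed, message = o$message,
                             stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  list(accepted = bind(acc), rejected = bind(rej))
}

#' Read a compound CSV
#'
#' @param path CSV file with a header; UTF-8.
#' @param cols Named vector mapping roles (`name`, `smiles`, `label`) to
#'   column names in the file.
#' @return Data frame with at least those columns.
#' @export
read_compound_csv <- function(path, cols = c(name = "name", smiles = "smiles",
                                             label = "label")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(unname(cols), names(df))
  if (length(missing)) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}

#' Write standardisation results to CSV files
#'
#' Writes the accepted records (input columns plus `standardized_smiles`)
#' and a sidecar rejects file with the per-record failure stage and message.
#'
#' @param result The list returned by [standardize_dataset()].
#' @param accepted_path,rejected_path Output CSV paths.
#' @return Invisibly, `result`.
#' @export
write_standardized_csv <- function(result, accepted_path, rejected_path) {
  acc <- result$accepted
  rej <- result$rejected
  if (is.null(acc)) {
    acc <- data.frame(compound_id = character(), name = character(),
                      smiles = character(), label = integer(),
                      standardized_smiles = character())
  }
  if (is.null(rej)) {
    rej <- data.frame(name = character(), smiles = character(),
                      stage_failed = character(), message = character())
  }
  utils::write.csv(acc, accepted_path, row.names = FALSE)
  utils::write.csv(rej, rejected_path, row.names = FALSE)
  invisible(result)
}
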