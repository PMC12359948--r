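# Molecular graph featurisation: basic graphs (atomic number / bond type)
# and custom graphs carrying geometry- and charge-derived features from the
# MMFF94-optimised conformer.

schema_vocab <- list(
  elements = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  hybridisation = c("SP", "SP2", "SP3", "SP3D", "SP3D2", "other"),
  bond_type = c("single", "double", "triple", "aromatic"),
  chirality = c("none", "CW", "CCW", "other")
)

#' Feature schema for molecular graphs
#'
#' Defines the node and edge features, their encodings and the resulting
#' dimensions. `basic` mode encodes the atomic number (one-hot over the ten
#' allowed elements) and the bond type (one-hot over four classes). `custom`
#' mode adds degree, formal charge, hybridisation, aromaticity, hydrogen
#' count, ring membership, chirality, radical electrons, Gasteiger partial
#' charge, total valence and explicit valence on nodes, and ring membership
#' plus the MMFF94-optimised bond length (Angstrom) on edges.
#'
#' Categorical features are one-hot over fixed vocabularies; counts are
#' encoded as real scalars; partial charge and bond length are raw scalars.
#'
#' @param mode `"custom"` or `"basic"`.
#' @return Object of class `feature_schema` with `mode`, `vocab`,
#'   `node_features`, `edge_features`, `d_node`, `d_edge`.
#' @export
feature_schema <- function(mode = c("custom", "basic")) {
  mode <- match.arg(mode)
  if (mode == "basic") {
    node_features <- "atomic_number"
    edge_features <- "bond_type"
    d_node <- length(schema_vocab$elements)
    d_edge <- length(schema_vocab$bond_type)
  } else {
    node_features <- c("atomic_number", "degree", "formal_charge",
                       "hybridisation", "aromatic", "n_hydrogens", "in_ring",
                       "chirality", "radical_electrons", "gasteiger_charge",
                       "total_valence", "explicit_valence")
    edge_features <- c("bond_type", "in_ring", "bond_length")
    d_node <- length(schema_vocab$elements) + 1 + 1 +
      length(schema_vocab$hybridisation) + 1 + 1 + 1 +
      length(schema_vocab$chirality) + 1 + 1 + 1 + 1
    d_edge <- length(schema_vocab$bond_type) + 1 + 1
  }
  structure(list(mode = mode, vocab = schema_vocab,
                 node_features = node_features, edge_features = edge_features,
                 d_node = d_node, d_edge = d_edge),
            class = "feature_schema")
}

one_hot <- function(value, vocab) {
  v <- numeric(length(vocab))
  idx <- match(value, vocab)
  if (is.na(idx)) idx <- length(vocab)  # fall through to trailing class
  v[idx] <- 1
  v
}

sybyl_hybridisation <- function(sybyl) {
  suffix <- sub("^[A-Za-z]+\\.?", "", sybyl)
  switch(suffix,
         "1" = "SP", "2" = "SP2", "3" = "SP3", "ar" = "SP2",
         "am" = "SP2", "pl3" = "SP2", "co2" = "SP2",
         "o" = "SP3", "o2" = "SP3", "th" = "SP3", "4" = "SP3",
         "other")
}

mol2_bond_class <- function(type) {
  switch(type, "1" = "single", "2" = "double", "3" = "triple",
         "ar" = "aromatic", "am" = "single", "single")
}

mol2_bond_order <- function(type) {
  switch(type, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, 1)
}

# Per-atom chirality tags from SMILES bracket atoms, in SMILES atom order
# (which the toolkit preserves through SDF conversion). "@@" is the
# clockwise tag, "@" anticlockwise, extended tags map to "other".
smiles_chirality_tags <- function(smiles) {
  tags <- character()
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      tag <- if (grepl("@(TH|AL|SP|TB|OH)", inner)) "other"
             else if (grepl("@@", inner, fixed = TRUE)) "CW"
             else if (grepl("@", inner, fixed = TRUE)) "CCW"
             else "none"
      tags <- c(tags, tag)
      i <- j + 1L
    } else if (ch %in% c("C", "B")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ch
      if (two %in% c("Cl", "Br")) {
        tags <- c(tags, "none"); i <- i + 2L
      } else {
        tags <- c(tags, "none"); i <- i + 1L
      }
    } else if (ch %in% c("N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      tags <- c(tags, "none"); i <- i + 1L
    } else {
      i <- i + 1L  # bonds, branches, ring closures, digits
    }
  }
  tags
}

# Bridge detection: a bond is in a ring iff it is not a bridge.
ring_bonds <- function(n_atoms, bonds) {
  if (!nrow(bonds)) return(logical())
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
  }
  in_ring <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    # BFS from i to j avoiding bond k
    src <- bonds$i[k]; dst <- bonds$j[k]
    seen <- logical(n_atoms); seen[src] <- TRUE
    queue <- src
    while (length(queue) && !seen[dst]) {
      a <- queue[1]; queue <- queue[-1]
      for (bk in adj[[a]]) {
        if (bk == k) next
        b <- if (bonds$i[bk] == a) bonds$j[bk] else bonds$i[bk]
        if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
      }
    }
    in_ring[k] <- seen[dst]
  }
  in_ring
}

#' Perceive chemical features of an optimised conformer
#'
#' Derives, for every atom and bond, the descriptors consumed by the graph
#' featuriser: SYBYL-type-based hybridisation and aromaticity, Gasteiger
#' partial charges, formal charges, radical electrons, ring membership,
#' heavy-atom degree, hydrogen counts, valences, SMILES-derived chirality
#' tags and the optimised 3D bond lengths.
#'
#' @param optimized An `optimized_conformer` (see [mmff_optimize()]).
#' @param smiles The standardised SMILES the conformer was built from (used
#'   only for the chirality tags; may be `NULL`).
#' @return Object of class `mol_perception`.
#' @export
perceive_molecule <- function(optimized, smiles = NULL) {
  stopifnot(inherits(optimized, "optimized_conformer"))
  m2txt <- ob_convert("SDF", "MOL2", optimized$sdf,
                      c(partialcharge = "gasteiger"))
  if (!nzchar(m2txt)) stop("MOL2 conversion failed during perception")
  m2 <- parse_mol2(m2txt)
  mb <- parse_molblock(split_sdf(optimized$sdf)[[1]])
  n <- mb$n_atoms
  stopifnot(length(m2$sybyl) == n)

  elements <- mb$elements
  heavy <- which(elements != "H")
  bonds <- m2$bonds
  bond_class <- vapply(bonds$type, mol2_bond_class, "")
  bond_order <- vapply(bonds$type, mol2_bond_order, 0)

  arom_bond <- bonds$type == "ar"
  arom_atom <- logical(n)
  arom_atom[c(bonds$i[arom_bond], bonds$j[arom_bond])] <- TRUE
  arom_atom <- arom_atom | grepl("\\.ar$", m2$sybyl)

  deg_heavy <- integer(n)
  n_h <- integer(n)
  exp_val <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (elements[j] == "H") n_h[i] <- n_h[i] + 1L
    if (elements[i] == "H") n_h[j] <- n_h[j] + 1L
    if (elements[i] != "H" && elements[j] != "H") {
      deg_heavy[i] <- deg_heavy[i] + 1L
      deg_heavy[j] <- deg_heavy[j] + 1L
      exp_val[i] <- exp_val[i] + bond_order[k]
      exp_val[j] <- exp_val[j] + bond_order[k]
    }
  }

  gast <- m2$charge
  charge_flag <- any(!is.finite(gast))
  gast[!is.finite(gast)] <- 0

  chir <- rep("none", n)
  if (!is.null(smiles)) {
    tags <- smiles_chirality_tags(smiles)
    # SMILES order = heavy-atom order in the molblock (hydrogens appended)
    if (length(tags) == length(heavy)) chir[heavy] <- tags
  }

  heavy_bonds_idx <- which(elements[bonds$i] != "H" & elements[bonds$j] != "H")
  hb <- bonds[heavy_bonds_idx, , drop = FALSE]
  ring <- logical(nrow(bonds))
  if (length(heavy_bonds_idx)) {
    ring[heavy_bonds_idx] <- ring_bonds(n, hb)
  }
  ring_atom <- logical(n)
  ring_atom[c(bonds$i[ring], bonds$j[ring])] <- TRUE

  lengths <- bond_distances(mb$coords, as.matrix(bonds[, c("i", "j")]))

  structure(list(
    n_atoms = n, elements = elements, heavy = heavy, coords = mb$coords,
    formal_charge = mb$charges, radicals = mb$radicals,
    sybyl = m2$sybyl, gasteiger = gast, gasteiger_flag = charge_flag,
    aromatic_atom = arom_atom, chirality = chir,
    degree_heavy = deg_heavy, n_hydrogens = n_h,
    explicit_valence = exp_val, total_valence = exp_val + n_h,
    in_ring_atom = ring_atom,
    bonds = data.frame(i = bonds$i, j = bonds$j, class = bond_class,
                       in_ring = ring, length = lengths,
                       stringsAsFactors = FALSE)
  ), class = "mol_perception")
}

#' Node feature vector
#'
#' Encodes one atom under a feature schema. Custom mode emits, in order:
#' one-hot atomic number, heavy-atom degree, formal charge, one-hot
#' hybridisation, aromaticity flag, hydrogen count, ring flag, one-hot
#' chirality, radical electron count, Gasteiger partial charge, total
#' valence and explicit valence. Basic mode emits the one-hot atomic number
#' only.
#'
#' @param perception A `mol_perception` object.
#' @param atom 1-based atom index (into all atoms, hydrogens included).
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$d_node`.
#' @export
node_feature_vector <- function(perception, atom, schema) {
  p <- perception
  el <- one_hot(p$elements[atom], schema$vocab$elements)
  if (schema$mode == "basic") return(el)
  c(el,
    p$degree_heavy[atom],
    p$formal_charge[atom],
    one_hot(sybyl_hybridisation(p$sybyl[atom]), schema$vocab$hybridisation),
    as.numeric(p$aromatic_atom[atom]),
    p$n_hydrogens[atom],
    as.numeric(p$in_ring_atom[atom]),
    one_hot(p$chirality[atom], schema$vocab$chirality),
    p$radicals[atom],
    p$gasteiger[atom],
    p$total_valence[atom],
    p$explicit_valence[atom])
}

#' Edge feature vector
#'
#' Encodes one bond under a feature schema: one-hot bond type, plus (custom
#' mode) the ring flag and the optimised bond length in Angstrom.
#'
#' @param perception A `mol_perception` object.
#' @param bond 1-based row index into `perception$bonds`.
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$d_edge`.
#' @export
edge_feature_vector <- function(perception, bond, schema) {
  b <- perception$bonds[bond, ]
  bt <- one_hot(b$class, schema$vocab$bond_type)
  if (schema$mode == "basic") return(bt)
  c(bt, as.numeric(b$in_ring), b$length)
}

#' Build a molecular graph
#'
#' Assembles the heavy-atom graph of a molecule: nodes are non-hydrogen
#' atoms (hydrogens contribute through the hydrogen-count feature), and
#' each chemical bond is stored as two directed arcs carrying identical
#' edge features.
#'
#' @param perception A `mol_perception` object.
#' @param label Integer class label (0/1), or a small integer vector for
#'   multi-task data.
#' @param schema A [feature_schema()].
#' @param graph_id Identifier string.
#' @return Object of class `molecular_graph`: list with `graph_id`,
#'   `n_nodes`, `node_matrix` (n x d_node), `arcs` (|arcs| x 2, 1-based
#'   node indices, closed under reversal), `edge_matrix` (|arcs| x d_edge),
#'   `label`.
#' @export
build_graph <- function(perception, label, schema, graph_id = "g") {
  p <- perception
  heavy <- p$heavy
  n <- length(heavy)
  stopifnot(n >= 1L)
  node_matrix <- t(vapply(heavy, function(a) node_feature_vector(p, a, schema),
                          numeric(schema$d_node)))
  remap <- integer(p$n_atoms)
  remap[heavy] <- seq_len(n)
  hb <- which(p$elements[p$bonds$i] != "H" & p$elements[p$bonds$j] != "H")
  if (length(hb)) {
    ef <- t(vapply(hb, function(k) edge_feature_vector(p, k, schema),
                   numeric(schema$d_edge)))
    src <- remap[p$bonds$i[hb]]
    dst <- remap[p$bonds$j[hb]]
    arcs <- cbind(c(src, dst), c(dst, src))
    edge_matrix <- rbind(ef, ef)
  } else {
    arcs <- matrix(integer(), 0, 2)
    edge_matrix <- matrix(numeric(), 0, schema$d_edge)
  }
  structure(list(graph_id = graph_id, n_nodes = n, node_matrix = node_matrix,
                 arcs = arcs, edge_matrix = edge_matrix, label = label),
            class = "molecular_graph")
}

#' Featurise a standardised dataset into molecular graphs
#'
#' For every accepted record: embed a 3D conformer, minimise it with
#' MMFF94, perceive features and build the molecular graph under the
#' requested schema. Molecules that fail to embed or optimise are reported
#' in `failed`, not silently dropped.
#'
#' @param standardized Data frame with columns `compound_id`,
#'   `standardized_smiles` and `label` (the accepted table of
#'   [standardize_dataset()]).
#' @param mode Feature schema mode, `"custom"` or `"basic"`.
#' @param seed Recorded in provenance (see [embed_conformer()] on
#'   embedding randomness).
#' @return Object of class `graph_dataset`: list with `schema`, `graphs`
#'   (list of `molecular_graph`), `labels`, `ids`, `failed`, `provenance`.
#' @export
featurize_dataset <- function(standardized, mode = "custom", seed = 1L) {
  stopifnot(all(c("compound_id", "standardized_smiles", "label") %in%
                  names(standardized)))
  schema <- feature_schema(mode)
  ids <- as.character(standardized$compound_id)
  res <- embed_and_optimize(standardized$standardized_smiles, ids)
  graphs <- list()
  labels <- list()
  kept <- character()
  failed <- character()
  for (k in seq_along(res)) {
    r <- res[[k]]
    if (is.null(r$optimized) || !isTRUE(r$optimized$converged)) {
      failed <- c(failed, r$id)
      next
    }
    perc <- tryCatch(perceive_molecule(r$optimized, r$smiles),
                     error = function(e) NULL)
    if (is.null(perc)) {
      failed <- c(failed, r$id)
      next
    }
    g <- build_graph(perc, standardized$label[k], schema, graph_id = r$id)
    graphs[[length(graphs) + 1L]] <- g
    labels[[length(labels) + 1L]] <- standardized$label[k]
    kept <- c(kept, r$id)
  }
  structure(list(schema = schema, graphs = graphs,
                 labels = unlist(labels), ids = kept, failed = failed,
                 provenance = list(seed = seed, mode = mode,
                                   created = format(Sys.time(), "%Y-%m-%d"))),
            class = "graph_dataset")
}

#' Write a graph dataset to a self-describing JSON container
#'
#' The file holds a header (schema mode, vocabularies, dimensions,
#' provenance) plus the per-graph columnar arrays. Numeric values are
#' serialised at full precision so that a read/write round trip is
#' bit-exact.
#'
#' @param dataset A `graph_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graph_dataset <- function(dataset, path) {
  payload <- list(
    header = list(
      container = "molgraphnn/graph_dataset/v1",
      mode = dataset$schema$mode,
      vocab = dataset$schema$vocab,
      d_node = dataset$schema$d_node,
      d_edge = dataset$schema$d_edge,
      provenance = dataset$provenance
    ),
    ids = dataset$ids,
    labels = dataset$labels,
    failed = dataset$failed,
    graphs = lapply(dataset$graphs, function(g) {
      list(graph_id = g$graph_id, n_nodes = g$n_nodes, label = g$label,
           node_matrix = g$node_matrix, arcs = g$arcs,
           edge_matrix = g$edge_matrix)
    })
  )
  # I(17) significant digits guarantee a bit-exact double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a graph dataset written by [write_graph_dataset()]
#'
#' @param path JSON container path.
#' @return A `graph_dataset`.
#' @export
read_graph_dataset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  h <- payload$header
  if (!identical(h$container, "molgraphnn/graph_dataset/v1")) {
    stop("not a molgraphnn graph dataset: ", path)
  }
  schema <- feature_schema(h$mode)
  graphs <- lapply(payload$graphs, function(g) {
    nm <- if (is.list(g$node_matrix)) do.call(rbind, g$node_matrix) else
      g$node_matrix
    arcs <- if (is.list(g$arcs)) do.call(rbind, g$arcs) else g$arcs
    if (length(arcs) == 0L) arcs <- matrix(integer(), 0, 2)
    em <- if (is.list(g$edge_matrix)) do.call(rbind, g$edge_matrix) else
      g$edge_matrix
    if (length(em) == 0L) em <- matrix(numeric(), 0, schema$d_edge)
    structure(list(graph_id = g$graph_id, n_nodes = g$n_nodes,
                   node_matrix = nm, arcs = arcs, edge_matrix = em,
                   label = g$label),
              class = "molecular_graph")
  })
  structure(list(schema = schema, graphs = graphs,
                 labels = unlist(payload$labels),
                 ids = unlist(payload$ids),
                 failed = if (length(payload$failed)) unlist(payload$failed)
                          else character(),
                 provenance = h$provenance),
            class = "graph_dataset")
}
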