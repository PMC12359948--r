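test_that("schema dimensions and the custom/basic superset relation hold", {
  basic <- feature_schema("basic")
  custom <- feature_schema("custom")
  expect_equal(basic$d_node, 10L)
  expect_equal(basic$d_edge, 4L)
  expect_equal(custom$d_node, 29L)
  expect_equal(custom$d_edge, 6L)
  expect_gt(custom$d_node, basic$d_node)
  expect_gt(custom$d_edge, basic$d_edge)
  expect_equal(length(custom$node_features), 12L)
  expect_equal(length(custom$edge_features), 3L)
})

test_that("node features encode benzene and methane chemistry correctly", {
  schema <- feature_schema("custom")
  benz <- perceive_molecule(toy_optimized()$benzene$optimized, "c1ccccc1")
  c1 <- benz$heavy[1]
  expect_true(benz$aromatic_atom[c1])
  expect_true(benz$in_ring_atom[c1])
  expect_equal(ns$sybyl_hybridisation(benz$sybyl[c1]), "SP2")
  expect_equal(benz$n_hydrogens[c1], 1L)

  meth_conf <- embed_conformer("C", max_attempts = 10)
  meth <- perceive_molecule(mmff_optimize(meth_conf), "C")
  a <- meth$heavy[1]
  expect_equal(meth$degree_heavy[a], 0L)
  expect_equal(meth$n_hydrogens[a], 4L)
  expect_equal(meth$formal_charge[a], 0L)
  expect_equal(meth$total_valence[a], 4)
  v <- node_feature_vector(meth, a, schema)
  expect_length(v, schema$d_node)
  # one-hot atomic number block sums to one
  expect_equal(sum(v[1:10]), 1)
})

test_that("gasteiger charges match the toolkit's charge routine", {
  opt <- toy_optimized()$benzene$optimized
  perc <- perceive_molecule(opt, "c1ccccc1")
  m2 <- ns$ob_convert("SDF", "MOL2", opt$sdf, c(partialcharge = "gasteiger"))
  ref <- ns$parse_mol2(m2)$charge
  expect_equal(perc$gasteiger, ref, tolerance = 1e-6)
  # charges sum to the net formal charge (neutral here)
  expect_lt(abs(sum(perc$gasteiger)), 1e-3)
})

test_that("edge features encode bond class, ring flag and length", {
  schema <- feature_schema("custom")
  basic <- feature_schema("basic")
  benz <- perceive_molecule(toy_optimized()$benzene$optimized, "c1ccccc1")
  cc <- which(benz$bonds$class == "aromatic")
  expect_length(cc, 6L)
  v <- edge_feature_vector(benz, cc[1], schema)
  expect_length(v, schema$d_edge)
  expect_equal(v[1:4], c(0, 0, 0, 1))          # aromatic one-hot
  expect_equal(v[5], 1)                        # in ring
  expect_true(v[6] >= 1.35 && v[6] <= 1.45)    # optimised length

  eth_conf <- embed_conformer("CC", max_attempts = 10)
  eth <- perceive_molecule(mmff_optimize(eth_conf), "CC")
  k <- which(eth$elements[eth$bonds$i] != "H" & eth$elements[eth$bonds$j] != "H")
  ve <- edge_feature_vector(eth, k[1], schema)
  expect_equal(ve[1:4], c(1, 0, 0, 0))         # single bond
  expect_equal(ve[5], 0)                       # acyclic
  vb <- edge_feature_vector(eth, k[1], basic)
  expect_length(vb, 4L)
})

test_that("build_graph produces heavy-atom graphs closed under arc reversal", {
  schema <- feature_schema("custom")
  eth <- perceive_molecule(mmff_optimize(embed_conformer("CCO")), "CCO")
  g <- build_graph(eth, 1L, schema, "ethanol")
  expect_equal(g$n_nodes, 3L)
  expect_equal(nrow(g$arcs), 4L)
  expect_equal(dim(g$node_matrix), c(3L, schema$d_node))
  expect_equal(dim(g$edge_matrix), c(4L, schema$d_edge))

  benz <- perceive_molecule(toy_optimized()$benzene$optimized, "c1ccccc1")
  gb <- build_graph(benz, 0L, schema, "benzene")
  expect_equal(gb$n_nodes, 6L)
  expect_equal(nrow(gb$arcs), 12L)
  ring_col <- 5L
  expect_true(all(gb$edge_matrix[, ring_col] == 1))

  # arc list closed under reversal with identical edge features
  key <- paste(gb$arcs[, 1], gb$arcs[, 2])
  rev_key <- paste(gb$arcs[, 2], gb$arcs[, 1])
  expect_setequal(key, rev_key)
  for (k in seq_len(nrow(gb$arcs))) {
    r <- match(rev_key[k], key)
    expect_equal(gb$edge_matrix[k, ], gb$edge_matrix[r, ])
  }
  expect_false(any(gb$arcs[, 1] == gb$arcs[, 2]))

  # single heavy atom: valid graph with zero arcs
  gm <- build_graph(perceive_molecule(mmff_optimize(embed_conformer("C")), "C"),
                    1L, schema, "methane")
  expect_equal(gm$n_nodes, 1L)
  expect_equal(nrow(gm$arcs), 0L)
})

test_that("bond length stored on arcs equals the conformer measurement", {
  schema <- feature_schema("custom")
  opt <- toy_optimized()$aspirin$optimized
  perc <- perceive_molecule(opt, "CC(=O)Oc1ccccc1C(=O)O")
  g <- build_graph(perc, 1L, schema, "aspirin")
  hb <- which(perc$elements[perc$bonds$i] != "H" &
                perc$elements[perc$bonds$j] != "H")
  lens <- measure_bond_lengths(opt, perc$bonds[hb, c("i", "j")])
  expect_equal(g$edge_matrix[seq_along(hb), schema$d_edge], lens,
               tolerance = 1e-9)
})

test_that("atom-order permutation yields an isomorphic graph", {
  schema <- feature_schema("custom")
  # same molecule written with different atom orders
  g1 <- build_graph(perceive_molecule(mmff_optimize(embed_conformer("OCC")),
                                      "OCC"), 1L, schema, "a")
  g2 <- build_graph(perceive_molecule(mmff_optimize(embed_conformer("CCO")),
                                      "CCO"), 1L, schema, "b")
  expect_equal(g1$n_nodes, g2$n_nodes)
  expect_equal(nrow(g1$arcs), nrow(g2$arcs))
  # compare canonical multisets of discrete node features (one-hot blocks)
  disc <- c(1:19, 21:27)  # all but the scalar charge/valence columns
  m1 <- apply(round(g1$node_matrix[, disc], 6), 1, paste, collapse = ",")
  m2 <- apply(round(g2$node_matrix[, disc], 6), 1, paste, collapse = ",")
  expect_setequal(m1, m2)
})

test_that("graph dataset JSON container round-trips bit-exactly", {
  ds <- small_graph_dataset("custom")
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_dataset(ds, path)
  back <- read_graph_dataset(path)
  expect_equal(back$schema$mode, ds$schema$mode)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$ids, ds$ids)
  expect_length(back$graphs, length(ds$graphs))
  for (k in seq_along(ds$graphs)) {
    expect_identical(unname(back$graphs[[k]]$node_matrix),
                     unname(ds$graphs[[k]]$node_matrix))
    expect_identical(unname(back$graphs[[k]]$edge_matrix),
                     unname(ds$graphs[[k]]$edge_matrix))
    expect_equal(unname(as.matrix(back$graphs[[k]]$arcs)),
                 unname(as.matrix(ds$graphs[[k]]$arcs)))
  }
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(header = list(container = "something_else")), other,
                       auto_unbox = TRUE)
  expect_error(read_graph_dataset(other), "not a molgraphnn graph dataset")
})
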