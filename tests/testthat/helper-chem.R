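# Lazily computed, shared chemistry fixtures (standardisation and
# featurisation of the toy library are toolkit calls worth caching across
# test files within one run).

.chem_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .chem_cache)) {
    assign(key, force(expr), envir = .chem_cache)
  }
  get(key, envir = .chem_cache)
}

toy_standardized <- function() {
  cached("toy_std", standardize_dataset(toy_library()))
}

# A small featurised synthetic dataset for trainer tests: 48 molecules,
# substructure signal, no label noise.
small_graph_dataset <- function(mode = "custom") {
  cached(paste0("small_ds_", mode), {
    spec <- synthetic_spec(48, "substructure", label_noise = 0, seed = 77)
    recs <- generate_synthetic_dataset(spec)
    std <- standardize_dataset(recs)
    featurize_dataset(std$accepted, mode = mode)
  })
}

# Optimised conformers of a few toy molecules, for geometry tests.
toy_optimized <- function() {
  cached("toy_opt", {
    smis <- c(ethanol = "CCO", benzene = "c1ccccc1",
              aspirin = "CC(=O)Oc1ccccc1C(=O)O",
              paracetamol = "CC(=O)Nc1ccc(O)cc1")
    lapply(smis, function(s) {
      conf <- embed_conformer(s, max_attempts = 25)
      list(conformer = conf, optimized = mmff_optimize(conf))
    })
  })
}

fast_config <- function(conv_type = "gcn", ...) {
  model_config(conv_type, hidden_channels = 4L, dropout = 0,
               learning_rate = 3e-3, batch_size = 16L, seed = 5L,
               max_epochs = 30L, patience = 10L, ...)
}
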