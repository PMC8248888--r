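# Small shared fixtures, built in code.

rnd_grid <- function(dims, cell = unit_cell(8, 8, 8), sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  real_grid(array(rnorm(prod(dims), 0, sd), dims), cell)
}

# tiny crystal: n atoms at crystal-like packing, plus its exact dataset
tiny_dataset <- function(n_atoms = 12, d_min = 1.1, seed = 3,
                         class_tag = "weak", vol_per_atom = 16) {
  spec <- scenario_spec(class_tag, n_atoms = n_atoms, vol_per_atom = vol_per_atom,
                        d_min = d_min, min_dist = 1.4, seed = seed)
  st <- generate_structure(spec)
  c(make_dataset(st, d_min), list(structure = st))
}

# cache for expensive shared computations within a test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}
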