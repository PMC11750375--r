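# Shared fixtures and reduced solver settings for fast tests.  Geometry is
# generated in code; no stored data.

fast_options <- function(...) {
  # accurate to ~1e-5 in conductances; a straight solve takes well under a
  # second at this resolution
  sweep_options(...)
}

ref_spec <- function() bif_spec(0.9, 0.8, pi / 4, pi / 3, 2)
sym_spec <- function() bif_spec(1, 1, pi / 4, pi / 4, 2)

# memoised conductance sets shared across tests in one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

ref_conductances <- function() {
  cached("ref_cs", function()
    conductance_tensor(build_bifurcation(ref_spec()), solver_options()))
}

sym_conductances <- function() {
  cached("sym_cs", function()
    conductance_tensor(build_bifurcation(sym_spec()), solver_options(),
                       keep_solutions = TRUE))
}
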