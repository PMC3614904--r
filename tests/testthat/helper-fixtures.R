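# Shared small fixtures, built once per test run.

the <- new.env(parent = emptyenv())

suite_cached <- function() {
  if (is.null(the$suite)) the$suite <- fixture_suite(1)
  the$suite
}

poly <- function(seq, secondary = "helix") {
  build_peptide(fixture_spec(seq, secondary), id = paste0("poly_", seq))
}
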