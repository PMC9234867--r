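# The full synthetic asset bundle is used by several test files; build it
# once per test run.
toy_assets <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache)) cache <<- make_toy_assets(seed)
    cache
  }
})

# The printed 33-residue alpha2-gliadin peptide, used across tests.
PEP33 <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"
PEP13 <- "LGQQQPFPPQQPY"
PEP10 <- "QLIPCMDVVL"
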