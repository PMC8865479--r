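# One small simulation shared by tests that only need mock genomes, protein
# databases and profiles (built once per test run).
.simCache <- new.env(parent = emptyenv())

tinySim <- function() {
  if (is.null(.simCache$sim))
    .simCache$sim <- simulateVirome(simConfig(seed = 3,
                                              readsPerLibrary = 300L))
  .simCache$sim
}
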