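# The length-recovery study: 20 synthetic datasets at reduced scale
# (5e5 bp genome, L = 100 bp, motif length uniform in 15-30 bp, 3 enrichment
# cycles plus control, 2e6 reads-equivalent per cycle, seeds 1..20), each
# run through the full pipeline. Computed once per test session and shared
# between the acceptance tests that consume it.
recoveryBatch <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$batch)) {
      cache$batch <- lapply(1:20, function(s) {
        cfg <- simConfig(genomeSize = 5e5, totalReads = 2e6,
                         fragmentLength = 100L, seed = s)
        ds <- simulateDataset(cfg)
        graded <- gradePeaks(callPeaks(ds@series, peakCallConfig(100L)),
                             ds@series)
        st <- recoveryStats(graded, ds@truth$bTrue)
        list(bTrue = ds@truth$bTrue, nSites = nrow(ds@truth$sites),
             nPeaks = nrow(graded), stats = st)
      })
    }
    cache$batch
  }
})
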