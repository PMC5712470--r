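# The Monte-Carlo comparison study on the default fixture is needed by
# several acceptance checks; run it once per test session and cache it.
.study_cache <- new.env(parent = emptyenv())

default_fixture_study <- function(seeds = 1:20) {
  key <- paste0("s", min(seeds), "_", max(seeds))
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- replicate_comparison(seeds = seeds)
  .study_cache[[key]]
}

study_medians <- function(res) {
  agg <- aggregate(cbind(ME, r2) ~ taxon + factor + method, data = res,
                   FUN = median)
  agg[order(agg$taxon, agg$method, agg$factor), ]
}
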