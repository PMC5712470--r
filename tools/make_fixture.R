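# Regenerates inst/extdata/synthetic_reef_cover.csv — a fully synthetic
# example survey produced by the package's own generator: 15 transects of
# 200 m spaced 200 m apart, quadrats every 5 m, point-count noise at 25
# points, with 20 quadrats masked out (as field campaigns lose points) so
# the file holds 580 records. Zones and depth follow a simple cross-reef
# bathymetric profile: a shallow crest band flanked by deeper windward and
# leeward sand plains. Run from the repository root:
#   Rscript tools/make_fixture.R

library(reefgrid)

seed <- 2024L
mask <- rep(TRUE, 600)
set.seed(seed)
mask[sample(600, 20)] <- FALSE

reef <- simulate_reef(seed, mask = mask)
s <- reef$samples

# cross-reef zonation along the transect axis (y): windward -> crest -> leeward
zone <- cut(s$y, breaks = c(-Inf, 70, 130, Inf),
            labels = c("windward", "crest", "leeward"))
s$zone <- as.character(zone)
set.seed(seed + 1L)
s$depth <- round(16 - 9 * exp(-((s$y - 100) / 40)^2) + rnorm(nrow(s), 0, 0.8),
                 1)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_samples(s, "inst/extdata/synthetic_reef_cover.csv")
cat("wrote", nrow(s), "records\n")
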