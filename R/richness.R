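# Presence/absence reclassification and habitat-former richness synthesis.

#' Reclassify a cover raster to presence/absence
#'
#' A cell becomes 1 (present) when its value exceeds `threshold`, 0
#' otherwise; NODATA propagates. With the default threshold 0 any positive
#' predicted cover counts as presence, which is the permissive convention —
#' interpolation halos around isolated colonies make the threshold
#' consequential, so it is exposed.
#'
#' @param raster a [cover_raster()].
#' @param threshold presence threshold, percent cover (>= 0).
#' @return A binary [cover_raster()].
#' @export
to_presence <- function(raster, threshold = 0) {
  stopifnot(inherits(raster, "cover_raster"), threshold >= 0)
  v <- raster$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v > threshold))
  cover_raster(raster$grid, out, taxon = raster$taxon,
               provenance = c(raster$provenance,
                              sprintf("presence threshold %g", threshold)))
}

#' Richness map from presence layers
#'
#' Cell-wise sum of presence/absence rasters: the number of taxa present in
#' each cell, on a 0-to-k scale for k layers. A cell is NODATA only where
#' every layer is NODATA; a layer that is NODATA over a cell where others
#' have data counts as absent there.
#'
#' @param presence_rasters list of binary [cover_raster()]s on one shared
#'   grid.
#' @return An integer-valued [cover_raster()].
#' @export
richness_map <- function(presence_rasters) {
  stopifnot(is.list(presence_rasters), length(presence_rasters) >= 1L)
  g <- presence_rasters[[1L]]$grid
  for (r in presence_rasters) {
    stopifnot(inherits(r, "cover_raster"))
    if (!identical(unclass(r$grid), unclass(g)))
      stop("presence rasters do not share one grid")
  }
  acc <- matrix(0, g$n_rows, g$n_cols)
  all_na <- matrix(TRUE, g$n_rows, g$n_cols)
  for (r in presence_rasters) {
    v <- r$values
    all_na <- all_na & is.na(v)
    v[is.na(v)] <- 0          # partial NODATA counts as absence
    acc <- acc + v
  }
  acc[all_na] <- NA_real_
  cover_raster(g, acc, taxon = "richness",
               provenance = sprintf("sum of %d presence layers",
                                    length(presence_rasters)))
}

#' Richness area at several presence thresholds
#'
#' Sensitivity helper: recomputes the richness map at each threshold and
#' reports how many cells reach each richness level — a quick check of how
#' much the presence threshold choice matters.
#'
#' @param cover_rasters list of per-taxon [cover_raster()]s (one grid).
#' @param thresholds numeric vector of presence thresholds.
#' @return A data frame: `threshold`, `richness`, `n_cells`.
#' @export
richness_sensitivity <- function(cover_rasters, thresholds = c(0, 1, 5)) {
  out <- list()
  for (th in thresholds) {
    rich <- richness_map(lapply(cover_rasters, to_presence, threshold = th))
    tab <- table(factor(rich$values[!is.na(rich$values)],
                        levels = 0:length(cover_rasters)))
    out[[as.character(th)]] <- data.frame(
      threshold = th, richness = as.integer(names(tab)),
      n_cells = as.integer(tab))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
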