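# SampleSet container and delimited-text / config I/O.

RESERVED_COLS <- c("x", "y", "transect_id", "position_index", "depth", "zone")

as_reef_samples <- function(df, taxa) {
  stopifnot(is.data.frame(df), all(c("x", "y") %in% names(df)),
            all(taxa %in% names(df)))
  structure(df, class = c("reef_samples", "data.frame"), taxa = taxa)
}

#' Cover column names of a sample table
#'
#' @param samples a `reef_samples` data frame.
#' @return Character vector of taxon (cover) column names.
#' @export
sample_taxa <- function(samples) {
  tx <- attr(samples, "taxa")
  if (!is.null(tx)) return(tx)
  setdiff(names(samples), RESERVED_COLS)
}

# One taxon's cover vector, with validation.
sample_cover <- function(samples, taxon) {
  if (!taxon %in% names(samples))
    stop(sprintf("no cover column '%s' in samples (have: %s)", taxon,
                 paste(sample_taxa(samples), collapse = ", ")))
  as.numeric(samples[[taxon]])
}

#' @export
print.reef_samples <- function(x, ...) {
  tx <- sample_taxa(x)
  nt <- if ("transect_id" %in% names(x)) length(unique(x$transect_id)) else NA
  cat(sprintf("reef_samples: %d points%s, %d taxa (%s)\n", nrow(x),
              if (is.na(nt)) "" else sprintf(" on %d transects", nt),
              length(tx), paste(tx, collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a sample table from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header row. Columns `x` and
#' `y` (planar metres) are mandatory; `transect_id`, `position_index`,
#' `depth` and `zone` are recognised when present; every other numeric
#' column is treated as a taxon percent-cover column. Cover values outside
#' `[0, 100]` abort with the offending row and column named. Duplicate
#' coordinates trigger a warning and are averaged into one record.
#'
#' @param path path to the CSV file.
#' @return A `reef_samples` data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("x", "y"))
    if (!col %in% names(df))
      stop(sprintf("missing mandatory coordinate column '%s' in %s", col, path))
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric %s at data row %d of %s", col, bad[1L], path))
    df[[col]] <- v
  }
  taxa <- setdiff(names(df), RESERVED_COLS)
  for (tx in taxa) {
    v <- suppressWarnings(as.numeric(df[[tx]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cover '%s' at data row %d", tx, bad[1L]))
    out <- which(v < 0 | v > 100)
    if (length(out) > 0L)
      stop(sprintf("cover value %g outside [0, 100] at data row %d, column '%s'",
                   v[out[1L]], out[1L], tx))
    df[[tx]] <- v
  }
  key <- paste(df$x, df$y)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate coordinate(s) in %s; averaging cover within each location",
                    sum(duplicated(key)), path))
    first <- !duplicated(key)
    for (tx in taxa)
      df[[tx]][first] <- as.numeric(tapply(df[[tx]], key, mean)[key[first]])
    df <- df[first, , drop = FALSE]
    rownames(df) <- NULL
  }
  if ("position_index" %in% names(df))
    df$position_index <- as.integer(df$position_index)
  as_reef_samples(df, taxa)
}

#' Write a sample table to delimited text
#'
#' @param samples a `reef_samples` data frame.
#' @param path output path (CSV, UTF-8, '.' decimal).
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-zone summary of a sample table
#'
#' Mean percent cover of every taxon within each `zone` label (e.g. reef
#' crest / windward / leeward), plus point counts — the kind of per-region
#' abundance table a community-structure survey reports.
#'
#' @param samples a `reef_samples` data frame with a `zone` column.
#' @return A data frame with one row per zone: `zone`, `n`, then one mean
#'   cover column per taxon.
#' @export
zone_summary <- function(samples) {
  if (!"zone" %in% names(samples))
    stop("samples carry no 'zone' column")
  taxa <- sample_taxa(samples)
  zones <- sort(unique(samples$zone))
  out <- data.frame(zone = zones,
                    n = as.integer(table(samples$zone)[zones]))
  for (tx in taxa)
    out[[tx]] <- as.numeric(tapply(samples[[tx]], samples$zone, mean)[zones])
  out
}

#' Serialise a fitted variogram model to a config-style text file
#'
#' Writes a small YAML file holding the model family and parameters so a
#' fit can be frozen and reused across runs.
#'
#' @param model a [variogram_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variogram <- function(model, path) {
  stopifnot(inherits(model, "variogram_model"))
  yaml::write_yaml(list(model_type = model$model_type, nugget = model$nugget,
                        psill = model$psill, range = model$range), path)
  invisible(path)
}

#' Read a variogram model written by [write_variogram()]
#'
#' @param path path to the YAML file.
#' @return A [variogram_model()].
#' @export
read_variogram <- function(path) {
  v <- yaml::read_yaml(path)
  need <- c("model_type", "nugget", "psill", "range")
  if (!all(need %in% names(v)))
    stop("variogram file must define ", paste(need, collapse = ", "))
  variogram_model(v$model_type, v$nugget, v$psill, v$range)
}
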