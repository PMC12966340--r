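#' Occurrence record ingestion and spatio-temporal filtering
#'
#' A record set is a plain data frame of occurrence records (one row per
#' record) with canonical columns `species`, `lon`, `lat`, `date`, `count`,
#' `dataset`, plus a `provenance` attribute logging the source and every
#' filtering step applied.
#'
#' @name occurrence_io
NULL

#' Default Darwin-Core-style column mapping
#'
#' Maps accepted source header names onto the canonical fields. Both the
#' canonical dialect (`species, lon, lat, date, count, dataset`) and the
#' Darwin Core dialect (`scientificName, decimalLongitude, decimalLatitude,
#' eventDate, individualCount, datasetKey`) are recognised.
#'
#' @return named character vector: source header -> canonical field.
#' @export
default_column_map <- function() {
  c(species = "species", lon = "lon", lat = "lat", date = "date",
    count = "count", dataset = "dataset",
    scientificName = "species", decimalLongitude = "lon",
    decimalLatitude = "lat", eventDate = "date",
    individualCount = "count", datasetKey = "dataset")
}

record_set <- function(df, provenance = list()) {
  stopifnot(all(c("species", "lon", "lat", "date", "count", "dataset")
                %in% names(df)))
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("record_set", "data.frame")
  df
}

provenance <- function(rs) attr(rs, "provenance")

add_provenance <- function(rs, ...) {
  p <- c(attr(rs, "provenance"), list(...))
  attr(rs, "provenance") <- p
  rs
}

#' Read occurrence records from a CSV table
#'
#' Rows lacking coordinates or a parseable date are dropped (and counted in
#' the provenance log); a missing or non-positive individual count is imputed
#' as 1 — an occurrence implies at least one individual. Coordinates are
#' validated against WGS84 bounds.
#'
#' @param path CSV file with a header row.
#' @param column_map named character vector mapping source headers to the
#'   canonical fields (`species`, `lon`, `lat`, `date`, `count`, `dataset`);
#'   default accepts both canonical and Darwin Core headers.
#' @return a `record_set` data frame.
#' @export
read_occurrences <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("occurrence file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hits <- intersect(names(raw), names(column_map))
  df <- data.frame(species = NA_character_, lon = NA_real_, lat = NA_real_,
                   date = NA_character_, count = NA_real_,
                   dataset = NA_character_)[rep(1, nrow(raw)), , drop = FALSE]
  for (h in hits) df[[column_map[[h]]]] <- raw[[h]]
  needed <- c("species", "lon", "lat", "date")
  if (nrow(raw) > 0 && length(setdiff(needed, unname(column_map[hits]))) > 0) {
    stop("required columns not found in header: ",
         paste(setdiff(needed, unname(column_map[hits])), collapse = ", "),
         call. = FALSE)
  }
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  df$date <- suppressWarnings(as.Date(df$date))
  df$count <- suppressWarnings(as.numeric(df$count))
  df$species <- as.character(df$species)
  df$dataset <- as.character(df$dataset)

  n0 <- nrow(df)
  ok_coord <- !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  ok_date <- !is.na(df$date)
  ok_sp <- !is.na(df$species) & nzchar(df$species)
  keep <- ok_coord & ok_date & ok_sp
  df <- df[keep, , drop = FALSE]
  imputed <- sum(is.na(df$count) | df$count < 1)
  df$count[is.na(df$count) | df$count < 1] <- 1
  df$count <- as.numeric(df$count)
  if (nrow(df) == 0) stop("no valid occurrence rows in ", path, call. = FALSE)
  record_set(df, provenance = list(
    source = path, rows_read = n0,
    dropped_invalid = n0 - nrow(df), count_imputed = imputed))
}

#' Remove duplicate occurrence records
#'
#' Records sharing (species, dataset, lon, lat, date) are duplicates;
#' exactly one survives — the one with the largest individual count (first
#' occurrence on ties), so abundance signal is not lost. Idempotent.
#'
#' @param rs a `record_set`.
#' @return deduplicated `record_set`.
#' @export
deduplicate <- function(rs) {
  key <- paste(rs$species, rs$dataset, rs$lon, rs$lat, rs$date, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -rs$count)
  out <- rs[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  # restore first-appearance order of the surviving records
  out <- out[order(match(paste(out$species, out$dataset, out$lon, out$lat,
                               out$date, sep = "\r"), unique(key))), ,
             drop = FALSE]
  out <- record_set(as.data.frame(out), provenance(rs))
  add_provenance(out, deduplicated = nrow(rs) - nrow(out))
}

#' Assign spatial and temporal context to records
#'
#' Removes records outside every dataset polygon or outside the study time
#' frame, then annotates survivors with the containing `dataset` (first
#' polygon in configuration order wins if polygons overlap, with a warning),
#' the grid cell (`cell_x`, `cell_y`) at the configured resolution, and the
#' zero-based `time_unit` (calendar-year offset from the start of the time
#' frame).
#'
#' @param rs a `record_set`.
#' @param cfg a [study_config()] with non-empty `datasets`.
#' @return annotated, filtered `record_set`.
#' @export
assign_context <- function(rs, cfg) {
  if (length(cfg$datasets) == 0) stop("cfg$datasets is empty", call. = FALSE)
  n0 <- nrow(rs)
  in_time <- rs$date >= cfg$time_start & rs$date <= cfg$time_end
  df <- as.data.frame(rs)[in_time, , drop = FALSE]

  ids <- names(cfg$datasets)
  assigned <- rep(NA_character_, nrow(df))
  multi <- FALSE
  for (i in seq_along(cfg$datasets)) {
    inside <- points_in_polygon(df$lon, df$lat, cfg$datasets[[i]])
    clash <- inside & !is.na(assigned)
    if (any(clash)) multi <- TRUE
    take <- inside & is.na(assigned)
    assigned[take] <- ids[[i]]
  }
  if (multi) {
    warning("records inside overlapping polygons assigned to the first ",
            "dataset in configuration order", call. = FALSE)
  }
  keep <- !is.na(assigned)
  df <- df[keep, , drop = FALSE]
  df$dataset <- assigned[keep]
  ci <- cell_index(df$lon, df$lat, cfg$cell_resolution)
  df$cell_x <- ci[, "cell_x"]
  df$cell_y <- ci[, "cell_y"]
  df$time_unit <- time_unit_index(df$date, cfg)
  out <- record_set(df, provenance(rs))
  add_provenance(out, context_filtered = n0 - nrow(df))
}

#' Write / re-read a record set
#'
#' Round-trips all canonical fields (and context columns, if present)
#' through CSV.
#'
#' @param rs a `record_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path) {
  utils::write.csv(as.data.frame(rs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
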