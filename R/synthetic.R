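#' Synthetic occurrence data with planted commonness tiers
#'
#' Generates multi-dataset, multi-year occurrence tables whose species
#' belong to three planted commonness tiers. Each tier differs in exactly
#' the dimensions the commonness features measure: dataset-occupancy
#' probability (drives `InterDs`), records-per-year rate (`IntraDs`, `HF`),
#' individuals-per-record rate (`A`), occupied-cell fraction (`E`) and
#' active-year fraction (`F`). Datasets are axis-aligned rectangular
#' polygons. The planted tier labels stand in for expert reference
#' assessments in evaluation.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe a moderately imbalanced pool of 150 species (60 very
#' common, 50 fairly common, 40 rare — rare below the ~40% minority bound
#' that anomaly scoring assumes) observed over 20 one-degree-spaced
#' rectangular areas and a ten-year frame.
#'
#' @param n_datasets number of rectangular area polygons.
#' @param polygon_size rectangle side, degrees (0.1 deg = 10x10 grid cells
#'   at the default 0.01 deg resolution).
#' @param n_species named integer vector: species per tier.
#' @param occupancy per-tier probability that a species occupies a dataset.
#' @param records_per_year per-tier Poisson mean of records per active year
#'   in an occupied dataset.
#' @param individuals per-tier mean individuals per record (shifted
#'   Poisson: `1 + rpois(mean - 1)`).
#' @param cell_fraction per-tier fraction of a dataset's grid cells the
#'   species can occur in.
#' @param active_years per-tier fraction of the time frame's years in which
#'   the species is observable in an occupied dataset.
#' @param time_start,time_end time frame (default the 2016-2025 decade).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 20,
                       polygon_size = 0.1,
                       n_species = c(very_common = 60, fairly_common = 50,
                                     rare = 40),
                       occupancy = c(very_common = 0.9, fairly_common = 0.5,
                                     rare = 0.1),
                       records_per_year = c(very_common = 8,
                                            fairly_common = 3, rare = 1),
                       individuals = c(very_common = 5, fairly_common = 2,
                                       rare = 1),
                       cell_fraction = c(very_common = 0.6,
                                         fairly_common = 0.3, rare = 0.1),
                       active_years = c(very_common = 0.9,
                                        fairly_common = 0.5, rare = 0.2),
                       time_start = as.Date("2016-01-01"),
                       time_end = as.Date("2025-12-31"),
                       seed = 42L) {
  tiers <- c("very_common", "fairly_common", "rare")
  for (p in list(n_species, occupancy, records_per_year, individuals,
                 cell_fraction, active_years)) {
    stopifnot(setequal(names(p), tiers))
  }
  stopifnot(all(occupancy >= 0 & occupancy <= 1),
            all(cell_fraction > 0 & cell_fraction <= 1),
            all(active_years > 0 & active_years <= 1),
            all(records_per_year >= 0), all(individuals >= 1))
  structure(list(n_datasets = as.integer(n_datasets),
                 polygon_size = polygon_size,
                 n_species = n_species[tiers], occupancy = occupancy[tiers],
                 records_per_year = records_per_year[tiers],
                 individuals = individuals[tiers],
                 cell_fraction = cell_fraction[tiers],
                 active_years = active_years[tiers],
                 time_start = as.Date(time_start),
                 time_end = as.Date(time_end),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Rectangular dataset polygons: dataset i occupies [i, i + size) x [0, size).
sim_polygons <- function(scfg) {
  polys <- lapply(seq_len(scfg$n_datasets), function(i) {
    x0 <- i - 1
    close_ring(cbind(lon = c(x0, x0 + scfg$polygon_size,
                             x0 + scfg$polygon_size, x0),
                     lat = c(0, 0, scfg$polygon_size, scfg$polygon_size)))
  })
  names(polys) <- sprintf("DS%02d", seq_len(scfg$n_datasets))
  polys
}

#' Generate a synthetic occurrence record set
#'
#' For each species and dataset, the dataset is occupied with the tier's
#' occupancy probability; a tier-dependent subset of the dataset's grid
#' cells and of the frame's years is chosen once per species-dataset; each
#' active year contributes `rpois(records_per_year)` records placed
#' uniformly inside cells sampled from the subset, each with
#' `1 + rpois(individuals - 1)` individuals and a random date in the year.
#' Deterministic given `scfg$seed`.
#'
#' @param scfg a [sim_config()].
#' @return list: `records` (a `record_set`), `truth` (data frame `species`,
#'   `tier`), `cfg` (a matching [study_config()] with the generated
#'   polygons and seed), `sim_config`.
#' @export
generate_occurrences <- function(scfg = sim_config()) {
  polys <- sim_polygons(scfg)
  years <- seq(as.integer(format(scfg$time_start, "%Y")),
               as.integer(format(scfg$time_end, "%Y")))
  res_deg <- 0.01
  cells_per_side <- max(1L, round(scfg$polygon_size / res_deg))
  tiers <- names(scfg$n_species)
  species <- unlist(lapply(tiers, function(tr)
    sprintf("%s_sp%03d", tr, seq_len(scfg$n_species[[tr]]))))
  truth <- data.frame(
    species = species,
    tier = rep(tiers, times = unname(scfg$n_species)),
    stringsAsFactors = FALSE)

  rows <- with_seed(scfg$seed, {
    out <- vector("list", length(species))
    for (si in seq_along(species)) {
      sp <- species[si]; tr <- truth$tier[si]
      occ <- stats::runif(scfg$n_datasets) < scfg$occupancy[[tr]]
      sp_rows <- list()
      for (di in which(occ)) {
        n_cells_sub <- max(1L, ceiling(scfg$cell_fraction[[tr]] *
                                         cells_per_side^2))
        cell_ids <- sample.int(cells_per_side^2, n_cells_sub)
        n_active <- max(1L, ceiling(scfg$active_years[[tr]] * length(years)))
        yrs <- sort(sample(years, n_active))
        for (y in yrs) {
          n_rec <- stats::rpois(1, scfg$records_per_year[[tr]])
          if (n_rec == 0) next
          cid <- cell_ids[sample.int(n_cells_sub, n_rec, replace = TRUE)] - 1L
          cx <- cid %% cells_per_side
          cy <- cid %/% cells_per_side
          lon <- (di - 1) + (cx + stats::runif(n_rec)) * res_deg
          lat <- (cy + stats::runif(n_rec)) * res_deg
          day <- sample.int(365, n_rec, replace = TRUE) - 1L
          sp_rows[[length(sp_rows) + 1L]] <- data.frame(
            species = sp,
            lon = round(lon, 6), lat = round(lat, 6),
            date = as.Date(sprintf("%d-01-01", y)) + day,
            count = 1 + stats::rpois(n_rec,
                                     max(0, scfg$individuals[[tr]] - 1)),
            dataset = names(polys)[di],
            stringsAsFactors = FALSE)
        }
      }
      out[[si]] <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
    }
    out
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(species = character(), lon = numeric(), lat = numeric(),
                     date = as.Date(character()), count = numeric(),
                     dataset = character(), stringsAsFactors = FALSE)
  }
  cfg <- study_config(time_start = scfg$time_start, time_end = scfg$time_end,
                      cell_resolution = res_deg, datasets = polys,
                      seed = scfg$seed)
  list(records = record_set(df, provenance = list(source = "synthetic",
                                                  seed = scfg$seed)),
       truth = truth, cfg = cfg, sim_config = scfg)
}

#' Write a named fixture to disk
#'
#' Known fixtures:
#' * `"default"` — the full 150-species, 20-dataset, 10-year simulation.
#' * `"tiny"` — a hand-checkable single-species, 2-dataset set whose
#'   feature vector at `Thr = 3` is exactly
#'   `(A, IntraDs, InterDs, E, F, HF) = (2.0, 2.0, 0.5, 0.2, 0.2, 0.1)`.
#' * `"degenerate"` — all species identical, to exercise zero-variance and
#'   tie handling downstream.
#'
#' Writes `occurrences.csv`, `areas.geojson` and `truth.csv` under `dir`.
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @param seed seed for the stochastic fixtures.
#' @return list as from [generate_occurrences()], invisibly, with an added
#'   `paths` element.
#' @export
make_fixture <- function(name = c("default", "tiny", "degenerate"),
                         dir = tempfile("fixture"), seed = 42L) {
  name <- match.arg(name)
  gen <- switch(name,
    default = generate_occurrences(sim_config(seed = seed)),
    tiny = tiny_fixture(),
    degenerate = {
      sc <- sim_config(
        n_species = c(very_common = 12, fairly_common = 0, rare = 0),
        seed = seed)
      g <- generate_occurrences(sc)
      # collapse to identical species: every species gets species 1's records
      one <- g$records[g$records$species == g$truth$species[1], , drop = FALSE]
      reps <- lapply(g$truth$species, function(sp) {
        r <- one; r$species <- sp; r
      })
      g$records <- record_set(do.call(rbind, reps),
                              provenance = list(source = "synthetic-degenerate",
                                                seed = seed))
      g
    })
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- file.path(dir, "occurrences.csv")
  areas <- file.path(dir, "areas.geojson")
  tru <- file.path(dir, "truth.csv")
  write_records(gen$records, occ)
  write_areas_geojson(gen$cfg$datasets, areas)
  utils::write.csv(gen$truth, tru, row.names = FALSE, quote = FALSE)
  gen$paths <- c(occurrences = occ, areas = areas, truth = tru)
  invisible(gen)
}

# The hand-checkable example: dataset DS01 (10 x 1 cells) holds 4 records
# totalling 8 individuals in 2 cells, 3 records in 2016 and 1 in 2017 of a
# 2016-2025 frame; DS02 is empty.
tiny_fixture <- function() {
  polys <- list(
    DS01 = close_ring(cbind(c(0, 0.1, 0.1, 0), c(0, 0, 0.01, 0.01))),
    DS02 = close_ring(cbind(c(1, 1.1, 1.1, 1), c(0, 0, 0.01, 0.01))))
  df <- data.frame(
    species = "tiny_species",
    lon = c(0.005, 0.006, 0.015, 0.005),
    lat = rep(0.005, 4),
    date = as.Date(c("2016-05-01", "2016-06-01", "2016-07-01", "2017-05-01")),
    count = c(2, 2, 2, 2),
    dataset = "DS01",
    stringsAsFactors = FALSE)
  cfg <- study_config(time_start = as.Date("2016-01-01"),
                      time_end = as.Date("2025-12-31"),
                      cell_resolution = 0.01, hf_threshold = 3,
                      datasets = polys, seed = 1L)
  list(records = record_set(df, provenance = list(source = "tiny")),
       truth = data.frame(species = "tiny_species", tier = "very_common",
                          stringsAsFactors = FALSE),
       cfg = cfg, sim_config = NULL)
}

# Serialise polygons as a GeoJSON FeatureCollection with dataset_id
# properties.
write_areas_geojson <- function(polys, path) {
  feats <- lapply(names(polys), function(id) {
    ring <- lapply(seq_len(nrow(polys[[id]])), function(i)
      as.numeric(polys[[id]][i, ]))
    list(type = "Feature",
         properties = list(dataset_id = id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
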