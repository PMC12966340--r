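#' Per-species commonness features
#'
#' Six aggregative statistics computed per species from its context-assigned
#' occurrence records over the configured datasets, grid and time frame:
#'
#' * `A` (species abundance): per-dataset mean individuals per record,
#'   summed over the datasets where the species occurs (or averaged when
#'   `cfg$a_mean` is set).
#' * `IntraDs` (intra-dataset abundance): total records divided by the total
#'   number of datasets.
#' * `InterDs` (inter-dataset abundance): fraction of datasets with at least
#'   one record of the species.
#' * `E` (extent): mean, over occupied datasets, of the fraction of that
#'   dataset's grid cells holding at least one record.
#' * `F` (observation frequency): mean, over occupied datasets, of the
#'   fraction of time-units with at least one record.
#' * `HF` (high-observation frequency): as `F`, counting only time-units
#'   with at least `cfg$hf_threshold` records (strictly more when
#'   `cfg$hf_strict`).
#'
#' All six are 0 for a species with no records. `HF <= F` always;
#' `InterDs`, `E`, `F`, `HF` lie in `[0, 1]`.
#'
#' @param rs a `record_set` that has passed [assign_context()].
#' @param species scientific name to evaluate.
#' @param cfg a [study_config()].
#' @return named numeric vector `c(A, IntraDs, InterDs, E, F, HF)`.
#' @export
compute_features <- function(rs, species, cfg) {
  feat_names <- c("A", "IntraDs", "InterDs", "E", "F", "HF")
  n_ds <- length(cfg$datasets)
  if (n_ds == 0) stop("cfg$datasets is empty", call. = FALSE)
  n_tu <- n_time_units(cfg)
  sub <- rs[rs$species == species, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(stats::setNames(numeric(6), feat_names))
  }
  occ_ds <- split(seq_len(nrow(sub)), sub$dataset)  # occupied datasets only
  per_ds <- lapply(occ_ds, function(idx) {
    d <- sub[idx, , drop = FALSE]
    tu_counts <- table(d$time_unit)
    hf_units <- if (cfg$hf_strict) sum(tu_counts > cfg$hf_threshold)
                else sum(tu_counts >= cfg$hf_threshold)
    ds_cells <- polygon_cell_count(cfg$datasets[[d$dataset[1]]],
                                   cfg$cell_resolution)
    c(mean_ind = sum(d$count) / nrow(d),
      n_rec = nrow(d),
      e = length(unique(paste(d$cell_x, d$cell_y))) / ds_cells,
      f = length(tu_counts) / n_tu,
      hf = hf_units / n_tu)
  })
  m <- do.call(rbind, per_ds)
  A <- if (cfg$a_mean) mean(m[, "mean_ind"]) else sum(m[, "mean_ind"])
  stats::setNames(
    c(A,
      sum(m[, "n_rec"]) / n_ds,
      nrow(m) / n_ds,
      mean(m[, "e"]),
      mean(m[, "f"]),
      mean(m[, "hf"])),
    feat_names)
}

#' Build the species-data table
#'
#' One row per listed species, in list order; species absent from the
#' records get an all-zero raw feature vector. Standardized (`z_`-prefixed)
#' columns are appended by [standardize_features()].
#'
#' @param rs a context-assigned `record_set`.
#' @param species_list character vector of species names (no duplicates).
#' @param cfg a [study_config()].
#' @return data frame with columns `species`, `A`, `IntraDs`, `InterDs`,
#'   `E`, `F`, `HF` and the six `z_` columns.
#' @export
build_species_table <- function(rs, species_list, cfg) {
  if (length(species_list) == 0) stop("species_list is empty", call. = FALSE)
  if (anyDuplicated(species_list)) {
    stop("duplicate species names in species_list", call. = FALSE)
  }
  rows <- t(vapply(species_list, function(sp) compute_features(rs, sp, cfg),
                   numeric(6)))
  tab <- data.frame(species = species_list, rows, row.names = NULL,
                    check.names = FALSE)
  standardize_features(tab)
}

#' Standardize the feature columns
#'
#' Z-scores each feature column over species (sample standard deviation);
#' zero-variance columns standardize to all zeros. Raw values are retained;
#' standardized columns are prefixed `z_`. Requires at least two species.
#'
#' @param tab species-data table with raw feature columns.
#' @return the table with `z_` columns appended (replaced if present).
#' @export
standardize_features <- function(tab) {
  if (nrow(tab) < 2) {
    stop("standardisation needs at least two species", call. = FALSE)
  }
  for (f in feature_names()) {
    x <- tab[[f]]
    s <- stats::sd(x)
    tab[[paste0("z_", f)]] <- if (is.na(s) || s == 0) rep(0, length(x))
                              else (x - mean(x)) / s
  }
  tab
}

#' Names of the six features
#' @return character vector `c("A","IntraDs","InterDs","E","F","HF")`.
#' @export
feature_names <- function() c("A", "IntraDs", "InterDs", "E", "F", "HF")

# Standardized feature matrix (rows = species) for a subset of features.
z_matrix <- function(tab, features = feature_names()) {
  m <- as.matrix(tab[, paste0("z_", features), drop = FALSE])
  rownames(m) <- tab$species
  colnames(m) <- features
  m
}
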