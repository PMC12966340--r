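#' Study configuration
#'
#' Bundles the analysis parameters shared by every stage of the commonness
#' pipeline: the time frame and time-unit over which observation frequency is
#' assessed, the grid resolution used to quantify spatial extent, the
#' high-observation threshold, the area polygons ("datasets"), and the
#' cluster-number search range.
#'
#' @param time_start,time_end `Date` (or coercible) bounds of the analysis
#'   time frame; records outside are discarded. Defaults cover the past
#'   decade (2016-01-01 to 2025-12-31).
#' @param cell_resolution grid cell side, decimal degrees. Default 0.01
#'   (about 1 km), the resolution at which spatial extent `E` is measured.
#' @param hf_threshold minimum records per time-unit for that unit to count
#'   as "high-observation" in `HF`. Default 5.
#' @param hf_strict logical; if `FALSE` (default) a time-unit counts for `HF`
#'   when it holds at least `hf_threshold` records; if `TRUE` strictly more
#'   than `hf_threshold` are required.
#' @param datasets named list of polygons, one per dataset/area: each a
#'   two-column (lon, lat) numeric matrix of vertices. See [read_areas()].
#' @param time_unit currently only `"year"`: presence is assessed per
#'   calendar year.
#' @param k_min lower bound of the cluster-number sweep. Default 3, so the
#'   sweep can always distinguish rare / fairly common / very common.
#' @param unif_alpha significance level of the cluster-size uniformity test
#'   used by [multi_kmeans()]: the selected K* is the smallest K whose size
#'   distribution the chi-squared test does not reject at this level.
#'   Default 0.05.
#' @param n_classes number of commonness classes (quantile groups for the
#'   VAE). Default 3.
#' @param a_mean logical; if `TRUE` the abundance feature `A` is averaged
#'   over occupied datasets instead of summed. Default `FALSE` (the summed
#'   form).
#' @param seed integer master seed; each stochastic stage derives its own
#'   seed from it by a fixed offset.
#' @param kmeans_restarts,kmeans_max_iter K-means restarts per K and Lloyd
#'   iteration cap.
#' @param vae options list, see [vae_defaults()].
#'
#' @return an object of class `study_config`.
#' @export
study_config <- function(time_start = as.Date("2016-01-01"),
                         time_end = as.Date("2025-12-31"),
                         cell_resolution = 0.01,
                         hf_threshold = 5,
                         hf_strict = FALSE,
                         datasets = list(),
                         time_unit = "year",
                         k_min = 3,
                         unif_alpha = 0.05,
                         n_classes = 3,
                         a_mean = FALSE,
                         seed = 1L,
                         kmeans_restarts = 10,
                         kmeans_max_iter = 300,
                         vae = vae_defaults()) {
  time_start <- as.Date(time_start)
  time_end <- as.Date(time_end)
  stopifnot(time_start < time_end, cell_resolution > 0,
            hf_threshold >= 1, k_min >= 2, n_classes >= 2)
  time_unit <- match.arg(time_unit, "year")
  cfg <- list(
    time_start = time_start, time_end = time_end,
    cell_resolution = cell_resolution,
    hf_threshold = hf_threshold, hf_strict = hf_strict,
    datasets = datasets, time_unit = time_unit,
    k_min = as.integer(k_min), unif_alpha = unif_alpha,
    n_classes = as.integer(n_classes),
    a_mean = isTRUE(a_mean), seed = as.integer(seed),
    kmeans_restarts = as.integer(kmeans_restarts),
    kmeans_max_iter = as.integer(kmeans_max_iter),
    vae = utils::modifyList(vae_defaults(), vae)
  )
  class(cfg) <- "study_config"
  cfg
}

#' Default VAE hyperparameters
#'
#' Declared defaults for the variational-autoencoder architecture search and
#' optimiser: the growth search starts at two hidden layers of width 2 and
#' adds one node at a time (cap 8 per layer); latent dimensionality is swept
#' from 1 up to the feature dimensionality; training is full-batch Adam
#' with a fixed base step and epoch budget.
#'
#' @param start_widths integer(2), initial hidden-layer widths.
#' @param max_width per-layer width cap for the growth search.
#' @param latent_dims candidate latent dimensionalities (capped at the input
#'   dimension at fit time).
#' @param epochs full-batch gradient steps per candidate training.
#' @param lr fixed base learning rate for the Adam updates.
#' @param grow_tol minimum improvement in mean reconstruction log-probability
#'   (nats) for a grown architecture to be accepted.
#' @param search_samples Monte-Carlo posterior samples used to score
#'   candidate architectures during the search.
#' @param score_samples posterior samples for the final per-species scores.
#' @return a named list of options.
#' @export
vae_defaults <- function(start_widths = c(2L, 2L), max_width = 8L,
                         latent_dims = 1:6, epochs = 500L, lr = 0.01,
                         grow_tol = 1e-3, search_samples = 20L,
                         score_samples = 100L) {
  list(start_widths = as.integer(start_widths), max_width = as.integer(max_width),
       latent_dims = as.integer(latent_dims), epochs = as.integer(epochs),
       lr = lr, grow_tol = grow_tol,
       search_samples = as.integer(search_samples),
       score_samples = as.integer(score_samples))
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  time frame : %s .. %s (unit: %s, %d units)\n",
              x$time_start, x$time_end, x$time_unit, n_time_units(x)))
  cat(sprintf("  resolution : %g deg; HF threshold: %d (%s)\n",
              x$cell_resolution, x$hf_threshold,
              if (x$hf_strict) "strict >" else ">="))
  cat(sprintf("  datasets   : %d polygon(s)\n", length(x$datasets)))
  cat(sprintf("  K sweep    : from %d; classes: %d; seed: %d\n",
              x$k_min, x$n_classes, x$seed))
  invisible(x)
}

# Number of one-year time-units: calendar years from the year of time_start
# through the year of time_end, inclusive.
n_time_units <- function(cfg) {
  y0 <- as.integer(format(cfg$time_start, "%Y"))
  y1 <- as.integer(format(cfg$time_end, "%Y"))
  y1 - y0 + 1L
}

time_unit_index <- function(dates, cfg) {
  y0 <- as.integer(format(cfg$time_start, "%Y"))
  as.integer(format(as.Date(dates), "%Y")) - y0
}
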