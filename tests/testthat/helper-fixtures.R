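# Shared fixtures, built in code. Expensive objects (the default synthetic
# run) are computed once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The hand-checkable 2-dataset, 1-species record set.
tiny_fx <- function() cached("tiny", prevcommon:::tiny_fixture())

# The default 150-species simulation at seed 42, with context assigned and
# the species table built.
default_fx <- function() {
  cached("default", {
    g <- generate_occurrences(sim_config(seed = 42L))
    rs <- assign_context(deduplicate(g$records), g$cfg)
    tab <- build_species_table(rs, g$truth$species, g$cfg)
    list(gen = g, rs = rs, tab = tab,
         truth = stats::setNames(g$truth$tier, g$truth$species))
  })
}

# Full three-model assessment of the default fixture (shared by the
# end-to-end and sensitivity tests).
default_assessment <- function() {
  cached("assessment", {
    fx <- default_fx()
    assess_commonness(fx$tab, fx$gen$cfg)
  })
}

# Small record set builder for unit tests.
make_rs <- function(df) {
  prevcommon:::record_set(df)
}

# Well-separated Gaussian blobs along the diagonal: m points per group.
make_blobs <- function(seed, m = 20, K = 3, d = 6, sep = 8, s = 0.5) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(K), function(k)
    matrix(stats::rnorm(m * d, mean = sep * k, sd = s), m, d)))
}

# Naive, direct evaluation of the six feature formulas over a
# context-assigned record set -- the independent oracle for
# compute_features. Written as literal sums over datasets, kept free of the
# package's aggregation code path.
naive_features <- function(rs, species, cfg) {
  sub <- rs[rs$species == species, , drop = FALSE]
  n_ds <- length(cfg$datasets)
  n_tu <- prevcommon:::n_time_units(cfg)
  if (nrow(sub) == 0) return(c(A = 0, IntraDs = 0, InterDs = 0, E = 0,
                               F = 0, HF = 0))
  ds_occ <- unique(sub$dataset)
  a <- 0; e <- 0; f <- 0; hf <- 0
  for (ds in ds_occ) {
    d <- sub[sub$dataset == ds, , drop = FALSE]
    a <- a + sum(d$count) / nrow(d)
    n_cells <- prevcommon:::polygon_cell_count(cfg$datasets[[ds]],
                                               cfg$cell_resolution)
    e <- e + length(unique(paste(d$cell_x, d$cell_y))) / n_cells
    yrs_with <- 0; yrs_high <- 0
    for (tu in unique(d$time_unit)) {
      cnt <- sum(d$time_unit == tu)
      yrs_with <- yrs_with + 1
      high <- if (cfg$hf_strict) cnt > cfg$hf_threshold
              else cnt >= cfg$hf_threshold
      if (high) yrs_high <- yrs_high + 1
    }
    f <- f + yrs_with / n_tu
    hf <- hf + yrs_high / n_tu
  }
  c(A = if (cfg$a_mean) a / length(ds_occ) else a,
    IntraDs = nrow(sub) / n_ds,
    InterDs = length(ds_occ) / n_ds,
    E = e / length(ds_occ),
    F = f / length(ds_occ),
    HF = hf / length(ds_occ))
}

# Random small record set over rectangular datasets, for the
# oracle-equivalence property test.
random_small_rs <- function(seed, n_max = 50) {
  set.seed(seed)
  n_ds <- sample(2:4, 1)
  polys <- lapply(seq_len(n_ds), function(i) {
    x0 <- i - 1
    cbind(c(x0, x0 + 0.05, x0 + 0.05, x0), c(0, 0, 0.03, 0.03))
  })
  names(polys) <- paste0("D", seq_len(n_ds))
  cfg <- study_config(time_start = as.Date("2020-01-01"),
                      time_end = as.Date("2023-12-31"),
                      cell_resolution = 0.01, hf_threshold = 2,
                      datasets = polys, seed = seed)
  n <- sample(5:n_max, 1)
  sp <- sample(c("sp1", "sp2", "sp3"), n, replace = TRUE)
  di <- sample(n_ds, n, replace = TRUE)
  df <- data.frame(
    species = sp,
    lon = (di - 1) + runif(n, 0.001, 0.049),
    lat = runif(n, 0.001, 0.029),
    date = as.Date("2020-01-01") + sample.int(4 * 365, n, replace = TRUE) - 1,
    count = sample(1:6, n, replace = TRUE),
    dataset = paste0("D", di),
    stringsAsFactors = FALSE)
  list(rs = assign_context(deduplicate(make_rs(df)), cfg), cfg = cfg)
}
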