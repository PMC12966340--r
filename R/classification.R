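#' Quartile-based commonness classification
#'
#' Cluster (or VAE quantile-group) centroids are labelled feature-by-feature
#' against the 25th/75th percentiles of each feature across all species:
#' `H` (high) strictly above the 75th percentile, `L` (low) strictly below
#' the 25th, `M` (medium) otherwise — values exactly at a percentile are
#' `M`. A centroid whose `H` labels strictly outnumber both `M` and `L`
#' marks a high-commonness cluster (species become "very common");
#' a strict `L` majority marks a low-commonness cluster ("rare"); all other
#' clusters are medium ("fairly common").
#'
#' @name commonness_classification
NULL

#' Per-feature quartiles across all species
#'
#' @param tab species-data table (with `z_` columns).
#' @param features feature subset (default all six).
#' @return matrix with rows `p25`, `p75`, one column per feature, computed
#'   on the standardized values with the linear-interpolation quantile
#'   convention.
#' @export
feature_quartiles <- function(tab, features = feature_names()) {
  Z <- z_matrix(tab, features)
  apply(Z, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
        type = 7) |>
    (\(m) {rownames(m) <- c("p25", "p75"); m})()
}

#' Label a centroid H/M/L per feature
#'
#' @param centroid numeric vector in standardized feature space.
#' @param q quartile matrix from [feature_quartiles()] (same features, same
#'   order).
#' @return character vector of labels in `{"H","M","L"}` with attribute
#'   `counts` = `c(nH, nM, nL)`.
#' @export
label_centroid <- function(centroid, q) {
  stopifnot(length(centroid) == ncol(q))
  lab <- ifelse(centroid > q["p75", ], "H",
                ifelse(centroid < q["p25", ], "L", "M"))
  attr(lab, "counts") <- c(nH = sum(lab == "H"), nM = sum(lab == "M"),
                           nL = sum(lab == "L"))
  lab
}

#' Commonness class of a labelled centroid
#'
#' Strict dominance: high iff `nH > nM` and `nH > nL`; low iff `nL > nM`
#' and `nL > nH`; everything else (including ties) is medium.
#'
#' @param labels output of [label_centroid()] (or a named count vector
#'   `c(nH=, nM=, nL=)`).
#' @return one of `"very_common"`, `"fairly_common"`, `"rare"`.
#' @export
classify_cluster <- function(labels) {
  cnt <- if (is.character(labels)) attr(labels, "counts") %||%
           c(nH = sum(labels == "H"), nM = sum(labels == "M"),
             nL = sum(labels == "L")) else labels
  if (cnt[["nH"]] > cnt[["nM"]] && cnt[["nH"]] > cnt[["nL"]]) "very_common"
  else if (cnt[["nL"]] > cnt[["nM"]] && cnt[["nL"]] > cnt[["nH"]]) "rare"
  else "fairly_common"
}

#' Gradient prevalence score of a labelled centroid
#'
#' Extended commonness gradient: counts of high- and low-valued features
#' move the score away from the uninformative midpoint in steps of 0.05,
#' `score = 0.5 + 0.05 (nH - nL)`, clipped to `[0.2, 0.8]`. An all-H
#' centroid scores 0.8, all-L scores 0.2, all-M scores 0.5.
#'
#' @inheritParams classify_cluster
#' @return prevalence probability on the 0.05 lattice in `[0.2, 0.8]`.
#' @export
gradient_score <- function(labels) {
  cnt <- if (is.character(labels)) attr(labels, "counts") %||%
           c(nH = sum(labels == "H"), nM = sum(labels == "M"),
             nL = sum(labels == "L")) else labels
  min(0.8, max(0.2, 0.5 + 0.05 * (cnt[["nH"]] - cnt[["nL"]])))
}

#' Classify species from a clustering
#'
#' Labels each cluster centroid against the all-species feature quartiles
#' and classifies it; every species inherits its cluster's class (and
#' gradient score). Empty commonness classes are permitted: if no cluster
#' has an `L` majority the output contains no rare species.
#'
#' @param tab species-data table.
#' @param clustering a `pc_cluster_result` (or `pc_clustering`) fitted on
#'   the standardized features of `tab`.
#' @param features feature subset used for the fit.
#' @return data frame `species`, `cluster`, `class`, `gradient` (one row
#'   per species, in table order).
#' @export
classify_from_clustering <- function(tab, clustering,
                                     features = feature_names()) {
  cl <- if (inherits(clustering, "pc_cluster_result")) clustering$best
        else clustering
  q <- feature_quartiles(tab, features)
  per_cluster <- lapply(seq_len(cl$K), function(k) {
    lab <- label_centroid(cl$centroids[k, ], q)
    list(class = classify_cluster(lab), gradient = gradient_score(lab))
  })
  data.frame(
    species = tab$species,
    cluster = cl$assignments,
    class = vapply(per_cluster, `[[`, character(1), "class")[cl$assignments],
    gradient = vapply(per_cluster, `[[`, numeric(1), "gradient")[cl$assignments],
    stringsAsFactors = FALSE)
}

#' Classify species from VAE quantile groups
#'
#' Computes the centroid of the standardized feature vectors inside each
#' reconstruction-score quantile group and applies the same quartile
#' labelling and dominance classification as for clusters; species inherit
#' their group's class. Empty groups are skipped (logged).
#'
#' @param tab species-data table.
#' @param groups integer group indices from [quantile_groups()] (aligned
#'   with `tab` rows).
#' @param features feature subset in use.
#' @return data frame `species`, `group`, `class`, `gradient`.
#' @export
classify_from_vae <- function(tab, groups, features = feature_names()) {
  Z <- z_matrix(tab, features)
  q <- feature_quartiles(tab, features)
  gs <- sort(unique(groups))
  cls <- grad <- stats::setNames(vector("list", length(gs)), gs)
  for (g in gs) {
    members <- groups == g
    centroid <- colMeans(Z[members, , drop = FALSE])
    lab <- label_centroid(centroid, q)
    cls[[as.character(g)]] <- classify_cluster(lab)
    grad[[as.character(g)]] <- gradient_score(lab)
  }
  data.frame(
    species = tab$species,
    group = groups,
    class = unlist(cls)[as.character(groups)],
    gradient = unlist(grad)[as.character(groups)],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Majority ensemble of the three model classifications
#'
#' Per species, the class assessed by the majority of the three models
#' wins; with no strict majority (all three distinct) the ensemble defaults
#' to "fairly_common".
#'
#' @param l1,l2,l3 character vectors of per-species classes (same order).
#' @return character vector of ensemble classes.
#' @export
ensemble_class <- function(l1, l2, l3) {
  stopifnot(length(l1) == length(l2), length(l2) == length(l3))
  assert_classes(c(l1, l2, l3))
  mapply(function(a, b, c) {
    tab <- sort(table(c(a, b, c)), decreasing = TRUE)
    if (tab[1] >= 2) names(tab)[1] else "fairly_common"
  }, l1, l2, l3, USE.NAMES = FALSE)
}

#' Map commonness classes to prevalence probabilities
#'
#' The three classes anchor the prevalence prior used as a multiplicative
#' likelihood weight in Bayesian niche models: rare 0.2 (conservative),
#' fairly common 0.5 (uninformative), very common 0.8 (permissive; the cap
#' below 1 encodes residual uncertainty).
#'
#' @param class character vector of classes.
#' @return numeric vector of probabilities in `{0.2, 0.5, 0.8}`.
#' @export
map_prevalence <- function(class) {
  assert_classes(class, "class")
  c(rare = 0.2, fairly_common = 0.5, very_common = 0.8)[class] |> unname()
}

#' Enumerate the extended-gradient prevalence lattice
#'
#' All attainable gradient scores over the (nH, nM, nL) label-count
#' compositions of `n_features` features.
#'
#' @param n_features number of features (default 6).
#' @return data frame `nH`, `nM`, `nL`, `score`.
#' @export
gradient_lattice <- function(n_features = 6) {
  combos <- expand.grid(nH = 0:n_features, nL = 0:n_features)
  combos <- combos[combos$nH + combos$nL <= n_features, ]
  combos$nM <- n_features - combos$nH - combos$nL
  combos$score <- mapply(function(h, m, l)
    gradient_score(c(nH = h, nM = m, nL = l)),
    combos$nH, combos$nM, combos$nL)
  combos[, c("nH", "nM", "nL", "score")]
}
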