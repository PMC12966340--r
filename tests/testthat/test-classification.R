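test_that("feature quartiles follow the linear-interpolation convention", {
  tab <- data.frame(species = letters[1:8], A = 1:8, IntraDs = 1:8,
                    InterDs = 1:8, E = 1:8, F = 1:8, HF = rep(5, 8))
  tab <- standardize_features(tab)
  q <- feature_quartiles(tab)
  # raw 1..8 has p25 = 2.75, p75 = 6.25; on the z scale that is the same
  # affine image
  zA <- tab$z_A
  expect_equal(q["p25", "A"], unname(quantile(zA, 0.25)))
  expect_equal(q["p75", "A"], unname(quantile(zA, 0.75)))
  expect_equal((q["p25", "A"] * sd(1:8)) + mean(1:8), 2.75)
  expect_equal((q["p75", "A"] * sd(1:8)) + mean(1:8), 6.25)
  # constant feature: p25 = p75 (here 0 on the z scale)
  expect_equal(q["p25", "HF"], q["p75", "HF"])
  # permutation invariance
  tab2 <- standardize_features(tab[sample(8), ])
  expect_equal(feature_quartiles(tab2), q)
})

test_that("centroid labelling uses strict inequalities with boundary values medium", {
  q <- rbind(p25 = rep(-1, 6), p75 = rep(1, 6))
  colnames(q) <- feature_names()
  lab <- label_centroid(rep(2, 6), q)
  expect_equal(unname(attr(lab, "counts")), c(6L, 0L, 0L))
  # exactly at p75 -> M; exactly at p25 -> M
  lab2 <- label_centroid(c(1, -1, 0, 2, -2, 0.5), q)
  expect_equal(as.vector(lab2), c("M", "M", "M", "H", "L", "M"))
  # element-wise comparison oracle on a random centroid
  set.seed(4)
  cen <- runif(6, -2, 2)
  lab3 <- label_centroid(cen, q)
  expect_equal(as.vector(lab3),
               ifelse(cen > 1, "H", ifelse(cen < -1, "L", "M")))
})

test_that("cluster classification applies the strict dominance rule", {
  expect_equal(classify_cluster(c(nH = 4, nM = 1, nL = 1)), "very_common")
  expect_equal(classify_cluster(c(nH = 2, nM = 2, nL = 2)), "fairly_common")
  expect_equal(classify_cluster(c(nH = 1, nM = 2, nL = 3)), "rare")
  expect_equal(classify_cluster(c(nH = 3, nM = 3, nL = 0)), "fairly_common")
  expect_equal(classify_cluster(c(nH = 0, nM = 0, nL = 6)), "rare")
  # invariant to feature order: counts, not positions, decide
  q <- rbind(p25 = rep(-1, 6), p75 = rep(1, 6))
  colnames(q) <- feature_names()
  cen <- c(2, 2, 2, 0, 0, -2)
  for (perm in list(1:6, 6:1, c(3, 1, 4, 2, 6, 5))) {
    expect_equal(classify_cluster(label_centroid(cen[perm], q)),
                 "very_common")
  }
})

test_that("gradient scores span the 0.05 lattice and agree with the anchors", {
  expect_equal(gradient_score(c(nH = 6, nM = 0, nL = 0)), 0.8)
  expect_equal(gradient_score(c(nH = 0, nM = 0, nL = 6)), 0.2)
  expect_equal(gradient_score(c(nH = 0, nM = 6, nL = 0)), 0.5)
  expect_equal(gradient_score(c(nH = 3, nM = 3, nL = 0)), 0.65)
  lat <- gradient_lattice(6)
  scores <- sort(unique(lat$score))
  expect_equal(scores, seq(0.2, 0.8, by = 0.05))
  expect_true(all(abs(diff(scores) - 0.05) < 1e-12))
  # anchors coincide with the 3-class prevalence mapping
  expect_equal(gradient_score(c(nH = 6, nM = 0, nL = 0)),
               map_prevalence("very_common"))
  expect_equal(gradient_score(c(nH = 0, nM = 6, nL = 0)),
               map_prevalence("fairly_common"))
  expect_equal(gradient_score(c(nH = 0, nM = 0, nL = 6)),
               map_prevalence("rare"))
  # monotone in nH - nL
  diffs <- lat$nH - lat$nL
  expect_true(all(diff(lat$score[order(diffs)]) >= 0))
})

test_that("species inherit their cluster's class; empty classes are possible", {
  tab <- default_fx()$tab
  res <- default_assessment()
  cl <- classify_from_clustering(tab, res$multikmeans)
  expect_equal(nrow(cl), nrow(tab))
  # all members of one cluster share a class
  for (k in unique(cl$cluster)) {
    expect_equal(length(unique(cl$class[cl$cluster == k])), 1)
  }
  # planted-tier recovery through the clustering route
  truth <- default_fx()$truth[tab$species]
  expect_gte(accuracy(cl$class, unname(truth)), 0.85)

  # a clustering with no L-majority centroid yields no rare species
  tab2 <- data.frame(species = letters[1:8], A = 1:8, IntraDs = 1:8,
                     InterDs = 1:8, E = 1:8, F = 1:8, HF = 1:8)
  tab2 <- standardize_features(tab2)
  fake <- structure(list(K = 1, assignments = rep(1L, 8),
                         centroids = matrix(0, 1, 6), sse = 0,
                         sizes = 8L), class = "pc_clustering")
  cl2 <- classify_from_clustering(tab2, fake)
  expect_false("rare" %in% cl2$class)
})

test_that("vae group classification mirrors the cluster procedure", {
  v <- c(0, 1, 0, 1, 5, 6, 5, 6, 10, 11, 10, 11)  # tiered with spread
  tab <- data.frame(species = sprintf("s%02d", 1:12),
                    A = v, IntraDs = v, InterDs = v / 11,
                    E = v / 11, F = v / 11, HF = v / 11)
  tab <- standardize_features(tab)
  groups <- rep(1:3, each = 4)
  cl <- classify_from_vae(tab, groups)
  expect_equal(unique(cl$class[cl$group == 1]), "rare")
  expect_equal(unique(cl$class[cl$group == 2]), "fairly_common")
  expect_equal(unique(cl$class[cl$group == 3]), "very_common")
  # group classes need not be distinct
  cl2 <- classify_from_vae(tab, rep(c(1, 3), 6))
  expect_lte(length(unique(cl2$class)), 2)
})

test_that("the ensemble takes strict majorities and defaults to fairly common", {
  expect_equal(ensemble_class("very_common", "very_common", "rare"),
               "very_common")
  expect_equal(ensemble_class("very_common", "fairly_common", "rare"),
               "fairly_common")
  expect_equal(ensemble_class("rare", "rare", "rare"), "rare")
  expect_equal(ensemble_class(c("rare", "very_common"),
                              c("rare", "rare"),
                              c("fairly_common", "rare")),
               c("rare", "rare"))
})

test_that("prevalence mapping fixes the three anchors", {
  expect_equal(map_prevalence("rare"), 0.2)
  expect_equal(map_prevalence("fairly_common"), 0.5)
  expect_equal(map_prevalence("very_common"), 0.8)
  expect_equal(map_prevalence(c("rare", "very_common")), c(0.2, 0.8))
  expect_error(map_prevalence("common"), "alphabet")
})
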