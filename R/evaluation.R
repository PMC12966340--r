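#' Agreement evaluation against reference labels
#'
#' Tools to compare model commonness assessments with reference labels
#' (expert assessments or planted simulation truth): binary merging,
#' two-rater consensus, accuracy, Cohen's kappa, confusion matrices and a
#' leave-one-out feature sensitivity harness.
#'
#' @name evaluation
NULL

#' Merge the three-class labels to the binary assessment
#'
#' Distinguishes "very common" from everything else: rare and fairly common
#' merge into "less_common". Idempotent.
#'
#' @param labels character vector of classes (3-class alphabet or already
#'   binarized).
#' @return character vector over `{"very_common", "less_common"}`.
#' @export
binarize <- function(labels) {
  bad <- setdiff(unique(labels), c(canonical_classes(), "less_common"))
  if (length(bad) > 0) stop("unknown labels: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  ifelse(labels == "very_common", "very_common", "less_common")
}

#' Consensus of two reference labelings
#'
#' Built with the same consensus rule as the model ensemble: where the two
#' raters agree, the agreed class; where they disagree (no majority among
#' two), the moderate "fairly_common" default.
#'
#' @param ref1,ref2 character vectors of classes over the same species, in
#'   the same order (or named; names are matched when both are named).
#' @return character vector of consensus classes.
#' @export
reference_consensus <- function(ref1, ref2) {
  if (!is.null(names(ref1)) && !is.null(names(ref2))) {
    if (!setequal(names(ref1), names(ref2))) {
      stop("reference labelings cover different species sets", call. = FALSE)
    }
    ref2 <- ref2[names(ref1)]
  } else if (length(ref1) != length(ref2)) {
    stop("reference labelings have different lengths", call. = FALSE)
  }
  assert_classes(c(ref1, ref2), "reference labels")
  out <- ifelse(ref1 == ref2, ref1, "fairly_common")
  names(out) <- names(ref1)
  out
}

#' Classification accuracy
#'
#' Fraction of species assessed identically by the two labelings.
#'
#' @param pred,ref character vectors over the same species, same order.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  if (length(pred) == 0) stop("empty labelings", call. = FALSE)
  mean(pred == ref)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the two labelings'
#' marginals (unweighted, nominal classes). When `p_e = 1` (both raters
#' constant on the same class) kappa is defined as 1 if the labelings agree
#' everywhere and 0 otherwise (logged).
#'
#' @inheritParams accuracy
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  lv <- sort(unique(c(pred, ref)))
  n <- length(pred)
  po <- mean(pred == ref)
  pe <- sum((table(factor(pred, lv)) / n) * (table(factor(ref, lv)) / n))
  if (pe >= 1 - .Machine$double.eps^0.5) {
    pc_log("degenerate marginals (p_e = 1): kappa set to %d", as.integer(po == 1))
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Agreement report
#'
#' Confusion matrix, accuracy and Cohen's kappa of a prediction against a
#' reference.
#'
#' @inheritParams accuracy
#' @return list of class `pc_agreement`: `confusion`, `accuracy`, `kappa`,
#'   `n`.
#' @export
agreement_report <- function(pred, ref) {
  lv <- sort(unique(c(pred, ref)))
  cm <- table(pred = factor(pred, lv), ref = factor(ref, lv))
  structure(list(confusion = cm, accuracy = accuracy(pred, ref),
                 kappa = cohens_kappa(pred, ref), n = length(pred)),
            class = "pc_agreement")
}

#' @export
print.pc_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d species: accuracy %.3f, kappa %.3f\n",
              x$n, x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out feature sensitivity
#'
#' Reruns the full modelling and classification pipeline six times, each
#' time with one feature excluded (same seeds as the full run, so
#' differences reflect the feature and not sampling noise), and reports the
#' ensemble's accuracy and kappa against the reference in both the
#' three-class and binary settings, with relative percentage changes
#' `(metric_loo - metric_full) / metric_full * 100` against the full-feature
#' baseline. Features are ranked by kappa loss in the three-class setting.
#'
#' @param tab species-data table (raw + standardized features).
#' @param reference named character vector of reference classes (names =
#'   species) or unnamed in table order.
#' @param cfg a [study_config()].
#' @param full optional precomputed full-feature [assess_commonness()]
#'   result (recomputed when missing).
#' @return data frame of class `pc_sensitivity`, one row per excluded
#'   feature: metrics, relative changes and kappa-loss rank.
#' @export
leave_one_out_sensitivity <- function(tab, reference, cfg, full = NULL) {
  reference <- align_reference(reference, tab$species)
  if (is.null(full)) full <- assess_commonness(tab, cfg)
  base <- eval_metrics(full$table$EnsembleClass, reference)
  rows <- lapply(feature_names(), function(drop) {
    feats <- setdiff(feature_names(), drop)
    res <- assess_commonness(tab, cfg, features = feats)
    m <- eval_metrics(res$table$EnsembleClass, reference)
    data.frame(excluded = drop,
               accuracy3 = m$acc3, kappa3 = m$kap3,
               accuracy2 = m$acc2, kappa2 = m$kap2,
               d_accuracy3 = rel_change(m$acc3, base$acc3),
               d_kappa3 = rel_change(m$kap3, base$kap3),
               d_accuracy2 = rel_change(m$acc2, base$acc2),
               d_kappa2 = rel_change(m$kap2, base$kap2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_kappa3 <- rank(out$d_kappa3, ties.method = "first")
  attr(out, "baseline") <- base
  class(out) <- c("pc_sensitivity", "data.frame")
  out
}

eval_metrics <- function(pred, ref) {
  list(acc3 = accuracy(pred, ref), kap3 = cohens_kappa(pred, ref),
       acc2 = accuracy(binarize(pred), binarize(ref)),
       kap2 = cohens_kappa(binarize(pred), binarize(ref)))
}

rel_change <- function(x, base) {
  if (base == 0) return(NA_real_)
  (x - base) / base * 100
}

align_reference <- function(reference, species) {
  if (!is.null(names(reference))) {
    miss <- setdiff(species, names(reference))
    if (length(miss) > 0) {
      stop("reference labels missing for: ", paste(utils::head(miss, 5),
                                                   collapse = ", "),
           call. = FALSE)
    }
    reference <- reference[species]
  } else if (length(reference) != length(species)) {
    stop("unnamed reference must match the species table length", call. = FALSE)
  }
  assert_classes(reference, "reference")
  unname(reference)
}
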