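## Per-accession heterozygosity and SNP-based ploidy prediction from
## five-cluster array call profiles.
##
## On the five-cluster scale the homozygous classes are 0 (nulliplex) and
## 4 (quadruplex) for every accession regardless of biological ploidy: a
## diploid's AB cluster is called as duplex (class 2) and a triploid's
## 1/3 and 2/3 allele ratios land in the simplex and triplex classes.
## Ploidy prediction exploits exactly these signatures.

#' Percent heterozygosity of a call vector
#'
#' 100 x (calls strictly between the homozygous classes) / (called loci).
#' `scale` is the upper homozygous class of the encoding: 4 for
#' five-cluster array calls (for every accession, whatever its ploidy),
#' 2 for three-cluster diploid calls, or the biological ploidy when the
#' vector holds true B-copy dosages.
#'
#' @param calls Integer call vector (`NA` missing).
#' @param scale Upper homozygous class; default 4.
#' @return Percent in \[0,100\], or `NA` if no locus is called.
#' @examples
#' heterozygosity(c(0L, 4L, 2L, 0L, 4L, 1L), 4) # 33.3
#' @export
heterozygosity <- function(calls, scale = 4L) {
  called <- !is.na(calls)
  if (!any(called)) return(NA_real_)
  100 * sum(calls[called] > 0L & calls[called] < scale) / sum(called)
}

#' Dosage-class profile of a call vector
#'
#' Exact counts per call class plus the derived fractions driving ploidy
#' prediction: `het_fraction` (calls strictly between the homozygous
#' classes among called loci), `simplex_triplex_share` (classes 1 and 3
#' among heterozygous calls) and `duplex_share` (class 2 among
#' heterozygous calls).
#'
#' @param calls Integer five-cluster call vector.
#' @param scale Upper class of the encoding; default 4.
#' @return List of class `"call_class_profile"` with `counts` (named,
#'   classes 0..scale), `n_called`, `n_missing`, `het_fraction`,
#'   `simplex_triplex_share`, `duplex_share`.
#' @export
call_class_profile <- function(calls, scale = 4L) {
  counts <- vapply(0:scale, function(cl) sum(!is.na(calls) & calls == cl),
                   integer(1))
  names(counts) <- as.character(0:scale)
  n_called <- sum(counts)
  het_classes <- seq.int(1L, scale - 1L)
  n_het <- sum(counts[as.character(het_classes)])
  st <- if (scale == 4L) sum(counts[c("1", "3")]) else NA_integer_
  dup <- if (scale == 4L) counts[["2"]] else NA_integer_
  structure(list(counts = counts, n_called = n_called,
                 n_missing = sum(is.na(calls)),
                 het_fraction = if (n_called) n_het / n_called else NA_real_,
                 simplex_triplex_share = if (!is.na(st) && n_het)
                   st / n_het else NA_real_,
                 duplex_share = if (!is.na(dup) && n_het)
                   dup / n_het else NA_real_),
            class = "call_class_profile")
}

#' @export
print.call_class_profile <- function(x, ...) {
  cat("call_class_profile:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "),
      sprintf("(missing %d)\n", x$n_missing))
  cat(sprintf("  het %.3f, simplex+triplex share %.3f, duplex share %.3f\n",
              x$het_fraction, x$simplex_triplex_share, x$duplex_share))
  invisible(x)
}

#' Decision thresholds for SNP-based ploidy prediction
#'
#' Defaults were calibrated on the synthetic generator under its default
#' noise: diploids put essentially all heterozygous calls in the duplex
#' class and triploids in the simplex/triplex classes, so those shares
#' carry the 2x and 3x decisions; the 4x/5x split uses the sum of the
#' duplex share and the overall heterozygous fraction (pentaploids
#' collapse B-copy counts 2 and 3 into the duplex class and their
#' heterozygous copies are more likely, pushing both statistics up; the
#' sum separates the two profiles better than either alone).
#'
#' @param min_het_calls Minimum heterozygous call count for any
#'   prediction; default 50.
#' @param diploid_duplex Duplex share at or above which 2x is called.
#' @param triploid_st Simplex+triplex share at or above which 3x is called.
#' @param pentaploid_score Value of duplex share + het fraction at or
#'   above which (with all five classes present) the 4x/5x split calls
#'   5x; default 1.02.
#' @return List of class `"ploidy_thresholds"`.
#' @export
ploidy_thresholds <- function(min_het_calls = 50L, diploid_duplex = 0.9,
                              triploid_st = 0.9, pentaploid_score = 1.02) {
  structure(list(min_het_calls = as.integer(min_het_calls),
                 diploid_duplex = diploid_duplex,
                 triploid_st = triploid_st,
                 pentaploid_score = pentaploid_score),
            class = "ploidy_thresholds")
}

predict_ploidy_one <- function(profile, th) {
  n_het <- round(profile$het_fraction * profile$n_called)
  if (is.na(profile$het_fraction) || n_het < th$min_het_calls) {
    return(list(ploidy = NA_integer_, confidence = NA_real_,
                reason = "insufficient heterozygous calls"))
  }
  if (profile$duplex_share >= th$diploid_duplex) {
    return(list(ploidy = 2L, confidence = profile$duplex_share,
                reason = "duplex-dominated heterozygous profile"))
  }
  if (profile$simplex_triplex_share >= th$triploid_st) {
    return(list(ploidy = 3L, confidence = profile$simplex_triplex_share,
                reason = "simplex/triplex-dominated heterozygous profile"))
  }
  score <- profile$duplex_share + profile$het_fraction
  five <- score >= th$pentaploid_score && all(profile$counts > 0L)
  list(ploidy = if (five) 5L else 4L,
       # 4x/5x is the least certain split; confidence reflects the margin
       confidence = min(1, 0.5 + abs(score - th$pentaploid_score)),
       reason = if (five) "high duplex share plus heterozygosity"
                else "mixed five-class profile")
}

#' Predict ploidy from five-cluster call profiles
#'
#' Applies the threshold rules of [ploidy_thresholds()] per accession.
#' The 4x/5x boundary is intrinsically the least certain call (the two
#' profiles differ only in degree); its confidence is reported and the
#' ambiguity is visible rather than hidden.
#'
#' @param m A `genotype_matrix` with five-cluster calls, or a single
#'   `call_class_profile`.
#' @param thresholds A [ploidy_thresholds()] object.
#' @return Data.frame with columns `accession_id`, `predicted_ploidy`
#'   (`NA` when undetermined), `confidence`, `reason`, `het_pct`.
#' @export
predict_ploidy <- function(m, thresholds = ploidy_thresholds()) {
  if (inherits(m, "call_class_profile")) {
    r <- predict_ploidy_one(m, thresholds)
    return(data.frame(accession_id = NA_character_,
                      predicted_ploidy = r$ploidy, confidence = r$confidence,
                      reason = r$reason, het_pct = 100 * m$het_fraction,
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(m, "genotype_matrix"))
  scale <- encoding_scale(m$encoding)
  if (scale != 4L)
    stop("ploidy prediction requires five-cluster calls")
  rows <- lapply(rownames(m$calls), function(id) {
    pf <- call_class_profile(m$calls[id, ], scale)
    r <- predict_ploidy_one(pf, thresholds)
    data.frame(accession_id = id, predicted_ploidy = r$ploidy,
               confidence = r$confidence, reason = r$reason,
               het_pct = 100 * pf$het_fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconcile predicted against declared ploidy
#'
#' @param calls Data.frame from [predict_ploidy()].
#' @param meta Metadata data.frame with `accession_id` and
#'   `declared_ploidy` (NA for unknown).
#' @return List of class `"ploidy_reconciliation"`: `table` (per
#'   accession: declared, predicted, status in agree / disagree /
#'   was_unknown / undetermined) and `summary` (fractions over accessions
#'   with a prediction and a declaration).
#' @export
reconcile_ploidy <- function(calls, meta) {
  stopifnot(all(c("accession_id", "declared_ploidy") %in% names(meta)))
  declared <- meta$declared_ploidy[match(calls$accession_id,
                                         meta$accession_id)]
  status <- ifelse(is.na(calls$predicted_ploidy), "undetermined",
            ifelse(is.na(declared), "was_unknown",
            ifelse(calls$predicted_ploidy == declared,
                   "agree", "disagree")))
  tab <- data.frame(accession_id = calls$accession_id,
                    declared_ploidy = declared,
                    predicted_ploidy = calls$predicted_ploidy,
                    status = status, stringsAsFactors = FALSE)
  n_cmp <- sum(status %in% c("agree", "disagree"))
  summary <- list(
    n = nrow(tab),
    n_compared = n_cmp,
    n_agree = sum(status == "agree"),
    n_disagree = sum(status == "disagree"),
    n_was_unknown = sum(status == "was_unknown"),
    n_undetermined = sum(status == "undetermined"),
    pct_agree = if (n_cmp) 100 * sum(status == "agree") / n_cmp else NA_real_)
  structure(list(table = tab, summary = summary),
            class = "ploidy_reconciliation")
}

#' @export
print.ploidy_reconciliation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "ploidy_reconciliation: %d accessions, %.1f%% agreement (%d/%d)\n",
    s$n, s$pct_agree, s$n_agree, s$n_compared))
  cat(sprintf("  was_unknown %d, undetermined %d\n",
              s$n_was_unknown, s$n_undetermined))
  invisible(x)
}

#' Per-accession heterozygosity table
#'
#' @param m A `genotype_matrix`.
#' @return Data.frame with `accession_id` and `het_pct`.
#' @export
heterozygosity_table <- function(m) {
  scale <- encoding_scale(m$encoding)
  data.frame(accession_id = rownames(m$calls),
             het_pct = apply(m$calls, 1L, heterozygosity, scale = scale),
             stringsAsFactors = FALSE, row.names = NULL)
}
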