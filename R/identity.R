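## Paired-sample fingerprint identity QC and duplicate detection.

#' Fingerprint concordance between two call vectors
#'
#' Fraction of markers, among those called (non-missing) in both vectors,
#' with identical dosage calls. Symmetric; markers missing in either
#' member are excluded.
#'
#' @param a,b Integer call vectors over the same markers (`NA` missing).
#' @return List with `concordance` (fraction in \[0,1\], or `NA` when no
#'   locus is jointly called) and `overlap` (the joint call count).
#' @examples
#' concordance(c(0L, 2L, NA), c(0L, 2L, 4L)) # 1.0 over overlap 2
#' @export
concordance <- function(a, b) {
  if (length(a) != length(b)) stop("call vectors must cover equal marker sets")
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  list(concordance = if (n == 0L) NA_real_ else sum(a[both] == b[both]) / n,
       overlap = n)
}

#' All-pairs concordance and overlap matrices
#'
#' Computed by class-indicator cross-products, so cost is a handful of
#' dense matrix multiplications rather than an explicit pair loop.
#'
#' @param m A `genotype_matrix`.
#' @return List of two symmetric matrices, `concordance` (NA where the
#'   joint-call overlap is zero) and `overlap`.
#' @export
concordance_matrix <- function(m) {
  calls <- m$calls
  scale <- encoding_scale(m$encoding)
  called <- !is.na(calls)
  storage.mode(called) <- "double"
  overlap <- tcrossprod(called)
  matches <- matrix(0, nrow(calls), nrow(calls))
  for (cl in 0:scale) {
    e <- !is.na(calls) & calls == cl
    storage.mode(e) <- "double"
    matches <- matches + tcrossprod(e)
  }
  conc <- ifelse(overlap > 0, matches / overlap, NA_real_)
  dimnames(conc) <- dimnames(overlap) <- list(rownames(calls),
                                              rownames(calls))
  list(concordance = conc, overlap = overlap)
}

#' Per-pair concordance for mother / in-vitro pairs
#'
#' @param m A `genotype_matrix` containing both pair members.
#' @param pairs Data.frame with columns `pair_id`, `mother_id`,
#'   `invitro_id`.
#' @return `pairs` with `concordance` and `overlap` columns appended.
#'   Pairs whose members differ in call encoding conventions are the
#'   caller's responsibility; comparison is on raw dosage calls.
#' @export
pair_concordance <- function(m, pairs) {
  stopifnot(all(c("pair_id", "mother_id", "invitro_id") %in% names(pairs)))
  missing <- setdiff(c(pairs$mother_id, pairs$invitro_id), rownames(m$calls))
  if (length(missing) > 0L)
    stop("pair members absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  res <- mapply(function(mo, iv) {
    cc <- concordance(m$calls[mo, ], m$calls[iv, ])
    c(cc$concordance, cc$overlap)
  }, pairs$mother_id, pairs$invitro_id)
  pairs$concordance <- res[1L, ]
  pairs$overlap <- as.integer(res[2L, ])
  pairs
}

#' True-to-type verdicts and collection error rate
#'
#' A pair is `true_to_type` when its concordance reaches `threshold` over
#' at least `min_overlap` jointly called loci, `mismatch` when the
#' concordance falls below the threshold with sufficient overlap, and
#' `insufficient_data` otherwise. The collection error rate is
#' mismatches / (mismatches + true-to-type); insufficient pairs are
#' excluded from the denominator.
#'
#' @param pairs Data.frame from [pair_concordance()].
#' @param threshold Concordance required for a true-to-type verdict;
#'   default 0.98 (tolerates array-level miscalls while separating
#'   distinct clones).
#' @param min_overlap Minimum joint call count for any verdict;
#'   default 500 loci.
#' @return List of class `"pair_set"`: `pairs` (with `verdict` column),
#'   `error_rate`, `n_true_to_type`, `n_mismatch`, `n_insufficient`,
#'   `threshold`, `min_overlap`.
#' @export
classify_pairs <- function(pairs, threshold = 0.98, min_overlap = 500L) {
  if (nrow(pairs) == 0L) stop("empty pair set: error rate undefined")
  stopifnot("concordance" %in% names(pairs))
  verdict <- ifelse(is.na(pairs$concordance) | pairs$overlap < min_overlap,
                    "insufficient_data",
                    ifelse(pairs$concordance >= threshold,
                           "true_to_type", "mismatch"))
  pairs$verdict <- verdict
  n_ttt <- sum(verdict == "true_to_type")
  n_mis <- sum(verdict == "mismatch")
  er <- if (n_ttt + n_mis == 0L) NA_real_ else n_mis / (n_ttt + n_mis)
  structure(list(pairs = pairs, error_rate = er, n_true_to_type = n_ttt,
                 n_mismatch = n_mis,
                 n_insufficient = sum(verdict == "insufficient_data"),
                 threshold = threshold, min_overlap = min_overlap),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d pairs (%d TTT, %d mismatch, %d insufficient)\n",
              nrow(x$pairs), x$n_true_to_type, x$n_mismatch,
              x$n_insufficient))
  if (!is.na(x$error_rate))
    cat(sprintf("  error rate: %.1f%%\n", 100 * x$error_rate))
  invisible(x)
}

#' Duplicate-accession groups by fingerprint identity
#'
#' Single-linkage grouping over the graph connecting accession pairs with
#' concordance at or above `threshold` (over at least `min_overlap` joint
#' calls). Use on a concatenation of two collections for cross-collection
#' redundancy scans.
#'
#' @param m A `genotype_matrix`.
#' @param threshold Duplicate concordance threshold; default 0.995,
#'   stricter than the true-to-type threshold because duplicate groups
#'   are claims of genetic identity.
#' @param min_overlap Minimum joint call count for an edge.
#' @return List of class `"duplicate_groups"`: `groups` (list of
#'   character vectors, each sorted; groups ordered by first member) and
#'   `threshold`. Singleton groups are included.
#' @export
duplicate_groups <- function(m, threshold = 0.995, min_overlap = 1L) {
  ids <- rownames(m$calls)
  n <- length(ids)
  cm <- concordance_matrix(m)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        cij <- cm$concordance[i, j]
        if (!is.na(cij) && cij >= threshold && cm$overlap[i, j] >= min_overlap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, root)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, "", 1L))]
  names(groups) <- NULL
  structure(list(groups = groups, threshold = threshold),
            class = "duplicate_groups")
}

#' @export
print.duplicate_groups <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf(
    "duplicate_groups: %d groups (%d of size > 1) at concordance >= %.4g\n",
    length(x$groups), sum(sizes > 1L), x$threshold))
  invisible(x)
}
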