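#' @useDynLib potapop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbeta runif rbinom rmultinom prcomp sd cor setNames
#' @importFrom utils read.table write.table
NULL

SPECIES_CODES <- c("ADG", "CHA", "GON", "JUZ", "PHU", "STN", "TBR",
                   "AJH", "CUR", "SOL", "ND")
SAMPLE_ROLES <- c("mother", "in_vitro", "single")

#' Encoding scale of a call encoding
#'
#' Highest legal call class: 2 for three-cluster (diploid AA/AB/BB) calls,
#' 4 for five-cluster (nulliplex..quadruplex) calls.
#'
#' @param encoding `"three_cluster"` or `"five_cluster"`.
#' @return Integer scalar.
#' @export
encoding_scale <- function(encoding) {
  encoding <- match.arg(encoding, c("five_cluster", "three_cluster"))
  if (encoding == "three_cluster") 2L else 4L
}

#' Accession-by-marker genotype call matrix
#'
#' The universal input of the pipeline: integer dosage-class calls of the B
#' (alternate) allele, one row per accession, one column per marker, `NA`
#' for missing. Five-cluster calls are array *classes* on the 0..4
#' tetraploid scale for every accession regardless of its biological ploidy
#' (the array caller does not know the ploidy); three-cluster calls are
#' 0/1/2. Per-accession ploidy is carried as metadata, not encoded in the
#' calls.
#'
#' @param calls Integer matrix with unique rownames (accession ids) and
#'   unique colnames (marker ids); `NA` marks missing calls.
#' @param ploidy Optional named integer vector of per-accession ploidy in
#'   2..5; names must cover the rownames of `calls`.
#' @param encoding Call encoding, `"five_cluster"` (default) or
#'   `"three_cluster"`.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `calls`, `ploidy` (possibly `NULL`) and `encoding`.
#' @examples
#' m <- genotype_matrix(matrix(c(0L, 2L, 4L, NA), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("m1", "m2"))))
#' n_accessions(m)
#' @export
genotype_matrix <- function(calls, ploidy = NULL,
                            encoding = c("five_cluster", "three_cluster")) {
  encoding <- match.arg(encoding)
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  obj <- structure(list(calls = calls, ploidy = ploidy, encoding = encoding),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

#' Validate a genotype matrix
#'
#' Checks id uniqueness, call range against the encoding scale, and
#' ploidy metadata coverage. Called by [genotype_matrix()]; exported so
#' generated or externally assembled objects can be re-checked.
#'
#' @param m A `genotype_matrix`.
#' @return `m`, invisibly; errors describe the first violation found.
#' @export
validate_genotype_matrix <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  calls <- m$calls
  if (is.null(rownames(calls)) && nrow(calls) > 0L)
    stop("genotype matrix must have accession ids as rownames")
  if (is.null(colnames(calls)) && ncol(calls) > 0L)
    stop("genotype matrix must have marker ids as colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate accession ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  scale <- encoding_scale(m$encoding)
  bad <- which(!is.na(calls) & (calls < 0L | calls > scale), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "call %d at accession '%s', marker '%s' outside 0..%d for %s encoding",
      calls[bad[1, 1], bad[1, 2]], rownames(calls)[bad[1, 1]],
      colnames(calls)[bad[1, 2]], scale, m$encoding))
  }
  if (!is.null(m$ploidy)) {
    pl <- m$ploidy
    if (is.null(names(pl))) stop("ploidy must be a named vector")
    missing_ids <- setdiff(rownames(calls), names(pl))
    if (length(missing_ids) > 0L)
      stop("no ploidy for accessions: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    known <- pl[!is.na(pl)]
    if (any(!(known %in% 2:5)))
      stop("ploidy values must be in 2..5 (or NA for unknown)")
  }
  invisible(m)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers (%s)\n",
              nrow(x$calls), ncol(x$calls), x$encoding))
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm,
              if (length(x$calls)) 100 * nm / length(x$calls) else 0))
  if (!is.null(x$ploidy)) {
    tab <- table(x$ploidy[rownames(x$calls)], useNA = "ifany")
    cat("  ploidy:", paste(sprintf("%sx=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @export
n_accessions <- function(m) nrow(m$calls)

#' @rdname genotype_matrix
#' @export
n_markers <- function(m) ncol(m$calls)

#' @rdname genotype_matrix
#' @export
accession_ids <- function(m) rownames(m$calls)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(m) colnames(m$calls)

#' Subset a genotype matrix by accession
#'
#' @param m A `genotype_matrix`.
#' @param ids Accession ids to keep (order respected).
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_accessions <- function(m, ids) {
  stopifnot(all(ids %in% rownames(m$calls)))
  genotype_matrix(m$calls[ids, , drop = FALSE],
                  ploidy = if (is.null(m$ploidy)) NULL else m$ploidy[ids],
                  encoding = m$encoding)
}

#' Convert five-cluster class calls to allele-dosage counts
#'
#' Maps each accession's array classes (0..4) back to B-allele copy counts
#' on its own ploidy: dosage = round(ploidy * class / 4). Three-cluster
#' calls are mapped with scale 2. The inverse of the nearest-class mapping
#' the array (and the simulator) applies; for even classes of odd ploidies
#' the lower dosage is taken.
#'
#' @param m A `genotype_matrix` with per-accession ploidy available.
#' @param ploidy Optional named ploidy vector overriding `m$ploidy`
#'   (e.g. SNP-predicted ploidy).
#' @return Integer matrix of dosages, same dimnames as `m$calls`.
#' @export
as_dosage <- function(m, ploidy = NULL) {
  pl <- if (!is.null(ploidy)) ploidy else m$ploidy
  if (is.null(pl)) stop("per-accession ploidy required to recover dosage")
  pl <- pl[rownames(m$calls)]
  if (any(is.na(pl))) stop("ploidy unknown for some accessions")
  scale <- encoding_scale(m$encoding)
  d <- m$calls
  for (i in seq_len(nrow(d))) {
    d[i, ] <- as.integer(round(pl[i] * d[i, ] / scale))
  }
  d
}

## ---------------------------------------------------------------- IO ----

MISSING_TOKEN <- "NA"

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genotype call table
#'
#' Delimited text (TSV or CSV by extension), first column accession id,
#' header row marker ids, cells integer dosage classes or `NA`.
#'
#' @param path File path.
#' @param encoding Call encoding of the file (bounds cell validation).
#' @param ploidy Optional named ploidy vector to attach.
#' @param sep Field separator; guessed from the extension by default.
#' @return A `genotype_matrix`.
#' @export
read_genotype_table <- function(path,
                                encoding = c("five_cluster", "three_cluster"),
                                ploidy = NULL, sep = guess_sep(path)) {
  encoding <- match.arg(encoding)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = MISSING_TOKEN, quote = "",
                           comment.char = "")
  if (ncol(tab) < 1L) stop("empty genotype table: ", path)
  ids <- tab[[1L]]
  dat <- tab[, -1L, drop = FALSE]
  cells <- as.matrix(dat)
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is.na(cells) & (is.na(num) | num != round(num)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("malformed cell '%s' at row '%s', column '%s' in %s",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(dat)[bad[1, 2]], path))
  }
  calls <- matrix(as.integer(num), nrow = nrow(cells),
                  dimnames = list(ids, colnames(dat)))
  genotype_matrix(calls, ploidy = ploidy, encoding = encoding)
}

#' Write a genotype call table
#'
#' Deterministic layout: accession rows in matrix order, marker columns in
#' `marker_ids(m)` order, missing calls as the token `NA`. Round-trips
#' losslessly through [read_genotype_table()].
#'
#' @param m A `genotype_matrix`.
#' @param path Output file path (`.csv` writes commas, anything else tabs).
#' @param sep Field separator; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(m, path, sep = guess_sep(path)) {
  df <- as.data.frame(m$calls)
  df <- cbind(accession_id = rownames(m$calls), df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = MISSING_TOKEN)
  invisible(path)
}

#' Read an accession metadata table
#'
#' CSV with columns `accession_id`, `species_code`, `declared_ploidy`,
#' `country`, `sample_role` and optionally `pair_id`. Species codes are
#' checked against the controlled vocabulary (ADG, CHA, GON, JUZ, PHU, STN,
#' TBR, AJH, CUR, SOL, ND); unknown ploidy/country may be `NA`.
#'
#' @param path File path.
#' @return A data.frame, one row per accession.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                            stringsAsFactors = FALSE, quote = "\"",
                            na.strings = c("NA", ""))
  needed <- c("accession_id", "species_code", "declared_ploidy",
              "country", "sample_role")
  miss <- setdiff(needed, names(meta))
  if (length(miss) > 0L)
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$accession_id))
    stop("duplicate accession ids in metadata")
  bad <- setdiff(stats::na.omit(unique(meta$species_code)), SPECIES_CODES)
  if (length(bad) > 0L)
    stop("unknown species codes: ", paste(bad, collapse = ", "))
  badrole <- setdiff(stats::na.omit(unique(meta$sample_role)), SAMPLE_ROLES)
  if (length(badrole) > 0L)
    stop("unknown sample roles: ", paste(badrole, collapse = ", "))
  meta
}

#' Write an accession metadata table
#'
#' @param meta Data.frame as returned by [read_metadata()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

## ----------------------------------------------------------- filters ----

filter_report <- function(removed, unit, threshold) {
  structure(list(removed = removed, unit = unit, threshold = threshold),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d %s(s) removed at missingness >= %.3f\n",
              nrow(x$removed), x$unit, x$threshold))
  invisible(x)
}

#' Write a filter report as CSV
#'
#' @param report A `filter_report` from [filter_samples()] or
#'   [filter_markers()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$removed, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove samples with excessive missing data
#'
#' Drops every accession whose fraction of missing calls is greater than or
#' equal to `max_missing` (the collection-QC convention: "20% or more"
#' missing removes the sample).
#'
#' @param m A `genotype_matrix`.
#' @param max_missing Removal threshold in (0, 1]; default 0.20.
#' @return List with elements `matrix` (the filtered `genotype_matrix`) and
#'   `report` (a `filter_report` listing removed ids and their missing
#'   fractions).
#' @export
filter_samples <- function(m, max_missing = 0.20) {
  stopifnot(max_missing > 0, max_missing <= 1)
  frac <- rowMeans(is.na(m$calls))
  drop <- frac >= max_missing
  removed <- data.frame(accession_id = rownames(m$calls)[drop],
                        missing_fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  keep <- genotype_matrix(m$calls[!drop, , drop = FALSE],
                          ploidy = m$ploidy, encoding = m$encoding)
  list(matrix = keep, report = filter_report(removed, "sample", max_missing))
}

#' Remove markers with excessive missing data
#'
#' Drops every marker missing (no clear signal) in at least `max_missing`
#' of the retained individuals.
#'
#' @param m A `genotype_matrix`.
#' @param max_missing Removal threshold in (0, 1]; default 0.10.
#' @return List with elements `matrix` and `report`, as [filter_samples()].
#' @export
filter_markers <- function(m, max_missing = 0.10) {
  stopifnot(max_missing > 0, max_missing <= 1)
  frac <- colMeans(is.na(m$calls))
  drop <- frac >= max_missing
  removed <- data.frame(marker_id = colnames(m$calls)[drop],
                        missing_fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  keep <- genotype_matrix(m$calls[, !drop, drop = FALSE],
                          ploidy = m$ploidy, encoding = m$encoding)
  list(matrix = keep, report = filter_report(removed, "marker", max_missing))
}

#' Drop markers on a curated exclusion list
#'
#' Hook for array SNPs previously flagged as poor or questionable: a plain
#' text file of marker ids (one per line) or a character vector. No default
#' list is shipped.
#'
#' @param m A `genotype_matrix`.
#' @param exclude Character vector of marker ids, or path to a text file.
#' @return Filtered `genotype_matrix`.
#' @export
exclude_markers <- function(m, exclude) {
  if (length(exclude) == 1L && file.exists(exclude))
    exclude <- readLines(exclude, warn = FALSE)
  exclude <- trimws(exclude)
  exclude <- exclude[nzchar(exclude)]
  keep <- setdiff(colnames(m$calls), exclude)
  genotype_matrix(m$calls[, keep, drop = FALSE],
                  ploidy = m$ploidy, encoding = m$encoding)
}
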