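## Rule-based species prediction from admixture proportions: per-species
## interval constraints on the six named cluster frequencies, a scoring
## policy, species calls with hybrid candidates, and accuracy evaluation.

CLUSTER_NAMES <- c("yellow", "red", "blue", "pink", "teal", "green")

parse_rule_cell <- function(cell, species, cluster) {
  cell <- trimws(gsub("%", "", cell))
  cell <- gsub("–", "-", cell)  # en dash
  if (cell == "" || is.na(cell)) return(NULL)
  if (toupper(cell) == "NO")
    return(data.frame(species = species, cluster = cluster, type = "zero",
                      lo = 0, hi = 0, stringsAsFactors = FALSE))
  if (cell == "-")
    return(data.frame(species = species, cluster = cluster, type = "low",
                      lo = 0, hi = NA_real_, stringsAsFactors = FALSE))
  if (grepl("^>", cell)) {
    lo <- as.numeric(sub(">", "", cell))
    return(data.frame(species = species, cluster = cluster,
                      type = "interval", lo = lo, hi = 100,
                      stringsAsFactors = FALSE))
  }
  if (grepl("^<", cell)) {
    hi <- as.numeric(sub("<", "", cell))
    return(data.frame(species = species, cluster = cluster,
                      type = "interval", lo = 0, hi = hi,
                      stringsAsFactors = FALSE))
  }
  if (grepl("-", cell, fixed = TRUE)) {
    parts <- as.numeric(strsplit(cell, "-", fixed = TRUE)[[1]])
    return(data.frame(species = species, cluster = cluster,
                      type = "interval", lo = parts[1], hi = parts[2],
                      stringsAsFactors = FALSE))
  }
  stop(sprintf("unparseable rule cell '%s' (%s / %s)", cell, species,
               cluster))
}

#' Load a species rule table
#'
#' CSV with one row per species and one column per cluster colour
#' (yellow, red, blue, pink, teal, green); cells are empty
#' (unconstrained), `NO` (zero value), `-` (low to no value), `>x`,
#' `<x`, or `a-b`, all in percent.
#'
#' @param path Rule file; defaults to the shipped table.
#' @return Object of class `"rule_table"`: a data.frame of constraints
#'   (`species`, `cluster`, `type`, `lo`, `hi`).
#' @export
load_rule_table <- function(path = system.file("extdata",
                                               "cluster_rules.csv",
                                               package = "potapop")) {
  raw <- utils::read.table(path, header = TRUE, sep = ",",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  miss <- setdiff(CLUSTER_NAMES, names(raw))
  if (length(miss) > 0L)
    stop("rule table missing cluster columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (r in seq_len(nrow(raw))) {
    sp <- raw$species[r]
    for (cl in CLUSTER_NAMES) {
      rows[[length(rows) + 1L]] <- parse_rule_cell(raw[[cl]][r], sp, cl)
    }
  }
  rules <- do.call(rbind, rows)
  bad <- !is.na(rules$hi) &
    (rules$lo > rules$hi | rules$lo < 0 | rules$hi > 100)
  if (any(bad)) {
    b <- rules[bad, ][1, ]
    stop(sprintf("contradictory bounds [%g, %g] for %s / %s",
                 b$lo, b$hi, b$species, b$cluster))
  }
  orphan <- setdiff(raw$species, rules$species)
  if (length(orphan) > 0L)
    stop("species with no constrained cluster: ",
         paste(orphan, collapse = ", "))
  structure(rules, class = c("rule_table", "data.frame"))
}

#' @rdname load_rule_table
#' @export
default_rule_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_rule_table()
    cache
  }
})

#' Classification policy parameters
#'
#' The scoring policy's free parameters. Defaults were fixed by requiring
#' that the fourteen published worked examples classify exactly to their
#' printed species under the shipped rule table.
#'
#' @param tolerance Percent band around an interval: full credit within
#'   `tolerance` points of the interval, then linear decay to zero over a
#'   further `tolerance` points. Default 5.
#' @param epsilon Upper bound (percent) still counting as a zero value;
#'   beyond it credit decays linearly over `tolerance` with no plateau.
#'   Default 0.5.
#' @param low_cap Upper bound (percent) of a "low to no value" cell.
#'   Default 10.
#' @param hybrid_margin Score gap below which the runner-up species is
#'   reported as a putative hybrid parent. Default 0.1.
#' @return List of class `"classification_policy"`.
#' @export
classification_policy <- function(tolerance = 5, epsilon = 0.5,
                                  low_cap = 10, hybrid_margin = 0.1) {
  stopifnot(tolerance > 0, epsilon >= 0, low_cap > 0, hybrid_margin >= 0)
  structure(list(tolerance = tolerance, epsilon = epsilon,
                 low_cap = low_cap, hybrid_margin = hybrid_margin),
            class = "classification_policy")
}

as_percent <- function(q) {
  q <- as.numeric(q)
  if (sum(q, na.rm = TRUE) <= 1.5) q * 100 else q
}

## satisfaction and narrowness weight of one constraint at value x percent
constraint_sat <- function(x, type, lo, hi, policy) {
  tol <- policy$tolerance
  if (type == "zero") {
    eps <- policy$epsilon
    sat <- if (x <= eps) 1 else max(0, 1 - (x - eps) / tol)
    width <- eps
  } else {
    if (type == "low") hi <- policy$low_cap
    d <- max(lo - x, x - hi, 0)
    sat <- if (d <= tol) 1 else max(0, 1 - (d - tol) / tol)
    width <- hi - lo
  }
  c(sat = sat, weight = max(0.01, 1 - width / 100))
}

#' Score a Q row against every species rule
#'
#' Per species, the score is the narrowness-weighted mean constraint
#' satisfaction: each constrained cluster contributes its satisfaction
#' (1 inside the interval and within `tolerance` points of it, linearly
#' decaying to 0 over a further `tolerance`; zero-value cells get no
#' plateau beyond `epsilon`) with weight 1 - width/100, so narrow,
#' informative constraints dominate permissive ones. Scores are in
#' \[0, 1\].
#'
#' @param q Admixture proportions for one accession: a numeric vector of
#'   length 6, optionally named by cluster colour; fractions or percents
#'   (canonicalised internally).
#' @param rules A `rule_table`.
#' @param policy A [classification_policy()].
#' @return Named numeric vector of species scores, with attribute
#'   `"specificity"` (mean constraint weight per species, used for tie
#'   breaking).
#' @export
score_species <- function(q, rules = default_rule_table(),
                          policy = classification_policy()) {
  qp <- as_percent(q)
  if (is.null(names(q))) {
    if (length(qp) != length(CLUSTER_NAMES))
      stop("q must have ", length(CLUSTER_NAMES), " cluster entries")
    names(qp) <- CLUSTER_NAMES
  } else {
    names(qp) <- names(q)
    miss <- setdiff(unique(rules$cluster), names(qp))
    if (length(miss) > 0L)
      stop("q missing clusters: ", paste(miss, collapse = ", "))
  }
  species <- unique(rules$species)
  scores <- spec <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    rr <- rules[rules$species == sp, , drop = FALSE]
    sw <- t(mapply(function(cl, ty, lo, hi)
      constraint_sat(qp[[cl]], ty, lo, hi, policy),
      rr$cluster, rr$type, rr$lo, rr$hi))
    scores[sp] <- sum(sw[, "sat"] * sw[, "weight"]) / sum(sw[, "weight"])
    spec[sp] <- mean(sw[, "weight"])
  }
  attr(scores, "specificity") <- spec
  scores
}

#' Classify one accession from its Q row
#'
#' Primary call is the top-scoring species; ties are broken toward the
#' species with the narrower (more specific) mean constraint, then
#' lexicographically. When the runner-up is within `hybrid_margin` of the
#' top score the call is flagged as a putative hybrid with both species
#' as parent candidates. A top score of zero yields `"unclassified"`.
#'
#' @inheritParams score_species
#' @return List of class `"species_call"`: `primary`, `score`, `hybrid`,
#'   `candidates` (ranked, at most two), `scores` (all species).
#' @export
classify_q <- function(q, rules = default_rule_table(),
                       policy = classification_policy()) {
  scores <- score_species(q, rules, policy)
  spec <- attr(scores, "specificity")
  ord <- order(-scores, -spec, names(scores))
  ranked <- scores[ord]
  if (ranked[1] <= 0) {
    return(structure(list(primary = "unclassified", score = 0,
                          hybrid = FALSE, candidates = character(0),
                          scores = scores), class = "species_call"))
  }
  hybrid <- length(ranked) >= 2L &&
    (ranked[1] - ranked[2]) < policy$hybrid_margin && ranked[2] > 0
  structure(list(primary = names(ranked)[1],
                 score = unname(ranked[1]),
                 hybrid = hybrid,
                 candidates = if (hybrid) names(ranked)[1:2]
                              else names(ranked)[1],
                 scores = scores),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("species_call: %s (score %.3f)%s\n", x$primary, x$score,
              if (x$hybrid) sprintf(" putative hybrid [%s]",
                                    paste(x$candidates, collapse = " x "))
              else ""))
  invisible(x)
}

#' Classify every row of a Q-matrix
#'
#' @param Q Accessions x 6 matrix (rownames = accession ids). Matrices
#'   with fewer than six columns are padded with zero ancestry in the
#'   trailing named clusters (useful for reduced-K exploratory runs).
#' @inheritParams score_species
#' @return Data.frame: `accession_id`, `species`, `score`, `hybrid`,
#'   `parent1`, `parent2`.
#' @export
classify_accessions <- function(Q, rules = default_rule_table(),
                                policy = classification_policy()) {
  if (ncol(Q) < length(CLUSTER_NAMES)) {
    pad <- matrix(0, nrow(Q), length(CLUSTER_NAMES) - ncol(Q))
    Q <- cbind(Q, pad)
  }
  colnames(Q) <- CLUSTER_NAMES[seq_len(ncol(Q))]
  rows <- lapply(seq_len(nrow(Q)), function(i) {
    call <- classify_q(Q[i, ], rules, policy)
    data.frame(accession_id = rownames(Q)[i], species = call$primary,
               score = call$score, hybrid = call$hybrid,
               parent1 = call$candidates[1],
               parent2 = if (length(call$candidates) > 1L)
                 call$candidates[2] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accuracy of species predictions against confirmed labels
#'
#' Primary accuracy counts a call correct when the primary species equals
#' the confirmed label; hybrid-extended accuracy also accepts a match to
#' either putative hybrid parent candidate. Accessions with no usable
#' label (`SOL`, `ND`, `NA`) are excluded from the denominators.
#'
#' @param calls Data.frame from [classify_accessions()].
#' @param truth Character vector of confirmed species labels, aligned
#'   with `calls` rows (or named by accession id).
#' @return List of class `"prediction_accuracy"`: `overall_pct`,
#'   `extended_pct`, `n_evaluated`, `per_species` (data.frame).
#' @export
evaluate_predictions <- function(calls, truth) {
  if (!is.null(names(truth))) truth <- truth[calls$accession_id]
  stopifnot(length(truth) == nrow(calls))
  usable <- !is.na(truth) & !(truth %in% c("SOL", "ND"))
  calls <- calls[usable, , drop = FALSE]
  truth <- truth[usable]
  primary_ok <- calls$species == truth
  extended_ok <- primary_ok |
    (!is.na(calls$parent2) & calls$parent2 == truth) |
    (calls$parent1 == truth)
  per <- do.call(rbind, lapply(sort(unique(truth)), function(sp) {
    idx <- truth == sp
    data.frame(species = sp, n = sum(idx),
               primary_pct = 100 * mean(primary_ok[idx]),
               extended_pct = 100 * mean(extended_ok[idx]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    overall_pct = if (length(truth)) 100 * mean(primary_ok) else NA_real_,
    extended_pct = if (length(truth)) 100 * mean(extended_ok) else NA_real_,
    n_evaluated = length(truth), per_species = per),
    class = "prediction_accuracy")
}

#' @export
print.prediction_accuracy <- function(x, ...) {
  cat(sprintf(
    "prediction_accuracy: %.1f%% primary, %.1f%% hybrid-extended (n=%d)\n",
    x$overall_pct, x$extended_pct, x$n_evaluated))
  print(x$per_species, row.names = FALSE, digits = 3)
  invisible(x)
}
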