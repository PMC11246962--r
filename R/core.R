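## Core and mini-core subset selection under the accession-to-nearest-
## entry (ANE) objective: greedy farthest-point seeding plus steepest-
## descent single-swap local search.

#' Accession-to-nearest-entry objective
#'
#' Mean, over all accessions, of the distance to the closest selected
#' entry (zero for selected members themselves). Smaller is better: a
#' low ANE means every accession in the collection is well represented
#' by some core entry.
#'
#' @param d Complete symmetric distance matrix with accession dimnames.
#' @param selected Character vector of selected accession ids (or
#'   integer indices).
#' @return Numeric objective value.
#' @export
ane_objective <- function(d, selected) {
  d <- as.matrix(d)
  if (length(selected) == 0L) stop("selection must be non-empty")
  if (is.character(selected)) {
    stopifnot(all(selected %in% rownames(d)))
  }
  mean(apply(d[, selected, drop = FALSE], 1L, min))
}

## nearest and second-nearest selected entry per accession
nearest_two <- function(d, sel_idx) {
  sub <- d[, sel_idx, drop = FALSE]
  n1 <- max.col(-sub, ties.method = "first")
  v1 <- sub[cbind(seq_len(nrow(sub)), n1)]
  if (length(sel_idx) == 1L) {
    return(list(idx1 = sel_idx[n1], v1 = v1,
                v2 = rep(Inf, nrow(sub))))
  }
  sub2 <- sub
  sub2[cbind(seq_len(nrow(sub)), n1)] <- Inf
  n2 <- max.col(-sub2, ties.method = "first")
  list(idx1 = sel_idx[n1], v1 = v1, v2 = sub2[cbind(seq_len(nrow(sub)), n2)])
}

greedy_seed <- function(d, ids, cand_idx, size, start_idx) {
  sel <- start_idx
  while (length(sel) < size) {
    mind <- apply(d[, sel, drop = FALSE], 1L, min)
    pool <- setdiff(cand_idx, sel)
    pick <- pool[order(-mind[pool], ids[pool])[1L]]
    sel <- c(sel, pick)
  }
  sel
}

local_search <- function(d, ids, cand_idx, sel, max_sweeps) {
  obj <- ane_objective(d, ids[sel])
  sweep_n <- 0L
  repeat {
    sweep_n <- sweep_n + 1L
    nt <- nearest_two(d, sel)
    best_gain <- 0
    best_swap <- NULL
    pool <- setdiff(cand_idx, sel)
    # deterministic scan order (by id) makes tie-breaking content-based
    for (s in sel[order(ids[sel])]) {
      # objective with s removed: accessions whose nearest entry is s
      # fall back to their second nearest
      base <- ifelse(nt$idx1 == s, nt$v2, nt$v1)
      for (u in pool[order(ids[pool])]) {
        val <- mean(pmin(base, d[, u]))
        gain <- obj - val
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_swap <- c(s, u)
        }
      }
    }
    if (is.null(best_swap) || sweep_n > max_sweeps) break
    sel <- c(setdiff(sel, best_swap[1L]), best_swap[2L])
    obj <- obj - best_gain
    if (sweep_n >= max_sweeps) break
  }
  list(sel = sel, objective = ane_objective(d, ids[sel]))
}

#' Select a core collection under the ANE objective
#'
#' Multi-start greedy seeding plus steepest-descent single-swap local
#' search. Each start seeds the selection at one of the `n_starts` most
#' central candidates (ranked by distance row sum) and grows it by
#' repeatedly adding the accession farthest from its nearest selected
#' entry; local search then swaps entries until no single swap improves
#' the ANE objective or `max_sweeps` is reached, and the best start wins.
#' All ties are broken toward the lexicographically smallest accession
#' id, so the selection is invariant to row relabelling and needs no
#' randomness.
#'
#' @param d Complete symmetric distance matrix with accession dimnames.
#' @param fraction Target selection fraction (default 0.1168, the sizing
#'   rule that draws 451 entries from a 3,860-accession collection);
#'   ignored when `size` is given.
#' @param size Absolute selection size.
#' @param candidates Optional candidate id set to select from (used by
#'   [select_mini_core()]); the objective is always evaluated over all
#'   accessions.
#' @param max_sweeps Local-search sweep limit per start; default 50.
#' @param n_starts Number of greedy starting points; default 5.
#' @return Object of class `"core_selection"`: `selected` (sorted ids),
#'   `objective`, `size`, `greedy_objective` (best greedy-only value).
#' @export
select_core <- function(d, fraction = 0.1168, size = NULL,
                        candidates = NULL, max_sweeps = 50L,
                        n_starts = 5L) {
  d <- as.matrix(d)
  if (any(is.na(d))) stop("distance matrix has missing entries")
  ids <- rownames(d)
  n <- length(ids)
  if (is.null(candidates)) candidates <- ids
  stopifnot(all(candidates %in% ids))
  cand_idx <- sort(match(candidates, ids))
  if (is.null(size)) {
    stopifnot(fraction > 0, fraction < 1)
    size <- max(1L, round(fraction * n))
  }
  size <- as.integer(size)
  if (size > length(cand_idx))
    stop("requested size exceeds the candidate set")

  rs <- rowSums(d)[cand_idx]
  starts <- cand_idx[order(rs, ids[cand_idx])]
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  greedy_obj <- Inf
  for (st in starts) {
    sel0 <- greedy_seed(d, ids, cand_idx, size, st)
    greedy_obj <- min(greedy_obj, ane_objective(d, ids[sel0]))
    cand <- local_search(d, ids, cand_idx, sel0, max_sweeps)
    if (is.null(best) || cand$objective < best$objective - 1e-12 ||
        (abs(cand$objective - best$objective) <= 1e-12 &&
         paste(sort(ids[cand$sel]), collapse = "|") <
           paste(sort(ids[best$sel]), collapse = "|"))) {
      best <- cand
    }
  }

  structure(list(selected = sort(ids[best$sel]), objective = best$objective,
                 size = size, greedy_objective = greedy_obj),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection: %d entries, ANE objective %.6g\n",
              x$size, x$objective))
  invisible(x)
}

#' Select a mini core from a core collection
#'
#' Runs the same optimiser with candidates restricted to the core
#' members; the ANE objective is still evaluated over the whole
#' collection, so the mini core represents everything, not just the core.
#'
#' @param core A `core_selection`.
#' @param d The full distance matrix.
#' @param size Mini-core size (must not exceed the core size).
#' @param max_sweeps Local-search sweep limit.
#' @return A `core_selection`; always a subset of `core$selected`.
#' @export
select_mini_core <- function(core, d, size, max_sweeps = 50L) {
  stopifnot(inherits(core, "core_selection"))
  if (size > core$size) stop("mini-core size exceeds the core size")
  select_core(d, size = size, candidates = core$selected,
              max_sweeps = max_sweeps)
}

#' Species composition of a selection
#'
#' @param selection A `core_selection` (or character id vector).
#' @param meta Metadata data.frame with `accession_id` and
#'   `species_code`.
#' @return Data.frame of per-species counts; counts sum to the selection
#'   size.
#' @export
composition_report <- function(selection, meta) {
  ids <- if (inherits(selection, "core_selection")) selection$selected
         else selection
  sp <- meta$species_code[match(ids, meta$accession_id)]
  sp[is.na(sp)] <- "ND"
  tab <- table(sp)
  data.frame(species = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
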