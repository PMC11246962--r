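## Synthetic multi-ploidy genebank collections with known ground truth.
## Generation model: Balding-Nichols differentiated allele frequencies
## across K ancestral populations (independent loci, independent
## frequencies), Dirichlet admixture per accession, per-copy population
## assignment, binomial B-allele sampling per copy, nearest-class array
## call mapping, adjacent-class miscalls, random missingness, and
## mother / in-vitro sample pairs with injected identity errors.

#' Simulation configuration for a synthetic genebank collection
#'
#' Defaults describe a desk-scale mixed-ploidy potato-like collection:
#' ploidy mix from the proportions observed in a large Andean landrace
#' genebank (about 15.5\% diploid, 5.1\% triploid, 79.2\% tetraploid,
#' 0.2\% pentaploid), moderate differentiation (Fst 0.15), strong but not
#' total admixture (Dirichlet alpha 0.2), 2\% random missing calls, 0.3\%
#' adjacent-class miscalls (array replicate reproducibility above 99\%),
#' and a 19.9\% pair-handling error rate.
#'
#' @param n_accessions Number of (mother) accessions.
#' @param n_markers Number of biallelic markers.
#' @param K_true Number of ancestral populations.
#' @param fst Balding-Nichols differentiation per population, in (0,1);
#'   recycled to length `K_true`.
#' @param alpha Dirichlet admixture concentration (> 0).
#' @param ploidy_mix Named proportions over ploidies "2".."5"; must sum
#'   to 1.
#' @param missing_rate Per-call missingness probability in \[0,1\].
#' @param call_error_rate Per-call probability of an adjacent-class
#'   miscall (reflected at the class bounds).
#' @param pair_error_rate Fraction of in-vitro partners replaced by the
#'   genotype of a different accession.
#' @param encoding Call encoding emitted; `"five_cluster"` (default)
#'   records nearest tetraploid array classes 0..4, `"three_cluster"`
#'   requires an all-diploid `ploidy_mix`.
#' @param seed Master RNG seed; sub-stages use fixed offsets from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_accessions = 200L, n_markers = 300L, K_true = 3L,
                       fst = 0.15, alpha = 0.2,
                       ploidy_mix = c("2" = 0.155, "3" = 0.051,
                                      "4" = 0.792, "5" = 0.002),
                       missing_rate = 0.02, call_error_rate = 0.003,
                       pair_error_rate = 0.199,
                       encoding = c("five_cluster", "three_cluster"),
                       seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(n_accessions >= 1, n_markers >= 1, K_true >= 1, alpha > 0)
  fst <- rep_len(fst, K_true)
  if (any(fst <= 0 | fst >= 1))
    stop("fst must lie strictly between 0 and 1")
  rates <- c(missing_rate, call_error_rate, pair_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!all(names(ploidy_mix) %in% c("2", "3", "4", "5")))
    stop("ploidy_mix names must be among 2..5")
  if (abs(sum(ploidy_mix) - 1) > 1e-8) stop("ploidy_mix must sum to 1")
  if (encoding == "three_cluster" &&
      any(ploidy_mix[names(ploidy_mix) != "2"] > 0))
    stop("three_cluster encoding requires an all-diploid ploidy_mix")
  structure(list(n_accessions = as.integer(n_accessions),
                 n_markers = as.integer(n_markers),
                 K_true = as.integer(K_true), fst = fst, alpha = alpha,
                 ploidy_mix = ploidy_mix, missing_rate = missing_rate,
                 call_error_rate = call_error_rate,
                 pair_error_rate = pair_error_rate, encoding = encoding,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %s = %s\n", nm,
                paste(format(val, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

#' Dirichlet sampler stable for tiny concentrations
#'
#' Uses the log-space shape-boost representation of the gamma draw so that
#' near-zero concentrations yield near-one-hot rows instead of 0/0.
#'
#' @param n Number of rows.
#' @param alpha Concentration vector (recycled).
#' @param K Dimension (defaults to `length(alpha)`).
#' @return n x K matrix with rows on the simplex.
#' @export
rdirichlet <- function(n, alpha, K = length(alpha)) {
  alpha <- rep_len(alpha, K)
  # log(Gamma(a)) = log(Gamma(a+1)) + log(U)/a, exact for any a > 0
  lg <- matrix(log(stats::rgamma(n * K, shape = rep(alpha + 1, each = n))) +
                 log(stats::runif(n * K)) / rep(alpha, each = n),
               nrow = n)
  m <- apply(lg, 1L, max)
  w <- exp(lg - m)
  w / rowSums(w)
}

#' Draw Balding-Nichols differentiated allele frequencies
#'
#' Per marker a shared ancestral frequency p ~ Uniform(0.05, 0.95); each
#' population k then draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the population's Fst, so that the
#' population frequency has mean p and variance p(1-p)F.
#'
#' @param cfg A [sim_config()].
#' @return List with `freqs` (K x markers matrix in (0,1)) and
#'   `ancestral` (length-markers vector of shared frequencies).
#' @export
simulate_ancestral_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  M <- cfg$n_markers
  K <- cfg$K_true
  p <- stats::runif(M, 0.05, 0.95)
  freqs <- matrix(NA_real_, K, M)
  for (k in seq_len(K)) {
    F <- cfg$fst[k]
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    f <- stats::rbeta(M, a, b)
    # keep strictly inside (0,1) for downstream likelihoods
    freqs[k, ] <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  }
  rownames(freqs) <- paste0("pop", seq_len(K))
  colnames(freqs) <- paste0("m", sprintf("%04d", seq_len(M)))
  list(freqs = freqs, ancestral = p)
}

## nearest array class for dosage g of ploidy p on a 0..scale class scale
dosage_to_class <- function(g, ploidy, scale) {
  as.integer(round(scale * g / ploidy))
}

## adjacent-class miscalls, reflected at the bounds
corrupt_calls <- function(calls, rate, scale) {
  if (rate <= 0) return(calls)
  hit <- which(stats::runif(length(calls)) < rate & !is.na(calls))
  if (length(hit) == 0L) return(calls)
  step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
  v <- calls[hit] + step
  v[v < 0L] <- 1L
  v[v > scale] <- scale - 1L
  calls[hit] <- v
  calls
}

#' Simulate accession genotypes from population frequencies
#'
#' Per accession: admixture proportions q ~ Dirichlet(alpha), ploidy drawn
#' from `ploidy_mix`; at each marker every one of its ploidy allele copies
#' independently picks a source population from q and is a B allele with
#' that population's frequency. The true B dosage is then reported as the
#' nearest array call class (five-cluster scale 0..4, or 0..2 for
#' three-cluster diploid calling), miscalled to an adjacent class with
#' probability `call_error_rate` and masked at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param freqs Result of [simulate_ancestral_freqs()] (or a K x markers
#'   frequency matrix).
#' @param id_prefix Prefix for generated accession ids.
#' @return List with `matrix` (the observed `genotype_matrix`) and
#'   `truth`, a list holding `ancestral_freqs`, `q_true` (accessions x K),
#'   `ploidy_true`, `species_true`, `dosage_true` (pre-corruption B-copy
#'   counts) and `clean_calls` (pre-noise array classes).
#' @export
simulate_accessions <- function(cfg, freqs = simulate_ancestral_freqs(cfg),
                                id_prefix = "ACC") {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.list(freqs)) freqs <- freqs$freqs
  K <- cfg$K_true
  M <- cfg$n_markers
  N <- cfg$n_accessions
  stopifnot(nrow(freqs) == K, ncol(freqs) == M)
  set.seed(cfg$seed + 2L)
  scale <- encoding_scale(cfg$encoding)

  q <- rdirichlet(N, cfg$alpha, K)
  ploidies <- as.integer(names(cfg$ploidy_mix))
  ploidy <- sample(ploidies, N, replace = TRUE, prob = cfg$ploidy_mix)
  ids <- sprintf("%s%05d", id_prefix, seq_len(N))

  dosage <- matrix(0L, N, M, dimnames = list(ids, colnames(freqs)))
  for (i in seq_len(N)) {
    for (cp in seq_len(ploidy[i])) {
      z <- sample.int(K, M, replace = TRUE, prob = q[i, ])
      b <- stats::rbinom(M, 1L, freqs[cbind(z, seq_len(M))])
      dosage[i, ] <- dosage[i, ] + b
    }
  }

  clean <- dosage
  for (i in seq_len(N)) clean[i, ] <- dosage_to_class(dosage[i, ],
                                                      ploidy[i], scale)
  calls <- corrupt_calls(clean, cfg$call_error_rate, scale)
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }

  names(ploidy) <- ids
  rownames(q) <- ids
  colnames(q) <- rownames(freqs)
  species <- stats::setNames(species_from_q(q), ids)

  m <- genotype_matrix(calls, ploidy = ploidy, encoding = cfg$encoding)
  truth <- list(ancestral_freqs = freqs, q_true = q, ploidy_true = ploidy,
                species_true = species, dosage_true = dosage,
                clean_calls = clean, corrupted_pairs = character(0))
  list(matrix = m, truth = truth)
}

#' Map true admixture proportions to species labels
#'
#' The deterministic ground-truth labelling used by the simulator. With
#' six clusters the shipped rule table is applied to the true q row (an
#' accession is labelled with the top-scoring species when that score is
#' at least `min_score`, otherwise `"SOL"`). For other cluster counts a
#' dominant-cluster map is used: a cluster holding at least `dominant`
#' of the ancestry labels the accession with that cluster's species from
#' `palette`, anything more admixed is `"SOL"`.
#'
#' @param q Accessions x K matrix of true admixture proportions.
#' @param rules Rule table used when K = 6.
#' @param min_score Minimum rule score for a six-cluster label.
#' @param dominant Dominance threshold for the generic map.
#' @param palette Species codes assigned to clusters under the generic map.
#' @return Character vector of species codes.
#' @export
species_from_q <- function(q, rules = default_rule_table(),
                           min_score = 0.95, dominant = 0.6,
                           palette = c("PHU", "TBR", "CHA",
                                       "AJH", "STN", "ADG")) {
  K <- ncol(q)
  n <- nrow(q)
  out <- character(n)
  if (K == 6L) {
    for (i in seq_len(n)) {
      call <- classify_q(as.numeric(q[i, ]), rules)
      out[i] <- if (call$score >= min_score) call$primary else "SOL"
    }
  } else {
    palette <- rep_len(palette, K)
    for (i in seq_len(n)) {
      k <- which.max(q[i, ])
      out[i] <- if (q[i, k] >= dominant) palette[k] else "SOL"
    }
  }
  out
}

#' Duplicate mother accessions into mother / in-vitro pairs
#'
#' Every accession of the input matrix becomes a mother; its in-vitro
#' partner re-samples noise (adjacent-class miscalls and missingness)
#' from the same clean genotype. With probability `pair_error_rate` the
#' partner instead carries the clean genotype of a different, randomly
#' chosen accession, emulating handling and labelling errors; such pair
#' ids are recorded as corrupted ground truth.
#'
#' @param sim Result of [simulate_accessions()] (matrix + truth).
#' @param cfg The [sim_config()] used to generate it.
#' @return List with `matrix` (mothers + `_iv` partners, in-vitro rows
#'   carry their mother's ploidy), `pairs` (data.frame `pair_id`,
#'   `mother_id`, `invitro_id`) and `truth` (updated with
#'   `corrupted_pairs`).
#' @export
make_pairs <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- sim$matrix
  truth <- sim$truth
  set.seed(cfg$seed + 3L)
  scale <- encoding_scale(m$encoding)
  ids <- rownames(m$calls)
  n <- length(ids)
  clean <- truth$clean_calls

  swapped <- stats::runif(n) < cfg$pair_error_rate
  if (n < 2L) swapped[] <- FALSE
  source_row <- seq_len(n)
  for (i in which(swapped)) {
    source_row[i] <- sample(seq_len(n)[-i], 1L)
  }

  iv <- clean[source_row, , drop = FALSE]
  iv <- corrupt_calls(iv, cfg$call_error_rate, scale)
  iv[stats::runif(length(iv)) < cfg$missing_rate] <- NA_integer_
  iv_ids <- paste0(ids, "_iv")
  rownames(iv) <- iv_ids

  calls <- rbind(m$calls, iv)
  ploidy <- c(m$ploidy, stats::setNames(m$ploidy[ids], iv_ids))
  combined <- genotype_matrix(calls, ploidy = ploidy, encoding = m$encoding)
  pairs <- data.frame(pair_id = ids, mother_id = ids, invitro_id = iv_ids,
                      stringsAsFactors = FALSE)
  truth$corrupted_pairs <- ids[swapped]
  list(matrix = combined, pairs = pairs, truth = truth)
}

#' Simulate a complete collection with paired samples
#'
#' Convenience wrapper chaining [simulate_ancestral_freqs()],
#' [simulate_accessions()] and [make_pairs()], and assembling the
#' accession metadata table (species and ploidy as *declared*, i.e. the
#' simulated truth, which QC stages may then challenge).
#'
#' @param cfg A [sim_config()].
#' @param pairs Generate mother / in-vitro pairs? Default `TRUE`.
#' @return List of class `"sim_collection"` with elements `matrix`,
#'   `pairs` (or `NULL`), `meta` (metadata data.frame), `truth` and `cfg`.
#' @export
simulate_collection <- function(cfg = sim_config(), pairs = TRUE) {
  freqs <- simulate_ancestral_freqs(cfg)
  sim <- simulate_accessions(cfg, freqs)
  if (pairs) {
    pr <- make_pairs(sim, cfg)
    mat <- pr$matrix
    pair_tab <- pr$pairs
    truth <- pr$truth
  } else {
    mat <- sim$matrix
    pair_tab <- NULL
    truth <- sim$truth
  }
  mothers <- rownames(sim$matrix$calls)
  all_ids <- rownames(mat$calls)
  role <- ifelse(all_ids %in% mothers,
                 if (pairs) "mother" else "single", "in_vitro")
  base_id <- sub("_iv$", "", all_ids)
  meta <- data.frame(accession_id = all_ids,
                     species_code = truth$species_true[base_id],
                     declared_ploidy = unname(truth$ploidy_true[base_id]),
                     country = "SIM",
                     sample_role = role,
                     pair_id = if (pairs) base_id else NA_character_,
                     stringsAsFactors = FALSE)
  structure(list(matrix = mat, pairs = pair_tab, meta = meta,
                 truth = truth, cfg = cfg),
            class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  cat(sprintf("sim_collection: %d samples x %d markers (K_true=%d)\n",
              nrow(x$matrix$calls), ncol(x$matrix$calls), x$cfg$K_true))
  if (!is.null(x$pairs))
    cat(sprintf("  %d mother/in-vitro pairs, %d corrupted\n",
                nrow(x$pairs), length(x$truth$corrupted_pairs)))
  invisible(x)
}

#' Write a simulated collection and its ground truth to disk
#'
#' Emits the pipeline's exchange formats (genotype TSV, metadata CSV,
#' pairs CSV) plus a ground-truth bundle (one CSV per component) and the
#' configuration echoed as round-trip-stable `key = value` lines.
#'
#' @param sim A `"sim_collection"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- character(0)
  p <- function(x) file.path(dir, x)
  write_genotype_table(sim$matrix, p("genotypes.tsv"))
  f <- c(f, p("genotypes.tsv"))
  write_metadata(sim$meta, p("metadata.csv"))
  f <- c(f, p("metadata.csv"))
  if (!is.null(sim$pairs)) {
    utils::write.table(sim$pairs, p("pairs.csv"), sep = ",", quote = FALSE,
                       row.names = FALSE)
    f <- c(f, p("pairs.csv"))
  }
  tr <- sim$truth
  utils::write.table(data.frame(accession_id = rownames(tr$q_true),
                                round(tr$q_true, 6)),
                     p("truth_q.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(accession_id = names(tr$ploidy_true),
                                ploidy = unname(tr$ploidy_true),
                                species = unname(tr$species_true)),
                     p("truth_labels.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(pop = rownames(tr$ancestral_freqs),
                                round(tr$ancestral_freqs, 6)),
                     p("truth_freqs.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeLines(tr$corrupted_pairs, p("truth_corrupted_pairs.txt"))
  write_sim_config(sim$cfg, p("config.txt"))
  f <- c(f, p("truth_q.csv"), p("truth_labels.csv"), p("truth_freqs.csv"),
         p("truth_corrupted_pairs.txt"), p("config.txt"))
  invisible(f)
}

#' @rdname write_simulation
#' @param cfg A [sim_config()].
#' @param path Config file path.
#' @export
write_sim_config <- function(cfg, path) {
  fmt <- function(v) paste(format(v, digits = 15, scientific = FALSE),
                           collapse = ",")
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    if (!is.null(names(v)) && nm == "ploidy_mix")
      sprintf("%s = %s", nm,
              paste(sprintf("%s:%s", names(v), format(v, digits = 15)),
                    collapse = ","))
    else sprintf("%s = %s", nm, fmt(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_simulation
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L,
                                                       FUN.VALUE = ""))
  mix <- strsplit(strsplit(vals[["ploidy_mix"]], ",")[[1]], ":")
  ploidy_mix <- stats::setNames(as.numeric(vapply(mix, `[[`, 2L, FUN.VALUE = "")),
                                vapply(mix, `[[`, 1L, FUN.VALUE = ""))
  num <- function(nm) as.numeric(strsplit(vals[[nm]], ",")[[1]])
  sim_config(n_accessions = num("n_accessions"), n_markers = num("n_markers"),
             K_true = num("K_true"), fst = num("fst"), alpha = num("alpha"),
             ploidy_mix = ploidy_mix, missing_rate = num("missing_rate"),
             call_error_rate = num("call_error_rate"),
             pair_error_rate = num("pair_error_rate"),
             encoding = vals[["encoding"]], seed = num("seed"))
}
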