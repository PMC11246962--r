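## STRUCTURE-style Bayesian admixture for arbitrary-ploidy dosage
## genotypes: model fitting, replicate management, label alignment and
## Evanno delta-K model selection.

resolve_dosage <- function(m, ploidy = NULL) {
  if (inherits(m, "genotype_matrix")) {
    pl <- if (!is.null(ploidy)) ploidy else m$ploidy
    if (is.null(pl)) stop("per-accession ploidy required for admixture")
    dosage <- as_dosage(m, pl)
    list(dosage = dosage, ploidy = as.integer(pl[rownames(dosage)]))
  } else {
    if (is.null(ploidy)) stop("supply ploidy alongside a raw dosage matrix")
    pl <- if (!is.null(names(ploidy))) ploidy[rownames(m)] else ploidy
    storage.mode(m) <- "integer"
    list(dosage = m, ploidy = as.integer(pl))
  }
}

#' Fit the admixture model by Gibbs sampling
#'
#' Bayesian admixture with independent allele frequencies: population
#' frequencies carry a Beta(lambda, lambda) prior per locus, accessions a
#' Dirichlet(alpha) admixture prior, and every accession contributes
#' ploidy allele copies per locus whose dosage call is treated as an
#' exact B-copy count with a latent partition among populations. Missing
#' calls contribute nothing to the likelihood. Returns the posterior-mean
#' Q-matrix and the mean recorded-sweep log-likelihood L(K) used for
#' model selection.
#'
#' Default chain lengths (2,000 burn-in + 2,000 recorded sweeps) are
#' desk-scale; production-fidelity lengths can be passed through the same
#' arguments.
#'
#' @param m A `genotype_matrix` (five-cluster calls are converted to
#'   dosages via the accession's ploidy) or an integer dosage matrix with
#'   accession rownames and marker colnames.
#' @param K Number of ancestral populations (>= 1).
#' @param ploidy Named per-accession ploidy; defaults to `m$ploidy`.
#' @param lambda Allele-frequency prior parameter; default 0.5433.
#' @param alpha Admixture Dirichlet parameter (fixed); default 0.2.
#' @param burn_in,reps Burn-in and recorded sweeps.
#' @param seed Integer seed; identical seed and data give identical fits
#'   regardless of accession row order.
#' @param conv_tol Maximum absolute difference between split-half Q
#'   estimates (max over entries) before the fit is flagged unconverged;
#'   default 0.15.
#' @return Object of class `"admix_fit"`: `Q` (accessions x K
#'   posterior-mean admixture proportions), `P` (K x markers posterior
#'   mean frequencies), `log_lik` (mean over recorded sweeps),
#'   `log_lik_trace`, `K`, `converged`, `split_half_diff`, and the call
#'   parameters.
#' @examples
#' \donttest{
#' sim <- simulate_collection(sim_config(n_accessions = 40, n_markers = 60,
#'                                       seed = 7), pairs = FALSE)
#' fit <- fit_admixture(sim$matrix, K = 3, burn_in = 200, reps = 200)
#' head(coef(fit))
#' }
#' @export
fit_admixture <- function(m, K, ploidy = NULL, lambda = 0.5433, alpha = 0.2,
                          burn_in = 2000L, reps = 2000L, seed = 1L,
                          conv_tol = 0.15) {
  dp <- resolve_dosage(m, ploidy)
  dosage <- dp$dosage
  if (K > nrow(dosage)) stop("K exceeds the number of accessions")
  res <- gibbs_admixture_cpp(dosage, dp$ploidy, rownames(dosage),
                             colnames(dosage), as.integer(K), lambda, alpha,
                             as.integer(burn_in), as.integer(reps),
                             as.numeric(seed))
  Q <- res$Q
  dimnames(Q) <- list(rownames(dosage), paste0("pop", seq_len(K)))
  P <- res$P
  dimnames(P) <- list(paste0("pop", seq_len(K)), colnames(dosage))
  shd <- max(abs(res$Q_first_half - res$Q_second_half))
  structure(list(Q = Q, P = P, log_lik = mean(res$loglik),
                 log_lik_trace = res$loglik, K = as.integer(K),
                 lambda = lambda, alpha = alpha,
                 burn_in = as.integer(burn_in), reps = as.integer(reps),
                 seed = as.integer(seed), split_half_diff = shd,
                 converged = shd <= conv_tol,
                 n_accessions = nrow(dosage), n_markers = ncol(dosage)),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K=%d, %d accessions x %d markers\n",
              x$K, x$n_accessions, x$n_markers))
  cat(sprintf("  mean log-likelihood %.2f over %d sweeps (burn-in %d)\n",
              x$log_lik, x$reps, x$burn_in))
  cat(sprintf("  lambda %.4g, alpha %.4g; split-half max |dQ| %.4f%s\n",
              x$lambda, x$alpha, x$split_half_diff,
              if (x$converged) "" else " [UNCONVERGED]"))
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  cat(sprintf("Admixture fit, K = %d\n", object$K))
  print.admix_fit(object)
  assigned <- apply(object$Q, 1L, which.max)
  cat("  accessions per dominant cluster:\n")
  print(table(factor(assigned, levels = seq_len(object$K),
                     labels = colnames(object$Q))))
  invisible(object)
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$log_lik, df = NA_integer_, class = "logLik")
}

#' @export
plot.admix_fit <- function(x, sort_by = "cluster", ...) {
  Q <- x$Q
  if (identical(sort_by, "cluster")) {
    dom <- apply(Q, 1L, which.max)
    strength <- Q[cbind(seq_len(nrow(Q)), dom)]
    Q <- Q[order(dom, -strength), , drop = FALSE]
  }
  graphics::barplot(t(Q), col = grDevices::hcl.colors(x$K, "Dark 3"),
                    border = NA, space = 0, las = 2,
                    cex.names = min(0.7, 40 / nrow(Q)),
                    ylab = "ancestry proportion", ...)
  invisible(x)
}

#' Simulate dosage matrices from a fitted admixture model
#'
#' Draws new binomial dosage calls from the posterior-mean Q and P of a
#' fit (each accession's calls are Binomial(ploidy, sum_k q_ik p_kl)).
#'
#' @param object An `admix_fit`.
#' @param nsim Number of matrices.
#' @param seed RNG seed.
#' @param ploidy Named per-accession ploidy used in the fit.
#' @param ... Unused.
#' @return List of `nsim` integer dosage matrices.
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = NULL,
                               ploidy = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ploidy))
    stop("supply the named per-accession ploidy used in the fit")
  mfreq <- object$Q %*% object$P
  ids <- rownames(object$Q)
  pl <- ploidy[ids]
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    d <- matrix(stats::rbinom(length(mfreq), rep(pl, ncol(mfreq)),
                              as.vector(mfreq)),
                nrow = nrow(mfreq),
                dimnames = list(ids, colnames(object$P)))
    out[[s]] <- d
  }
  out
}

#' Align cluster labels across replicate Q-matrices
#'
#' Gibbs replicates identify clusters only up to label permutation. Each
#' run's columns are permuted to best match the first run: exhaustively
#' over all K! permutations for K <= 8 (maximising the summed column-wise
#' agreement, i.e. minimising total absolute difference), greedily on
#' column correlation above that.
#'
#' @param runs List of Q-matrices with identical dimensions and row order.
#' @return List of aligned Q-matrices; attribute `"permutations"` records
#'   the column order applied to each run.
#' @export
align_labels <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L) stop("runs must be a list")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must share dimensions")
  K <- ncol(runs[[1]])
  ref <- runs[[1]]
  perms <- vector("list", length(runs))
  perms[[1]] <- seq_len(K)
  if (length(runs) == 1L) {
    attr(runs, "permutations") <- perms
    return(runs)
  }
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  cost <- function(Q, perm) sum(abs(Q[, perm, drop = FALSE] - ref))
  for (r in seq_along(runs)[-1]) {
    Q <- runs[[r]]
    if (K <= 8L) {
      cand <- all_perms(seq_len(K))
      costs <- vapply(cand, function(p) cost(Q, p), numeric(1))
      best <- cand[[which.min(costs)]]
    } else {
      # greedy: repeatedly take the best remaining column correlation
      cc <- suppressWarnings(stats::cor(ref, Q))
      cc[is.na(cc)] <- 0
      best <- integer(K)
      used_ref <- used_run <- logical(K)
      for (step in seq_len(K)) {
        idx <- which(cc == max(cc[!used_ref, !used_run, drop = FALSE]),
                     arr.ind = TRUE)
        idx <- idx[!used_ref[idx[, 1]] & !used_run[idx[, 2]], , drop = FALSE]
        i <- idx[1, 1]; j <- idx[1, 2]
        best[i] <- j
        used_ref[i] <- used_run[j] <- TRUE
        cc[i, ] <- -Inf; cc[, j] <- -Inf
      }
    }
    runs[[r]] <- Q[, best, drop = FALSE]
    colnames(runs[[r]]) <- colnames(ref)
    perms[[r]] <- best
  }
  attr(runs, "permutations") <- perms
  runs
}

#' Evanno delta-K statistic
#'
#' DeltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' defined for interior K with at least two replicates and positive
#' replicate standard deviation; the argmax is the selected K.
#'
#' @param diagnostics Data.frame with columns `K`, `replicate`,
#'   `log_lik` (one row per run).
#' @return List of class `"evanno"`: `table` (per K: `mean_log_lik`,
#'   `sd_log_lik`, `delta_k`, `note`) and `selected_k` (`NA` when no
#'   interior K admits the statistic).
#' @export
evanno_delta_k <- function(diagnostics) {
  stopifnot(all(c("K", "replicate", "log_lik") %in% names(diagnostics)))
  ks <- sort(unique(diagnostics$K))
  if (!all(diff(ks) == 1L) && length(ks) > 1L)
    stop("K values must form a contiguous range")
  mean_l <- vapply(ks, function(k)
    mean(diagnostics$log_lik[diagnostics$K == k]), numeric(1))
  sd_l <- vapply(ks, function(k)
    stats::sd(diagnostics$log_lik[diagnostics$K == k]), numeric(1))
  delta <- rep(NA_real_, length(ks))
  note <- rep("", length(ks))
  for (j in seq_along(ks)) {
    if (j == 1L || j == length(ks)) {
      note[j] <- "no neighbour"
    } else if (is.na(sd_l[j]) || sd_l[j] == 0) {
      note[j] <- "sd zero or single replicate: delta-K undefined"
    } else {
      delta[j] <- abs(mean_l[j + 1] - 2 * mean_l[j] + mean_l[j - 1]) / sd_l[j]
    }
  }
  tab <- data.frame(K = ks, mean_log_lik = mean_l, sd_log_lik = sd_l,
                    delta_k = delta, note = note, stringsAsFactors = FALSE)
  sel <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  structure(list(table = tab, selected_k = sel), class = "evanno")
}

#' @export
print.evanno <- function(x, ...) {
  cat("Evanno delta-K table:\n")
  print(x$table, row.names = FALSE, digits = 6)
  if (is.na(x$selected_k)) {
    cat("no interior K admits delta-K (need >= 3 K values with replicates)\n")
  } else {
    cat(sprintf("selected K = %d\n", x$selected_k))
  }
  invisible(x)
}

#' Run replicated admixture fits over a range of K
#'
#' Orchestrates `n_replicates` independent chains per K (seeds derived
#' from `seed` by fixed offsets), aligns replicate labels within each K,
#' averages the aligned Q-matrices, and applies [evanno_delta_k()].
#' Deterministic given `seed`.
#'
#' @param m Genotype matrix or dosage matrix (see [fit_admixture()]).
#' @param k_range Contiguous integer range of K values.
#' @param ploidy,lambda,alpha,burn_in,reps As [fit_admixture()].
#' @param n_replicates Independent runs per K; default 3.
#' @param seed Master seed.
#' @return List of class `"k_sweep"`: `diagnostics` (K, replicate,
#'   log_lik, converged), `evanno`, `selected_k`, `Q_by_k` (replicate-
#'   averaged aligned Q per K), `fits` (the first-replicate fit per K).
#' @export
run_k_sweep <- function(m, k_range, ploidy = NULL, lambda = 0.5433,
                        alpha = 0.2, burn_in = 2000L, reps = 2000L,
                        n_replicates = 3L, seed = 1L) {
  k_range <- sort(as.integer(k_range))
  stopifnot(length(k_range) >= 1L, all(diff(k_range) == 1L))
  diagnostics <- NULL
  Q_by_k <- list()
  fits <- list()
  for (K in k_range) {
    reps_q <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      sub_seed <- seed + 1000L * K + r
      fit <- fit_admixture(m, K, ploidy = ploidy, lambda = lambda,
                           alpha = alpha, burn_in = burn_in, reps = reps,
                           seed = sub_seed)
      reps_q[[r]] <- fit$Q
      if (r == 1L) fits[[as.character(K)]] <- fit
      diagnostics <- rbind(diagnostics,
                           data.frame(K = K, replicate = r,
                                      log_lik = fit$log_lik,
                                      converged = fit$converged))
    }
    aligned <- align_labels(reps_q)
    Q_by_k[[as.character(K)]] <- Reduce(`+`, aligned) / length(aligned)
  }
  ev <- if (length(k_range) >= 3L) evanno_delta_k(diagnostics) else NULL
  structure(list(diagnostics = diagnostics, evanno = ev,
                 selected_k = if (is.null(ev)) NA_integer_ else ev$selected_k,
                 Q_by_k = Q_by_k, fits = fits, k_range = k_range),
            class = "k_sweep")
}

#' @export
print.k_sweep <- function(x, ...) {
  cat(sprintf("k_sweep over K = %d..%d (%d replicates each)\n",
              min(x$k_range), max(x$k_range),
              max(x$diagnostics$replicate)))
  if (is.null(x$evanno)) {
    cat("delta-K table empty: fewer than three K values, no interior K\n")
  } else {
    print(x$evanno)
  }
  invisible(x)
}

#' Export a Q-matrix as CSV
#'
#' @param Q Accessions x K matrix.
#' @param path Output path.
#' @param digits Fixed decimal places; default 6.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(Q, path, digits = 6L) {
  df <- data.frame(accession_id = rownames(Q),
                   format(round(Q, digits), nsmall = digits,
                          trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
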