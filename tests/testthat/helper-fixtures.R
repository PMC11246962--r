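# shared fixture builders: everything is generated in code at test time

tiny_calls <- function(values, ids = NULL, markers = NULL) {
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(ids)) ids <- paste0("a", seq_len(n))
  if (is.null(markers)) markers <- paste0("m", seq_len(m))
  matrix(as.integer(values), n, m, dimnames = list(ids, markers))
}

random_genotype_matrix <- function(n, m, scale = 4L, missing = 0.1,
                                   seed = 1L) {
  set.seed(seed)
  calls <- matrix(sample(0:scale, n * m, replace = TRUE), n, m,
                  dimnames = list(sprintf("acc%03d", seq_len(n)),
                                  sprintf("mk%03d", seq_len(m))))
  calls[runif(n * m) < missing] <- NA_integer_
  genotype_matrix(calls,
                  encoding = if (scale == 4L) "five_cluster"
                             else "three_cluster")
}

single_ploidy_config <- function(ploidy, n = 200L, markers = 300L,
                                 seed = 1L, ...) {
  mix <- stats::setNames(as.numeric(c("2", "3", "4", "5") ==
                                      as.character(ploidy)),
                         c("2", "3", "4", "5"))
  sim_config(n_accessions = n, n_markers = markers, K_true = 3L,
             ploidy_mix = mix, seed = seed, pair_error_rate = 0, ...)
}

random_distance_matrix <- function(n, seed = 1L, ids = NULL) {
  set.seed(seed)
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(n))
  x <- matrix(runif(n * 3), n, 3)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(ids, ids)
  d
}
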