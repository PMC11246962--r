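# paired-sample fingerprint QC: concordance, verdicts, error rate,
# duplicate grouping

test_that("concordance follows the joint-call rule and is symmetric", {
  expect_equal(concordance(rep(2L, 10), rep(2L, 10)),
               list(concordance = 1.0, overlap = 10L))
  a <- c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L)
  b <- a; b[c(3, 8)] <- c(4L, 0L)
  expect_equal(concordance(a, b)$concordance, 0.8)
  expect_equal(concordance(c(0L, 2L, NA), c(0L, 2L, 4L)),
               list(concordance = 1.0, overlap = 2L))
  expect_equal(concordance(a, b), concordance(b, a))
  expect_true(is.na(concordance(c(NA, 1L), c(0L, NA))$concordance))
})

test_that("verdicts and error rate follow the threshold contract", {
  pairs <- data.frame(pair_id = paste0("p", 1:4),
                      mother_id = paste0("m", 1:4),
                      invitro_id = paste0("v", 1:4),
                      concordance = c(1, 0.99, 0.5, 0.985),
                      overlap = c(100L, 100L, 100L, 100L))
  ps <- classify_pairs(pairs, threshold = 0.98, min_overlap = 50L)
  expect_equal(ps$error_rate, 0.25)
  expect_equal(ps$n_mismatch, 1L)

  # insufficient overlap is excluded from the denominator
  pairs$overlap[4] <- 10L
  ps2 <- classify_pairs(pairs, threshold = 0.98, min_overlap = 50L)
  expect_equal(ps2$n_insufficient, 1L)
  expect_equal(ps2$error_rate, 1 / 3)

  pairs$concordance <- 1
  pairs$overlap <- 100L
  expect_equal(classify_pairs(pairs, 0.98, 50L)$error_rate, 0)
  expect_error(classify_pairs(pairs[0, ], 0.98, 50L), "empty pair set")
})

test_that("injected pair errors are recovered within the binomial CI", {
  cfg <- sim_config(n_accessions = 2000L, n_markers = 300L,
                    pair_error_rate = 0.2, seed = 31)
  sim <- simulate_collection(cfg)
  ps <- classify_pairs(pair_concordance(sim$matrix, sim$pairs),
                       threshold = 0.98, min_overlap = 150L)
  ci <- qnorm(c(0.005, 0.995), 0.2, sqrt(0.2 * 0.8 / 2000))
  expect_gt(ps$error_rate, ci[1])
  expect_lt(ps$error_rate, ci[2])
  # verdicts agree with ground truth almost everywhere
  truth_bad <- ps$pairs$pair_id %in% sim$truth$corrupted_pairs
  called_bad <- ps$pairs$verdict == "mismatch"
  expect_gt(mean(truth_bad == called_bad), 0.99)
})

test_that("error rate is invariant to pair order and double-missing loci", {
  m <- random_genotype_matrix(10, 60, seed = 32)
  pairs <- data.frame(pair_id = paste0("p", 1:5),
                      mother_id = rownames(m$calls)[1:5],
                      invitro_id = rownames(m$calls)[6:10])
  base <- classify_pairs(pair_concordance(m, pairs), 0.9, 10L)
  shuf <- classify_pairs(pair_concordance(m, pairs[5:1, ]), 0.9, 10L)
  expect_equal(base$error_rate, shuf$error_rate)

  # add a marker missing in both members of every pair: nothing changes
  calls2 <- cbind(m$calls, extra = NA_integer_)
  m2 <- genotype_matrix(calls2)
  with_extra <- classify_pairs(pair_concordance(m2, pairs), 0.9, 10L)
  expect_equal(with_extra$pairs$concordance, base$pairs$concordance)
})

test_that("duplicate grouping equals brute-force single linkage", {
  brute_groups <- function(m, threshold) {
    ids <- rownames(m$calls)
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      cc <- concordance(m$calls[i, ], m$calls[j, ])
      adj[i, j] <- !is.na(cc$concordance) && cc$concordance >= threshold
    }
    # transitive closure
    repeat {
      nxt <- adj | (adj %*% adj > 0)
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    groups <- unique(lapply(seq_len(n), function(i) sort(ids[adj[i, ]])))
    groups[order(vapply(groups, `[[`, "", 1L))]
  }
  for (seed in 1:5) {
    m <- random_genotype_matrix(12, 15, missing = 0.2, seed = seed)
    for (th in c(0.6, 0.8, 0.95)) {
      got <- duplicate_groups(m, threshold = th)
      expect_equal(got$groups, brute_groups(m, th),
                   label = sprintf("seed %d th %.2f", seed, th))
    }
  }
})

test_that("identical rows group together; grouping ignores row order", {
  calls <- tiny_calls(rbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(4, 4, 4, 4)),
                      ids = c("x1", "x2", "y1"))
  dg <- duplicate_groups(genotype_matrix(calls), 0.995)
  expect_true(any(vapply(dg$groups, identical, TRUE, c("x1", "x2"))))
  perm <- genotype_matrix(calls[c(3, 1, 2), ])
  expect_equal(duplicate_groups(perm, 0.995)$groups, dg$groups)
})

test_that("collections from disjoint populations share no duplicates", {
  cfg1 <- sim_config(n_accessions = 40L, n_markers = 200L, seed = 33,
                     pair_error_rate = 0)
  cfg2 <- sim_config(n_accessions = 40L, n_markers = 200L, seed = 34,
                     pair_error_rate = 0)
  s1 <- simulate_accessions(cfg1, id_prefix = "GBA")
  s2 <- simulate_accessions(cfg2, id_prefix = "GBB")
  joint <- genotype_matrix(rbind(s1$matrix$calls, s2$matrix$calls))
  dg <- duplicate_groups(joint, threshold = 0.995)
  cross <- vapply(dg$groups, function(g)
    any(grepl("^GBA", g)) && any(grepl("^GBB", g)), logical(1))
  expect_false(any(cross))
})
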