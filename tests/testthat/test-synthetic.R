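# synthetic collection generator: differentiation model, admixture
# sampling, dosage model, pair corruption, determinism

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(missing_rate = 1.2), "rates")
  expect_error(sim_config(ploidy_mix = c("2" = 0.5, "4" = 0.4)), "sum to 1")
  expect_error(sim_config(encoding = "three_cluster"), "all-diploid")
})

test_that("population frequencies follow the differentiation model", {
  # mean p and variance p(1-p)F, checked on standardised residuals
  cfg <- sim_config(n_markers = 10000L, K_true = 1L, fst = 0.3, seed = 11)
  fr <- simulate_ancestral_freqs(cfg)
  p <- fr$ancestral
  z <- (fr$freqs[1, ] - p) / sqrt(p * (1 - p) * 0.3)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.05)

  # tiny fst concentrates population frequencies at the ancestral value
  cfg2 <- sim_config(n_markers = 2000L, K_true = 2L, fst = 0.001, seed = 2)
  fr2 <- simulate_ancestral_freqs(cfg2)
  expect_lt(max(abs(sweep(fr2$freqs, 2, fr2$ancestral))), 0.1)
})

test_that("tiny alpha gives near-pure admixture rows", {
  # direct-gamma oracle for P(max component > 0.99) at alpha = 0.01, K = 3
  set.seed(1000)
  g <- matrix(rgamma(3 * 20000, 0.01), ncol = 3)
  g[g == 0] <- 1e-300
  oracle <- mean(apply(g / rowSums(g), 1, max) > 0.99)

  cfg <- sim_config(n_accessions = 2000L, n_markers = 5L, K_true = 3L,
                    alpha = 0.01, seed = 3)
  sim <- simulate_accessions(cfg)
  purity <- apply(sim$truth$q_true, 1, max)
  expect_lt(abs(mean(purity > 0.99) - oracle), 0.025)
  expect_gt(mean(purity > 0.99), 0.85)
  expect_equal(unname(rowSums(sim$truth$q_true)), rep(1, 2000),
               tolerance = 1e-12)
})

test_that("true dosages respect ploidy before corruption", {
  cfg <- sim_config(n_accessions = 150L, n_markers = 50L, seed = 4)
  sim <- simulate_accessions(cfg)
  for (pl in unique(sim$truth$ploidy_true)) {
    rows <- names(sim$truth$ploidy_true)[sim$truth$ploidy_true == pl]
    expect_lte(max(sim$truth$dosage_true[rows, ]), pl)
  }
})

test_that("mean scaled dosage matches the admixture-weighted frequency", {
  cfg <- sim_config(n_accessions = 2000L, n_markers = 10L, K_true = 3L,
                    alpha = 0.3, fst = 0.3, seed = 5)
  fr <- simulate_ancestral_freqs(cfg)
  sim <- simulate_accessions(cfg, fr)
  g <- sim$truth$dosage_true / sim$truth$ploidy_true
  expected <- sim$truth$q_true %*% fr$freqs
  # per-marker averages over 2000 accessions (law of large numbers)
  diff <- abs(colMeans(g) - colMeans(expected))
  expect_lt(max(diff), 0.03)
})

test_that("pair corruption hits the configured rate and never self-pairs", {
  cfg <- sim_config(n_accessions = 2000L, n_markers = 40L,
                    pair_error_rate = 0.199, seed = 6)
  sim <- simulate_collection(cfg)
  frac <- length(sim$truth$corrupted_pairs) / 2000
  ci <- qnorm(c(0.005, 0.995), 0.199, sqrt(0.199 * 0.801 / 2000))
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])

  # with certain corruption, no in-vitro partner is its own mother clone
  cfg2 <- sim_config(n_accessions = 40L, n_markers = 300L,
                     pair_error_rate = 1, missing_rate = 0,
                     call_error_rate = 0, seed = 7)
  sim2 <- simulate_collection(cfg2)
  pc <- pair_concordance(sim2$matrix, sim2$pairs)
  expect_true(all(pc$concordance < 0.999))
})

test_that("zero pair error leaves every pair concordant up to noise", {
  cfg <- sim_config(n_accessions = 80L, n_markers = 200L,
                    pair_error_rate = 0, seed = 8)
  sim <- simulate_collection(cfg)
  pc <- pair_concordance(sim$matrix, sim$pairs)
  expect_true(all(pc$concordance > 0.95))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_accessions = 30L, n_markers = 40L, seed = 9)
  a <- simulate_collection(cfg)
  b <- simulate_collection(cfg)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("mean heterozygosity increases with ploidy", {
  het_mean <- vapply(2:4, function(pl) {
    sim <- simulate_accessions(single_ploidy_config(pl, n = 500L,
                                                    markers = 120L,
                                                    seed = 20 + pl))
    mean(heterozygosity_table(sim$matrix)$het_pct)
  }, numeric(1))
  expect_true(all(diff(het_mean) > 0))
})

test_that("simulation config round-trips through its key=value file", {
  cfg <- sim_config(n_accessions = 17L, n_markers = 23L, K_true = 4L,
                    fst = c(0.1, 0.2, 0.15, 0.3), alpha = 0.37, seed = 99)
  f <- withr::local_tempfile()
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
})
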