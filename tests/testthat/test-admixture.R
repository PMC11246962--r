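# admixture Gibbs sampler, label alignment and Evanno delta-K

small_sim <- function(seed = 70, n = 40L, m = 60L, alpha = 0.2) {
  simulate_accessions(sim_config(n_accessions = n, n_markers = m,
                                 K_true = 3L, alpha = alpha, fst = 0.25,
                                 seed = seed, pair_error_rate = 0))
}

test_that("K = 1 gives a degenerate simplex and identical reruns match", {
  sim <- small_sim()
  f1 <- fit_admixture(sim$matrix, K = 1, burn_in = 100, reps = 100, seed = 1)
  expect_true(all(coef(f1) == 1))
  fa <- fit_admixture(sim$matrix, K = 3, burn_in = 200, reps = 200, seed = 5)
  fb <- fit_admixture(sim$matrix, K = 3, burn_in = 200, reps = 200, seed = 5)
  expect_identical(coef(fa), coef(fb))
  expect_identical(fa$log_lik_trace, fb$log_lik_trace)
})

test_that("Q rows lie on the simplex and P in the open unit interval", {
  sim <- small_sim(71)
  fit <- fit_admixture(sim$matrix, K = 3, burn_in = 200, reps = 200, seed = 2)
  expect_lt(max(abs(rowSums(coef(fit)) - 1)), 1e-9)
  expect_true(all(coef(fit) >= 0))
  expect_true(all(fit$P > 0 & fit$P < 1))
})

test_that("a dominant frequency prior shrinks P toward one half", {
  sim <- small_sim(72, n = 12L, m = 30L)
  fit <- fit_admixture(sim$matrix, K = 2, lambda = 5000, burn_in = 200,
                       reps = 200, seed = 3)
  expect_lt(max(abs(fit$P - 0.5)), 0.1)
})

test_that("permuting accession rows permutes Q rows identically", {
  sim <- small_sim(73, n = 25L, m = 40L)
  dosage <- as_dosage(sim$matrix)
  pl <- sim$truth$ploidy_true
  f1 <- fit_admixture(dosage, K = 3, ploidy = pl, burn_in = 150,
                      reps = 150, seed = 4)
  perm <- sample(nrow(dosage))
  f2 <- fit_admixture(dosage[perm, ], K = 3, ploidy = pl, burn_in = 150,
                      reps = 150, seed = 4)
  expect_identical(coef(f1)[rownames(dosage)[perm], ], coef(f2))
})

test_that("near-pure populations yield an indicator-like Q", {
  sim <- simulate_accessions(sim_config(n_accessions = 90L,
                                        n_markers = 300L, K_true = 3L,
                                        alpha = 0.005, fst = 0.35,
                                        seed = 74, pair_error_rate = 0))
  fit <- fit_admixture(sim$matrix, K = 3, burn_in = 800, reps = 800,
                       seed = 6)
  purity <- apply(coef(fit), 1, max)
  expect_gt(mean(purity > 0.95), 0.90)
})

test_that("model-based simulation reproduces the fitted dosage scale", {
  sim <- small_sim(75, n = 20L, m = 40L)
  fit <- fit_admixture(sim$matrix, K = 2, burn_in = 150, reps = 150,
                       seed = 7)
  new <- simulate(fit, nsim = 1, seed = 1,
                  ploidy = sim$truth$ploidy_true)[[1]]
  expect_equal(dim(new), dim(fit$Q %*% fit$P))
  expect_true(all(new >= 0 & new <= 5))
})

test_that("label alignment undoes column permutations and perturbations", {
  set.seed(80)
  Q <- rdirichlet(30, 0.3, 6)
  rownames(Q) <- paste0("a", 1:30)
  swapped <- Q[, c(3, 1, 2, 6, 4, 5)]
  al <- align_labels(list(Q, swapped))
  expect_equal(al[[2]], Q, ignore_attr = TRUE)
  expect_equal(attr(al, "permutations")[[2]], c(2, 3, 1, 5, 6, 4))

  # noisy permuted replicates align back within the perturbation
  reps <- lapply(1:4, function(i) {
    noise <- matrix(runif(length(Q), -0.02, 0.02), nrow(Q))
    p <- sample(6)
    qq <- pmax(Q + noise, 1e-6)[, p]
    qq / rowSums(qq)
  })
  al2 <- align_labels(c(list(Q), reps))
  for (r in 2:5) expect_lt(max(abs(al2[[r]] - Q)), 0.1)

  expect_identical(align_labels(list(Q))[[1]], Q)
  expect_error(align_labels(list(Q, Q[, 1:3])), "share dimensions")
})

test_that("delta-K is the scaled second difference of mean likelihood", {
  # exactly linear L(K): all interior delta-K are zero
  lin <- do.call(rbind, lapply(1:5, function(k)
    data.frame(K = k, replicate = 1:3,
               log_lik = -1000 + 50 * k + c(-1, 0, 1))))
  ev <- evanno_delta_k(lin)
  expect_equal(ev$table$delta_k[2:4], c(0, 0, 0))

  # single kink at K = 6 makes it the argmax
  means <- c(-900, -800, -700, -600, -500, -420, -415, -410)
  kink <- do.call(rbind, lapply(1:8, function(k)
    data.frame(K = k, replicate = 1:3,
               log_lik = means[k] + c(-2, 0, 2))))
  expect_equal(evanno_delta_k(kink)$selected_k, 6L)

  # three-point arithmetic oracle: |L3 - 2 L2 + L1| / sd(L2)
  three <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                      log_lik = c(-100, -100, -82, -78, -75, -75))
  ev3 <- evanno_delta_k(three)
  expect_equal(ev3$table$delta_k[2],
               abs(-75 - 2 * -80 + -100) / sd(c(-82, -78)))

  # zero replicate sd flags the statistic as undefined
  flat <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                     log_lik = c(-3, -3, -2, -2, -1, -1))
  evf <- evanno_delta_k(flat)
  expect_true(is.na(evf$table$delta_k[2]))
  expect_match(evf$table$note[2], "sd zero")
})

test_that("a two-value K range yields an empty delta-K table with notice", {
  sim <- small_sim(76, n = 20L, m = 30L)
  sw <- run_k_sweep(sim$matrix, 1:2, burn_in = 60, reps = 60,
                    n_replicates = 2, seed = 8)
  expect_null(sw$evanno)
  expect_true(is.na(sw$selected_k))
  expect_output(print(sw), "empty")
  # all replicate likelihoods are recorded
  expect_equal(nrow(sw$diagnostics), 4L)
})
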