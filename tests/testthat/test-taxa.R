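# rule-based species classification from admixture proportions

test_that("the shipped rule table parses to the expected constraints", {
  rt <- default_rule_table()
  phu <- rt[rt$species == "PHU", ]
  expect_setequal(phu$cluster[phu$type == "zero"],
                  c("yellow", "blue", "green"))
  teal <- phu[phu$cluster == "teal", ]
  expect_equal(c(teal$lo, teal$hi), c(80, 100))
  tbr <- rt[rt$species == "TBR", ]
  expect_equal(tbr$lo[tbr$cluster == "blue"], 50)
  expect_equal(tbr$hi[tbr$cluster == "yellow"], 10)
  gon <- rt[rt$species == "GON", ]
  expect_equal(c(gon$lo[gon$cluster == "teal"], gon$hi[gon$cluster == "teal"]),
               c(10, 40))
})

test_that("contradictory bounds are rejected at load time", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,yellow,red,blue,pink,teal,green",
               "BAD,40-10,,,,,"), f)
  expect_error(load_rule_table(f), "contradictory bounds")
})

test_that("scores agree with an independent constraint evaluator", {
  rt <- default_rule_table()
  pol <- classification_policy()
  oracle_score <- function(qp, sp) {
    rr <- rt[rt$species == sp, ]
    num <- den <- 0
    for (r in seq_len(nrow(rr))) {
      x <- qp[[rr$cluster[r]]]
      if (rr$type[r] == "zero") {
        sat <- if (x <= pol$epsilon) 1 else
          max(0, 1 - (x - pol$epsilon) / pol$tolerance)
        w <- 1 - pol$epsilon / 100
      } else {
        lo <- rr$lo[r]
        hi <- if (rr$type[r] == "low") pol$low_cap else rr$hi[r]
        dd <- max(lo - x, x - hi, 0)
        sat <- if (dd <= pol$tolerance) 1 else
          max(0, 1 - (dd - pol$tolerance) / pol$tolerance)
        w <- max(0.01, 1 - (hi - lo) / 100)
      }
      num <- num + sat * w
      den <- den + w
    }
    num / den
  }
  set.seed(90)
  for (i in 1:200) {
    q <- rdirichlet(1, 0.3, 6)[1, ]
    names(q) <- c("yellow", "red", "blue", "pink", "teal", "green")
    got <- score_species(q, rt, pol)
    qp <- q * 100
    for (sp in names(got)) {
      expect_equal(unname(got[sp]), oracle_score(qp, sp), tolerance = 1e-12)
    }
  }
})

test_that("interval boundaries give full satisfaction", {
  # TBR blue constraint is >50: exactly 50 percent must score as inside
  q_edge <- c(yellow = 0, red = 0, blue = 0.50, pink = 0, teal = 0,
              green = 0.50)
  s_edge <- score_species(q_edge)
  q_in <- c(yellow = 0, red = 0, blue = 0.60, pink = 0, teal = 0,
            green = 0.40)
  # the blue constraint itself contributes identically at 50 and 60
  expect_equal(unname(s_edge["TBR"] - score_species(q_in)["TBR"]),
               0, tolerance = 0.2)
  expect_gte(unname(s_edge["TBR"]), unname(
    score_species(replace(q_edge, "blue", 0.40))["TBR"]))
})

test_that("every published worked example classifies to its printed call", {
  ex <- utils::read.csv(system.file("extdata", "worked_examples_q.csv",
                                    package = "potapop"),
                        colClasses = c(accession_id = "character"))
  Q <- as.matrix(ex[, 2:7])
  rownames(Q) <- ex$accession_id
  calls <- classify_accessions(Q)
  expect_equal(calls$species, ex$species_prediction)
})

test_that("classification is scale- and rule-order-invariant", {
  set.seed(91)
  rt <- default_rule_table()
  perm_rt <- rt[sample(nrow(rt)), ]
  class(perm_rt) <- class(rt)
  for (i in 1:25) {
    q <- rdirichlet(1, 0.3, 6)[1, ]
    names(q) <- c("yellow", "red", "blue", "pink", "teal", "green")
    a <- classify_q(q)
    b <- classify_q(q * 100)
    expect_identical(a$primary, b$primary)
    expect_equal(a$score, b$score)
    cp <- classify_q(q, rules = perm_rt)
    expect_identical(a$primary, cp$primary)
  }
})

test_that("accuracy metrics follow the forced ratios and ordering", {
  calls <- data.frame(accession_id = paste0("a", 1:4),
                      species = c("ADG", "PHU", "TBR", "GON"),
                      score = 1, hybrid = c(FALSE, FALSE, FALSE, TRUE),
                      parent1 = c("ADG", "PHU", "TBR", "GON"),
                      parent2 = c(NA, NA, NA, "STN"))
  truth <- c("ADG", "PHU", "TBR", "STN")
  acc <- evaluate_predictions(calls, truth)
  expect_equal(acc$overall_pct, 75)
  expect_equal(acc$extended_pct, 100)

  all_right <- evaluate_predictions(calls[1:3, ], truth[1:3])
  expect_equal(all_right$overall_pct, 100)
  expect_equal(all_right$extended_pct, 100)

  # unlabelled accessions leave the denominator
  acc2 <- evaluate_predictions(calls, c("ADG", "SOL", "ND", NA))
  expect_equal(acc2$n_evaluated, 1L)
})

test_that("hybrid-extended accuracy never falls below primary accuracy", {
  set.seed(92)
  for (rep in 1:100) {
    Q <- rdirichlet(8, 0.3, 6)
    rownames(Q) <- paste0("a", 1:8)
    calls <- classify_accessions(Q)
    truth <- sample(c("ADG", "PHU", "TBR", "GON", "STN", "CHA"), 8,
                    replace = TRUE)
    acc <- evaluate_predictions(calls, truth)
    expect_gte(acc$extended_pct, acc$overall_pct)
  }
})

test_that("simulator species labels are recoverable from true Q", {
  cfg <- sim_config(n_accessions = 60L, n_markers = 10L, K_true = 6L,
                    alpha = 0.15, seed = 93, pair_error_rate = 0)
  sim <- simulate_accessions(cfg)
  labelled <- sim$truth$species_true != "SOL"
  expect_gt(sum(labelled), 5L)
  calls <- classify_accessions(sim$truth$q_true)
  acc <- evaluate_predictions(calls, sim$truth$species_true)
  expect_equal(acc$overall_pct, 100)
})
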