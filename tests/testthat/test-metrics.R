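test_that("probabilistic confusion accumulates score mass", {
  s <- patient_scores(c("A", "B", "C", "D"), c(0.7, 0.4, 0.9, 0.3))
  conf <- probabilistic_confusion(s, c("A", "C"))
  expect_equal(conf$TPs, 1.6)
  expect_equal(conf$FPs, 0.4)
  expect_equal(conf$FNs, 0.7)
  expect_equal(conf$TNs, 1.3)

  # all-zero probabilities degenerate to counting
  s0 <- patient_scores(letters[1:6], rep(0, 6))
  c0 <- probabilistic_confusion(s0, c("a", "b"))
  expect_equal(c(c0$TPs, c0$FPs, c0$FNs, c0$TNs), c(0, 2, 0, 4))

  expect_error(probabilistic_confusion(s, c("A", "ZZ")), "referential error")
})

test_that("conservation holds: cells sum to the number of scored patients", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:80, 1)
    s <- patient_scores(sprintf("p%03d", 1:n), runif(n))
    pos <- sample(s$patient_id, sample(0:n, 1))
    conf <- probabilistic_confusion(s, pos)
    expect_equal(conf$TPs + conf$FPs + conf$FNs + conf$TNs, n)
    expect_equal(conf$TPs + conf$FPs, length(pos))
  }
})

test_that("indexes follow the defining ratios and flag zero denominators", {
  s <- patient_scores(c("A", "B", "C", "D"), c(0.7, 0.4, 0.9, 0.3))
  est <- performance_indexes(probabilistic_confusion(s, c("A", "C")))
  expect_equal(est$sensitivity, 1.6 / 2.3)
  expect_equal(est$specificity, 1.3 / 1.7)
  expect_equal(est$ppv, 0.8)
  expect_equal(est$npv, 0.65)
  expect_equal(est$f_score, 2 * (1.6 / 2.3) * 0.8 / (1.6 / 2.3 + 0.8))

  # TPs == FPs forces PPV exactly 1/2
  s2 <- patient_scores(c("A", "B"), c(0.5, 0.5))
  expect_equal(performance_indexes(probabilistic_confusion(s2, c("A", "B")))$ppv,
               0.5)

  # no positives: PPV undefined and reported, not NaN-propagated
  est0 <- performance_indexes(probabilistic_confusion(s, character(0)))
  expect_true(is.na(est0$ppv))
  expect_true("ppv" %in% est0$undefined)
  expect_false(is.na(est0$sensitivity))

  conf_empty <- probabilistic_confusion(patient_scores(character(0), numeric(0)),
                                        character(0))
  expect_error(performance_indexes(conf_empty), "metrics error")
})

test_that("F-score sits between sensitivity and PPV", {
  set.seed(66)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    s <- patient_scores(sprintf("p%02d", 1:n), runif(n))
    pos <- sample(s$patient_id, sample(1:(n - 1), 1))
    est <- performance_indexes(probabilistic_confusion(s, pos))
    if (anyNA(c(est$sensitivity, est$ppv))) next
    expect_gte(est$f_score, min(est$sensitivity, est$ppv) - 1e-12)
    expect_lte(est$f_score, max(est$sensitivity, est$ppv) + 1e-12)
  }
})

test_that("0/1 scores reproduce the classical 2x2 indexes exactly", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    p <- rbinom(n, 1, 0.4)
    s <- patient_scores(sprintf("p%02d", 1:n), p)
    posm <- rbinom(n, 1, 0.5) == 1
    est <- performance_indexes(probabilistic_confusion(s, s$patient_id[posm]))
    ref <- naive_indexes(p, posm)
    got <- c(sensitivity = est$sensitivity, specificity = est$specificity,
             ppv = est$ppv, npv = est$npv, f_score = est$f_score)
    expect_identical(is.na(got), is.na(ref))
    expect_equal(got[!is.na(ref)], ref[!is.na(ref)])
  }
})

test_that("adding a certain true positive never hurts sensitivity or PPV", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- patient_scores(sprintf("p%02d", 1:n), runif(n))
    pos <- sample(s$patient_id, sample(1:n, 1))
    base <- performance_indexes(probabilistic_confusion(s, pos))
    s2 <- patient_scores(c(s$patient_id, "new"), c(s$p_case, 1))
    ext <- performance_indexes(probabilistic_confusion(s2, c(pos, "new")))
    expect_gte(ext$sensitivity, base$sensitivity - 1e-12)
    expect_gte(ext$ppv, base$ppv - 1e-12)
  }
})

test_that("bootstrap CIs are seeded, bracket the estimate and collapse for identical patients", {
  set.seed(21)
  n <- 400
  s <- patient_scores(sprintf("p%03d", 1:n), runif(n))
  pos <- sample(s$patient_id, 120)
  b1 <- bootstrap_cis(s, pos, n_reps = 300, seed = 9)
  b2 <- bootstrap_cis(s, pos, n_reps = 300, seed = 9)
  expect_identical(b1$ci, b2$ci)
  est <- performance_indexes(probabilistic_confusion(s, pos))
  for (ix in c("sensitivity", "specificity", "ppv", "npv", "f_score")) {
    expect_lte(b1$ci[ix, "lower"], est[[ix]] + 1e-12)
    expect_gte(b1$ci[ix, "upper"], est[[ix]] - 1e-12)
  }
  # identical patients: zero-width intervals
  sid <- patient_scores(sprintf("q%02d", 1:30), rep(0.6, 30))
  bid <- bootstrap_cis(sid, sid$patient_id, n_reps = 100, seed = 1)
  expect_equal(unname(bid$ci["ppv", "lower"]), 0.6)
  expect_equal(unname(bid$ci["ppv", "upper"]), 0.6)
  expect_equal(unname(bid$ci["sensitivity", 1:2]), c(1, 1))
})

test_that("the evaluation table mirrors definition structure", {
  sim <- simulate_claims(sim_config(n_patients = 3000, n_noise_codes = 30,
                                    t1d_prevalence = 0.02), seed = 51)
  sc <- oracle_scores(sim$test, sim$config)

  # two complementary definitions partition the test population
  ev <- sim$test$events
  has_hba1c <- unique(ev$patient_id[ev$code == "160010010"])
  d_yes <- case_definition("hba1c", code_predicate("procedure", "160010010"))
  # complement cannot be expressed without NOT; check N additivity instead
  res <- evaluate_definitions(sc, list(d_yes), sim$test, n_reps = 50, seed = 2)
  expect_equal(res$n_positive, length(intersect(has_hba1c,
                                                sim$test$patients$patient_id)))

  # a definition matching nobody yields an N=0 row with flagged PPV
  d_none <- case_definition("none", code_predicate("procedure", "absent_code"))
  res0 <- evaluate_definitions(sc, list(d_yes, d_none), sim$test,
                               n_reps = 50, seed = 2)
  expect_equal(res0$n_positive[2], 0)
  expect_true(is.na(res0$ppv[2]))
  expect_match(res0$undefined[2], "ppv")
  # complementary N: positives of d_yes + negatives of d_yes = all patients
  expect_equal(res0$n_positive[1] + (nrow(sim$test$patients) - res0$n_positive[1]),
               nrow(sim$test$patients))
  expect_output(print(res0), "Case definition")
})

test_that("scores must cover the evaluated population", {
  sim <- simulate_claims(sim_config(n_patients = 500, n_noise_codes = 10),
                         seed = 61)
  sc <- oracle_scores(sim$test, sim$config)
  expect_error(evaluate_definitions(sc[-1, ], builtin_definitions(), sim$test,
                                    n_reps = 10),
               "cover all test patients")
})
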