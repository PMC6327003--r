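dAB <- assay_design(c("A", "B"))

test_that("pair weights follow the homogamic/heterogamic form with biases", {
  expect_equal(pair_weight("A", "B", model_params(), dAB), 0.5)
  expect_equal(pair_weight("B", "B", model_params(), dAB), 0.5)
  expect_equal(pair_weight("A", "B", model_params(h = 1), dAB), 0)
  expect_equal(pair_weight("B", "A", model_params(h = 1), dAB), 0)
  expect_equal(pair_weight("A", "A", model_params(h = 0.5, b_female = 2), dAB),
               1.5)
  expect_equal(pair_weight("B", "A", model_params(h = 0.5, b_male = 4), dAB),
               (1 - 0.5) / 2 * 4)
})

test_that("step probabilities match hand-enumerated weights", {
  # fresh balanced chamber, random mating: uniform over the four pair types
  expect_equal(unname(step_probabilities(availability_state(dAB),
                                         model_params())),
               rep(0.25, 4))

  # availabilities 2,1 females / 1,1 males, h = 0.5: weights 3 : 1 : 0.5 : 1.5
  d <- assay_design(c("A", "B"), n_females = 2, n_males = 1, r_female = 0)
  st <- availability_state(d, female_mated = c(0, 1))
  expect_equal(unname(step_probabilities(st, model_params(h = 0.5))),
               c(1/2, 1/6, 1/12, 1/4))

  # complete isolation: heterogamic pair types have probability exactly 0
  p <- step_probabilities(availability_state(dAB), model_params(h = 1))
  expect_identical(unname(p[c("A:B", "B:A")]), c(0, 0))
  expect_equal(sum(p), 1)
})

test_that("step probabilities sum to one over random states and parameters", {
  set.seed(23)
  for (i in 1:30) {
    d <- assay_design(c("A", "B"), n_females = sample(2:12, 1),
                      n_males = sample(2:12, 1),
                      r_male = runif(1), r_female = runif(1, 0, 0.01))
    st <- availability_state(d, female_mated = sample(0:d$n_females, 2, TRUE),
                             male_mated = sample(0:(2 * d$n_males), 2, TRUE))
    p <- step_probabilities(st, model_params(runif(1, -0.95, 0.95),
                                             exp(runif(1, -2, 2)),
                                             exp(runif(1, -2, 2))))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("an exhausted chamber is reported as an error", {
  d <- assay_design(c("A", "B"), n_females = 1, n_males = 1,
                    r_male = 0, r_female = 0)
  st <- availability_state(d, female_mated = c(1, 1), male_mated = c(1, 1))
  expect_error(step_probabilities(st, model_params()), "exhausted")
})

test_that("sequence log-likelihood matches the step-by-step oracle", {
  # first event in a fresh balanced chamber at h = 0: log(1/4)
  ev1 <- events_df("A", "B")
  d1 <- assay_design(c("A", "B"), n_females = 1, n_males = 1, r_male = 0,
                     r_female = 0)
  expect_equal(sequence_loglik(ev1, dAB, model_params()), log(0.25))

  # with one female and one male left and no remating, the last step is forced
  ev2 <- events_df(c("A", "B"), c("B", "A"))
  expect_equal(sequence_loglik(ev2, d1, model_params()), log(0.25))

  # 3-event toy sequence on a 2/2/2/2 design at h = 0.5 against the oracle
  d2 <- assay_design(c("A", "B"), n_females = 2, n_males = 2,
                     r_male = 0, r_female = 0)
  fs <- c("A", "A", "B"); ms <- c("A", "B", "B")
  expect_equal(sequence_loglik(events_df(fs, ms), d2, model_params(h = 0.5)),
               log(oracle_seq_prob(fs, ms, d2, 0.5, 1, 1)))

  # randomized designs/parameters, relative error at numerical precision
  set.seed(31)
  for (i in 1:15) {
    d <- assay_design(c("A", "B"), n_females = 2, n_males = 2,
                      r_male = runif(1), r_female = runif(1, 0, 0.01))
    ds <- simulate_assay(d, model_params(runif(1, -0.8, 0.8)),
                         n_replicates = 1)
    h <- runif(1, -0.9, 0.9); bf <- exp(runif(1, -1, 1))
    bm <- exp(runif(1, -1, 1))
    ll <- sequence_loglik(ds$events, d, model_params(h, bf, bm))
    oracle <- log(oracle_seq_prob(ds$events$female_class,
                                  ds$events$male_class, d, h, bf, bm))
    expect_equal(ll, oracle, tolerance = 1e-12)
  }
})

test_that("impossible events give -Inf, not an error", {
  ev <- events_df(c("A", "A"), c("A", "B"))  # one heterogamic event
  expect_identical(sequence_loglik(ev, dAB, model_params(h = 1)), -Inf)
})

test_that("total probability over all complete orders is one without remating", {
  d <- assay_design(c("A", "B"), n_females = 2, n_males = 2,
                    r_male = 0, r_female = 0)
  expect_equal(oracle_total_prob(d, 0, 1, 1), 1, tolerance = 1e-9)
  expect_equal(oracle_total_prob(d, 0.5, 2, 0.7), 1, tolerance = 1e-9)
  d1 <- assay_design(c("A", "B"), n_females = 1, n_males = 2,
                     r_male = 0, r_female = 0)
  expect_equal(oracle_total_prob(d1, -0.4, 1.5, 1), 1, tolerance = 1e-9)
})

test_that("dataset log-likelihood is additive over replicates", {
  set.seed(41)
  ds <- simulate_assay(dAB, model_params(h = 0.4), n_replicates = 3)
  p <- model_params(h = 0.2, b_female = 1.3, b_male = 0.8)
  per_rep <- vapply(split(ds$events, ds$events$replicate),
                    sequence_loglik, numeric(1), design = dAB, params = p)
  expect_equal(dataset_loglik(ds, p), sum(per_rep))

  # duplicating a replicate doubles the log-likelihood
  one <- simulate_assay(dAB, model_params(h = 0.4), n_replicates = 1)
  two_ev <- rbind(one$events,
                  transform(one$events, replicate = "2"))
  two <- assay_dataset(two_ev, dAB)
  expect_equal(dataset_loglik(two, p), 2 * dataset_loglik(one, p))
})

test_that("relabeling classes maps h to h and biases to their reciprocals", {
  set.seed(43)
  ds <- simulate_assay(dAB, model_params(h = 0.3, b_female = 2), seed = 5)
  swapped_ev <- transform(ds$events,
                          female_class = ifelse(female_class == "A", "B", "A"),
                          male_class = ifelse(male_class == "A", "B", "A"))
  swapped <- assay_dataset(swapped_ev, dAB)
  p <- model_params(h = 0.25, b_female = 1.7, b_male = 0.6)
  p_swapped <- model_params(h = 0.25, b_female = 1 / 1.7, b_male = 1 / 0.6)
  expect_equal(dataset_loglik(swapped, p_swapped), dataset_loglik(ds, p))

  f1 <- esii(ds)
  f2 <- esii(swapped)
  expect_equal(f2$h_hat, f1$h_hat, tolerance = 1e-4)
  expect_equal(f2$b_female_hat, 1 / f1$b_female_hat, tolerance = 1e-3)
  expect_equal(f2$b_male_hat, 1 / f1$b_male_hat, tolerance = 1e-3)
})

test_that("analytic gradient agrees with numerical differentiation", {
  set.seed(47)
  ds <- simulate_assay(dAB, model_params(h = 0.5, b_male = 2), seed = 9)
  prep <- esii:::prepare_dataset(ds, 0.5, 0.001)
  theta <- c(0.3, 0.4, -0.2)
  eps <- 1e-6
  num <- vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- eps
    (esii:::loglik_theta(theta + e, prep) -
       esii:::loglik_theta(theta - e, prep)) / (2 * eps)
  }, numeric(1))
  expect_equal(esii:::grad_theta(theta, prep), num, tolerance = 1e-5)
})
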