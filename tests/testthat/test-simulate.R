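dAB <- assay_design(c("A", "B"))

test_that("complete isolation simulates only homogamic matings", {
  ds <- simulate_assay(dAB, model_params(h = 1), seed = 73)
  expect_true(all(ds$events$female_class == ds$events$male_class))
  expect_identical(naive_sii(ds)$value, 1)
})

test_that("the stop rule yields 24 events per replicate, 120 per assay", {
  seq1 <- simulate_sequence(dAB, seed = 79)
  expect_identical(nrow(seq1), 24L)
  ds <- simulate_assay(dAB, n_replicates = 5, seed = 79)
  expect_identical(n_events(ds), 120L)
  expect_identical(length(unique(ds$events$replicate)), 5L)
  # every female mates exactly once: 240 flies behind 120 matings
  per_class <- table(ds$events$replicate, ds$events$female_class)
  expect_true(all(per_class == 12L))
})

test_that("simulation is reproducible and restores the caller's RNG", {
  a <- simulate_assay(dAB, model_params(h = 0.3), seed = 83)
  b <- simulate_assay(dAB, model_params(h = 0.3), seed = 83)
  expect_identical(a$events, b$events)
  set.seed(5)
  x1 <- runif(1)
  set.seed(5)
  invisible(simulate_assay(dAB, seed = 83))
  expect_identical(runif(1), x1)
})

test_that("simulated datasets always validate against their design", {
  set.seed(89)
  for (i in 1:10) {
    d <- assay_design(c("A", "B"), n_females = sample(2:12, 1),
                      n_males = sample(2:12, 1), r_male = runif(1))
    ds <- simulate_assay(d, model_params(runif(1, -0.9, 0.9),
                                         exp(runif(1, -1.5, 1.5)),
                                         exp(runif(1, -1.5, 1.5))),
                         n_replicates = 2)
    expect_silent(validate_assay(ds))
    expect_identical(n_events(ds), 2L * 2L * d$n_females)
  }
})

test_that("first-event frequencies follow the model's step distribution", {
  params <- model_params(h = 0.5, b_female = 2)
  expected <- step_probabilities(availability_state(dAB), params)
  set.seed(97)
  first <- replicate(4000, {
    ev <- simulate_sequence(dAB, params)
    paste(ev$female_class[1], ev$male_class[1], sep = ":")
  })
  counts <- table(factor(first, levels = names(expected)))
  gof <- chisq.test(counts, p = expected)
  expect_gt(gof$p.value, 1e-4)
})

test_that("a male order bias concentrates class-A males in early ranks", {
  set.seed(101)
  ranks <- replicate(300, {
    ev <- simulate_sequence(dAB, model_params(h = 0, b_male = 3))
    mean(ev$order[ev$male_class == "A"]) - mean(ev$order[ev$male_class == "B"])
  })
  expect_lt(mean(ranks), 0)
  expect_lt(mean(ranks) + 3 * sd(ranks) / sqrt(length(ranks)), 0)
})

test_that("the homogamic fraction increases with h", {
  set.seed(103)
  frac <- vapply(c(0, 0.3, 0.6, 0.9), function(h) {
    mean(replicate(100, naive_sii(simulate_assay(dAB, model_params(h = h),
                                                 n_replicates = 1))$value))
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("scenario grids are reproducible and counted correctly", {
  scens <- lapply(c(0, 0.3, 0.6), function(h)
    list(params = model_params(h = h), n_replicates = 2))
  g1 <- simulate_scenarios(scens, master_seed = 7)
  g2 <- simulate_scenarios(scens, master_seed = 7)
  expect_identical(length(g1), 3L)
  for (i in seq_along(g1))
    expect_identical(g1[[i]]$dataset$events, g2[[i]]$dataset$events)
  expect_identical(simulate_scenarios(list(), 7), list())
  expect_identical(n_events(g1[[1]]$dataset), 48L)
})
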