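test_that("taxon pools carry recoverable planted statuses and are deterministic", {
  spec <- generator_spec(n_affiliated = 3, n_candidate = 2, seed = 9)
  pool <- simulate_pool(spec)
  expect_equal(nrow(pool), 5L)
  recovered <- classify_labels(pool$lineage, "phylum")
  expect_equal(unname(recovered), pool$status)

  empty <- simulate_pool(generator_spec(n_affiliated = 0, n_candidate = 0))
  expect_equal(nrow(empty), 0L)

  big <- simulate_pool(generator_spec(n_affiliated = 40, n_candidate = 45))
  expect_equal(sum(big$status == "affiliated"), 40L)
  expect_equal(sum(big$status == "candidate"), 45L)
  expect_equal(unname(classify_labels(big$lineage, "phylum")), big$status)
  expect_false(anyDuplicated(big$lineage) > 0)

  again <- simulate_pool(generator_spec(n_affiliated = 40, n_candidate = 45))
  expect_identical(big, again)
})

test_that("simulated profiles honour detection probabilities at the extremes", {
  spec1 <- generator_spec(n_affiliated = 6, n_candidate = 4,
                          detect_prob = list(
                            affiliated = c(V1V3 = 1, V4 = 1, V4V5 = 1,
                                           V5V8 = 1, V6V9 = 1),
                            candidate = c(V1V3 = 1, V4 = 1, V4V5 = 1,
                                          V5V8 = 1, V6V9 = 1)),
                          seed = 21)
  sim1 <- simulate_profiles(simulate_pool(spec1), spec1)
  expect_true(all(sim1$truth$unique_counts == 0))
  expect_equal(sim1$truth$shared_all, 10L)

  spec2 <- generator_spec(n_affiliated = 6, n_candidate = 4,
                          detect_prob = list(
                            affiliated = c(V1V3 = 1, V4 = 0, V4V5 = 0,
                                           V5V8 = 0, V6V9 = 0),
                            candidate = c(V1V3 = 1, V4 = 0, V4V5 = 0,
                                          V5V8 = 0, V6V9 = 0)),
                          seed = 22)
  sim2 <- simulate_profiles(simulate_pool(spec2), spec2)
  expect_equal(unname(sim2$truth$unique_counts["V1V3"]), 10L)
})

test_that("coverage statistics recover the generator's planted ground truth", {
  spec <- generator_spec(seed = 33)
  pool <- simulate_pool(spec)
  sim <- simulate_profiles(pool, spec)
  truth <- sim$truth

  # set accounting on the pool taxa (excluding the Unassigned bucket, which
  # the generator plants in every primer set)
  sets <- lapply(sim$profiles, function(p)
    setdiff(names(p$counts), "Unassigned"))
  expect_equal(unique_taxa(sets), truth$unique_counts)
  expect_equal(length(unique(unlist(sets))), truth$union_size)
  expect_equal(shared_fraction(sets)$n_shared, truth$shared_all)

  cs <- tally_by_status(sim$profiles)
  detected <- rowSums(truth$detection) > 0
  expect_equal(unname(cs$combined["n_affiliated"]),
               sum(truth$status[detected] == "affiliated"))
  expect_equal(unname(cs$combined["n_candidate"]),
               sum(truth$status[detected] == "candidate"))
  expect_equal(unname(cs$combined["n_unassigned"]), 1)

  # read budgets and the unassigned mass are honoured to rounding
  for (p in names(sim$profiles)) {
    total <- sum(sim$profiles[[p]]$counts)
    expect_equal(total, spec$read_budget[[p]], tolerance = 0.02)
    expect_equal(sim$profiles[[p]]$counts[["Unassigned"]] / total,
                 spec$unassigned_mass, tolerance = 0.02)
  }

  # full determinism under a fixed seed
  sim_again <- simulate_profiles(pool, spec)
  expect_identical(sim$profiles, sim_again$profiles)
})

test_that("merge of simulated profiles equals the explicit enumeration oracle", {
  spec <- generator_spec(seed = 44)
  sim <- simulate_profiles(simulate_pool(spec), spec)
  m <- merge_profiles(sim$profiles)
  expected <- oracle_merge(lapply(sim$profiles, `[[`, "counts"))
  expect_equal(m$representative[names(expected)], expected)
})

test_that("marginal-constrained fixtures satisfy their constraints exactly", {
  fx <- fixture_from_marginals(c(2, 2), 1, 3)
  expect_equal(lengths(fx), c(set1 = 2L, set2 = 2L))
  expect_equal(length(Reduce(intersect, fx)), 1L)
  expect_equal(length(unique(unlist(fx))), 3L)

  cases <- list(
    list(sizes = c(19, 20, 21, 28, 18), shared = 11, union = 33),
    list(sizes = c(33, 51, 40, 35), shared = 27, union = 57),
    list(sizes = c(89, 137, 97, 88), shared = 65, union = 168)
  )
  for (cs in cases) {
    fx <- fixture_from_marginals(cs$sizes, cs$shared, cs$union)
    expect_equal(unname(lengths(fx)), cs$sizes)
    expect_equal(length(Reduce(intersect, fx)), cs$shared)
    expect_equal(length(unique(unlist(fx))), cs$union)
    expect_false(any(vapply(fx, anyDuplicated, integer(1L)) > 0))
  }

  expect_error(fixture_from_marginals(c(3, 3), 4, 5), "smallest set")
  expect_error(fixture_from_marginals(c(3, 3), 1, 2), "largest set")
  expect_error(fixture_from_marginals(c(3, 3), 0, 7), "sum of set sizes")
  # k = 2 with incompatible inclusion-exclusion
  expect_error(fixture_from_marginals(c(3, 3), 2, 3), "all-shared")
})

test_that("mock simulation is exact at zero noise and degrades with noise", {
  mc <- zymo_mock_composition()
  exact <- simulate_mock(mc, noise = 0, seed = 1)
  expect_equal(exact$relative, mc$fractions)
  expect_identical(simulate_mock(mc, noise = 0.3, seed = 5)$relative,
                   simulate_mock(mc, noise = 0.3, seed = 5)$relative)

  # concordance checks need expected variance, which the even mock lacks;
  # use an uneven composition for the r = 1 and noise-degradation checks
  uneven <- mock_composition(stats::setNames(
    c(0.30, 0.20, 0.15, 0.12, 0.10, 0.06, 0.04, 0.03),
    names(mc$fractions)))
  expect_equal(pearson_concordance(uneven, simulate_mock(uneven, 0, seed = 1)),
               1.0)
  mean_r <- vapply(c(0.05, 0.3, 1.0), function(ns) {
    mean(vapply(1:60, function(i)
      pearson_concordance(uneven, simulate_mock(uneven, ns, seed = i)),
      numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_r) < 0))
})
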