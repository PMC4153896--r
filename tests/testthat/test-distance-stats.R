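test_that("minimal-distance profile matches brute force, halves included", {
  expect_equal(min_distance_profile(1, 10)$distance,
               c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1))
  expect_equal(min_distance_profile(2.5, 6)$distance[2], 0.5)
  for (seed in 1:10) {
    withr::with_seed(seed, {
      m <- sample(101, sample(1:8, 1)) + sample(c(0, 0.5), 1)
    })
    expect_equal(min_distance_profile(m, 101)$distance, oracle_profile(m, 101))
  }
  expect_error(min_distance_profile(numeric(0), 10), "empty")
})

test_that("mean minimal distance is asymmetric and equals brute force", {
  expect_equal(mean_min_distance(c(1, 5), c(1, 5), 20), 0)
  expect_equal(mean_min_distance(c(1, 11), 1, 20), 5)
  expect_equal(mean_min_distance(1, c(1, 11), 20), 0)
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(200, 12); b <- sample(200, 5)
    })
    expect_equal(mean_min_distance(a, b, 200), oracle_mean_min(a, b, 200))
    expect_equal(mean_min_distance(b, a, 200), oracle_mean_min(b, a, 200))
  }
})

test_that("MDA reproduces the exhaustive rotation null exactly", {
  # coincident singletons: no nonzero rotation can do as well
  r0 <- mda(5, 5, 50)
  expect_equal(r0$actual_mean, 0)
  expect_equal(r0$p_value, 0)
  expect_length(r0$control_means, 49)

  r <- mda(c(4, 15), c(3, 11), 20)
  o <- oracle_mda_p(c(4, 15), c(3, 11), 20)
  expect_equal(r$actual_mean, o$actual)
  expect_equal(r$control_means, o$controls)
  expect_equal(r$p_value, o$p)

  for (seed in 1:8) {
    withr::with_seed(seed, {
      L <- sample(40:120, 1)
      from <- sample(L, sample(2:6, 1))
      to <- sample(L, sample(2:6, 1)) + sample(c(0, 0.5), 1)
    })
    got <- mda(from, to, L)
    o <- oracle_mda_p(from, to, L)
    expect_equal(got$control_means, o$controls, info = seed)
    expect_equal(got$p_value, o$p, info = seed)
  }
})

test_that("MDA p-values are invariant under joint rotation of both sets", {
  withr::with_seed(44, {
    from <- sample(200, 10)
    to <- sample(200, 4)
  })
  p0 <- mda(from, to, 200)$p_value
  for (r in c(7, 100, 199)) {
    expect_equal(
      mda(rotate_positions(from, r, 200), rotate_positions(to, r, 200), 200)$p_value,
      p0)
  }
})

test_that("chance proximity probability equals the rotational identity", {
  expect_equal(chance_proximity_probability(50, 2, 100), 0.05)
  expect_equal(chance_proximity_probability(c(10, 60), 60, 100), 1)
  for (seed in 1:8) {
    withr::with_seed(seed, {
      m <- sample(97, sample(1:6, 1)) + sample(c(0, 0.5), 1)
      D <- sample(0:15, 1)
    })
    expect_equal(chance_proximity_probability(m, D, 97), oracle_chance_P(m, D, 97))
    # identity behind the binomial null: P equals the mean over rotations of
    # the indicator that one rotated breakpoint lands within D
    ind <- vapply(0:96, function(r) {
      oracle_nn_dist(((50 - 1 + r) %% 97) + 1, m, 97) <= D
    }, logical(1))
    expect_equal(chance_proximity_probability(m, D, 97), mean(ind))
  }
})

test_that("binomial conventions agree with direct summation and expose K = N", {
  expect_equal(enrichment_pvalue(5, 5, 1, "paper_literal"), 0)
  expect_equal(enrichment_pvalue(5, 5, 1, "at_least_K"), 1)
  expect_equal(enrichment_pvalue(0, 10, 0.3, "at_least_K"), 1)
  withr::with_seed(3, {
    for (i in 1:200) {
      N <- sample(1:40, 1); K <- sample(0:N, 1); P <- runif(1)
      expect_equal(enrichment_pvalue(K, N, P, "at_least_K"),
                   oracle_binom_tail(K, N, P), tolerance = 1e-12)
      expect_equal(enrichment_pvalue(K, N, P, "paper_literal"),
                   oracle_binom_tail(K + 1, N, P), tolerance = 1e-12)
    }
  })
})

test_that("enrichment curves match brute force at every distance", {
  # all from-points on motifs: K = N at D = 0
  cv0 <- enrichment_curve(c(5, 9), c(5, 9), 60, d_max = 5)
  expect_equal(cv0$K[1], 2L)

  withr::with_seed(12, {
    from <- sample(100, 15); to <- sample(100, 4)
  })
  cv <- enrichment_curve(from, to, 100, d_max = 50)
  prof <- oracle_profile(to, 100)
  dact <- oracle_nn_dist(from, to, 100)
  for (D in c(0, 3, 10, 25, 50)) {
    row <- cv[cv$D == D, ]
    expect_equal(row$K, sum(dact <= D))
    expect_equal(row$P, mean(prof <= D))
    expect_equal(row$expected, 15 * mean(prof <= D))
    expect_equal(row$p_value, oracle_binom_tail(row$K, 15, row$P), tolerance = 1e-12)
  }
  # invariants: K and P non-decreasing, and saturated at L/2
  expect_true(all(diff(cv$K) >= 0))
  expect_true(all(diff(cv$P) >= 0))
  expect_equal(cv$K[cv$D == 50], 15L)
  expect_equal(cv$P[cv$D == 50], 1)
  # overall means agree with the rotation identity
  expect_equal(attr(cv, "overall_actual_mean"), mean(dact))
  o <- oracle_mda_p(from, to, 100)
  expect_equal(attr(cv, "overall_control_mean"), mean(o$controls))
})

test_that("both-ends counts and chance probability match the rotation oracle", {
  dels <- tibble::tibble(id = paste0("d", 1:4),
                         bp5 = c(5L, 12L, 30L, 44L), bp3 = c(20L, 25L, 50L, 55L))
  mids <- c(5.5, 21, 47)
  got <- both_ends_enrichment(dels, mids, 60, D = 4)
  o <- oracle_both_ends(dels, mids, 60, 4)
  expect_equal(got$n_close, o$n_close)
  expect_equal(got$P, o$P)
  expect_equal(got$control_counts, o$counts[-1])
  expect_equal(got$p_value, oracle_binom_tail(got$n_close, 4, got$P), tolerance = 1e-12)

  # motifs at every breakpoint: everything qualifies
  all_mids <- c(dels$bp5, dels$bp3)
  expect_equal(both_ends_enrichment(dels, all_mids, 60, D = 0)$n_close, 4)
})

test_that("paired-repeat test matches its oracle and is stricter than pooled", {
  dels <- tibble::tibble(id = paste0("d", 1:3),
                         bp5 = c(10L, 10L, 40L), bp3 = c(30L, 52L, 52L))
  pairs <- tibble::tibble(mid5 = c(10, 40), mid3 = c(30, 52))
  got <- paired_repeat_both_ends(dels, pairs, 60, D = 0)
  o <- oracle_paired_both_ends(dels, pairs, 60, 0)
  expect_equal(got$n_close, o$n_close)
  expect_equal(got$P, o$P)
  # d2 matches unit5 of pair 1 and unit3 of pair 2 only: excluded in paired
  # mode, included when all unit midpoints are pooled
  expect_equal(got$n_close, 2)
  pooled <- both_ends_enrichment(dels, c(pairs$mid5, pairs$mid3), 60, D = 0)
  expect_equal(pooled$n_close, 3)

  withr::with_seed(71, {
    dels2 <- simulate_deletions(5, 80, "uniform")
    pairs2 <- tibble::tibble(mid5 = sample(80, 3) + 0.5, mid3 = sample(80, 3))
  })
  got2 <- paired_repeat_both_ends(dels2, pairs2, 80, D = 6)
  o2 <- oracle_paired_both_ends(dels2, pairs2, 80, 6)
  expect_equal(got2$n_close, o2$n_close)
  expect_equal(got2$control_counts, o2$counts[-1])
})

test_that("tidy, glance and autoplot work on every result type", {
  r <- mda(c(4, 15), c(3, 11), 20)
  expect_equal(tidy(r)$n_rotations, 19)
  expect_s3_class(autoplot(r), "ggplot")
  cv <- enrichment_curve(c(4, 15), c(3, 11), 20, d_max = 10)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$N, 2)
  expect_s3_class(autoplot(cv), "ggplot")
  be <- both_ends_enrichment(tibble::tibble(id = "d", bp5 = 4L, bp3 = 15L),
                             c(3, 11), 20, D = 2)
  expect_equal(tidy(be)$mode, "single_motif_set")
})
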