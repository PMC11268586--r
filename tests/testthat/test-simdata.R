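test_that("random collections honor the requested shapes and seeds", {
  c1 <- random_collection(10, c(10, 10), seed = 5)
  expect_length(c1, 10)
  expect_true(all(c1$sites$length == 10L))
  c2 <- random_collection(10, c(10, 10), seed = 5)
  expect_identical(c1$sites, c2$sites)
  c3 <- random_collection(10, c(10, 10), seed = 6)
  expect_false(identical(c1$sites$seq, c3$sites$seq))
  lad <- random_collection(10, c(5, 14), seed = 5, ladder = TRUE)
  expect_identical(sort(lad$sites$length), 5:14)
  expect_error(random_collection(9, c(5, 14), ladder = TRUE, seed = 1),
               "one site per length")
  mixed <- random_collection(40, c(5, 15), seed = 7)
  expect_true(all(mixed$sites$length >= 5 & mixed$sites$length <= 15))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(random_collection(5, c(4, 6), seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("the frequency study tallies sites and builds the uniform control", {
  coll <- random_collection(5, c(4, 6), seed = 81)
  st <- frequency_study(coll, L = 16, strands = "single", max_solutions = 8,
                        seed = 81)
  expect_identical(nrow(st$frequencies), 5L)
  expect_true(all(st$frequencies$frequency >= 0 &
                  st$frequencies$frequency <= 1))
  expect_true(all(st$frequencies$control_frequency >= 0 &
                  st$frequencies$control_frequency <= 1))
  expect_false(any(is.na(st$frequencies$mean_d_from)))
  expect_identical(length(st$entropy_trace), st$n_solutions)
  # a site shared by every optimum has frequency one: AAAA is in both
  # two-site optima of this hand-built collection
  shared <- site_collection(c("AAAA", "AAAC", "AAAG", "TTTT"))
  st2 <- frequency_study(shared, L = 5, strands = "single",
                         max_solutions = 10, seed = 1)
  f <- st2$frequencies
  expect_identical(st2$S_star, 2L)
  expect_identical(f$frequency[f$site_id == "site1"], 1)
})

test_that("upstream-biased sites land before downstream-biased sites", {
  st <- side_bias_study(n_collections = 3, seed = 2, n_sites = 6,
                        length_range = c(4, 7), L = 24)
  expect_gt(nrow(st$details), 0)
  expect_lt(st$mean_offset_upstream, st$mean_offset_downstream)
})

test_that("the promoter screen classifies the easy extremes", {
  # unconstrained single elements are always placeable
  easy <- list(fixed_element("TTGACA", c(0, 44)))
  st <- promoter_feasibility_study(n_collections = 3, seed = 11, L = 50,
                                   n_sites = 6, length_range = c(4, 8),
                                   elements = easy, time_limit = 30)
  expect_identical(st$fraction_infeasible, 0)
  # a window beyond the budget is always infeasible
  bad <- list(fixed_element("TTGACA", c(48, 48)))
  st2 <- promoter_feasibility_study(n_collections = 3, seed = 11, L = 50,
                                    n_sites = 6, length_range = c(4, 8),
                                    elements = bad, time_limit = 30)
  expect_identical(st2$fraction_infeasible, 1)
})

test_that("the greedy degradation harness reports ratios in [0, 1]", {
  df <- greedy_vs_optimal_study(sizes = c(3, 5), L = 18,
                                length_range = c(4, 6), n_reps = 2, seed = 3)
  expect_identical(nrow(df), 4L)
  expect_true(all(df$greedy <= df$optimal))
  expect_true(all(df$ratio >= 0 & df$ratio <= 1))
})
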