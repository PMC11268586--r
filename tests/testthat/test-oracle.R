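test_that("the path oracle solves the toy instances", {
  res <- brute_force_pack(toy_collection(), 5, "single")
  expect_identical(res$score, 3L)
  expect_true(all(c("AGCAG", "GCAGC", "CAGCA") %in% res$sequences))
  expect_identical(brute_force_pack(site_collection("AGC"), 2, "single")$score, 0L)
  # a site and its own reverse complement never both count
  dres <- brute_force_pack(site_collection("AGC"), 3, "double")
  expect_identical(dres$score, 1L)
  expect_setequal(dres$sequences, c("AGC", "GCT"))
  expect_error(brute_force_pack(random_collection(12, c(3, 4), seed = 1), 10,
                                "single"), "too large")
})

test_that("the sequence oracle agrees with the path oracle except for containment", {
  coll <- toy_collection()
  expect_identical(exhaustive_sequence_search(coll, 5, "single"), 3L)
  expect_identical(exhaustive_sequence_search(coll, 0, "single"), 0L)
  # AGCAG contains GC internally: the sequence oracle sees 2 sites where the
  # path oracle scores 1
  gap <- site_collection(c("AGCAG", "GC"))
  expect_identical(exhaustive_sequence_search(gap, 5, "single"), 2L)
  expect_identical(brute_force_pack(gap, 5, "single")$score, 1L)
  expect_error(exhaustive_sequence_search(coll, 30, "single"), "size limit")
})

test_that("path and sequence oracles are consistent on random tiny instances", {
  set.seed(71)
  for (s in 1:5) {
    coll <- random_collection(3, c(2, 4), seed = 500 + s)
    for (strands in c("single", "double")) {
      L <- 6
      po <- brute_force_pack(coll, L, strands)$score
      so <- exhaustive_sequence_search(coll, L, strands)
      expect_lte(po, so)
    }
  }
})

test_that("the path-count recurrence matches direct enumeration and the printed magnitude", {
  expect_identical(count_simple_paths(0), "1")
  expect_identical(count_simple_paths(1), "2")
  expect_identical(count_simple_paths(2), "5")   # {}, (1), (2), (1,2), (2,1)
  expect_identical(count_simple_paths(3), "16")
  # sum_k n!/(n-k)! computed directly for small n
  direct <- function(n) sum(factorial(n) / factorial(n - (0:n)))
  for (n in 4:10) {
    expect_identical(count_simple_paths(n), sprintf("%.0f", direct(n)))
  }
  expect_identical(round(decimal_log10(count_simple_paths(50))), 65)
  expect_identical(round(decimal_log10(exact_power(4, 200))), 120)
})

test_that("count_simple_paths(n)/n! converges to e", {
  ratio <- as.numeric(count_simple_paths(20)) / factorial(20)
  expect_lt(abs(ratio - exp(1)), 1e-10)
})

test_that("exact powers match machine arithmetic in range", {
  expect_identical(exact_power(2, 10), "1024")
  expect_identical(exact_power(10, 6), "1000000")
  expect_identical(exact_power(7, 0), "1")
})
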