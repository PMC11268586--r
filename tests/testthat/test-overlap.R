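test_that("shift distance reproduces the worked examples", {
  expect_identical(shift_distance("AGC", "CAG"), 2L)
  expect_identical(shift_distance("CAG", "AGC"), 1L)
  expect_identical(shift_distance("CGT", "CAG"), 3L)   # empty-overlap fallback
  expect_identical(shift_distance("AGCAG", "GC"), 4L)  # end-overhang, not 1
  expect_identical(shift_distance("AGC", "AGC"), 0L)
  expect_identical(shift_distance("AGC", "GC"), 1L)    # proper suffix
})

test_that("shift distance rejects empty or non-scalar input", {
  expect_error(shift_distance("", "AGC"), "empty")
  expect_error(shift_distance("AGC", ""), "empty")
  expect_error(shift_distance(c("A", "C"), "G"), "single")
})

test_that("shift distance matches the brute-force placement check on random pairs", {
  set.seed(101)
  for (i in 1:300) {
    a <- random_string(sample(1:9, 1))
    b <- random_string(sample(1:9, 1))
    d <- shift_distance(a, b)
    expect_identical(d, shift_by_enumeration(a, b))
    expect_lte(d, nchar(a))  # the empty-overlap fallback always qualifies
    expect_gte(d, 0L)
  }
})

test_that("shift distance is zero exactly when a is a prefix of b", {
  set.seed(102)
  for (i in 1:200) {
    a <- random_string(sample(1:6, 1))
    b <- random_string(sample(1:6, 1))
    expect_identical(shift_distance(a, b) == 0L, startsWith(b, a))
  }
})

test_that("the metric satisfies the triangle inequality", {
  set.seed(103)
  pool <- vapply(1:40, function(i) random_string(sample(2:10, 1)), character(1))
  m <- length(pool)
  d <- matrix(0L, m, m)
  for (i in 1:m) for (j in 1:m) if (i != j) d[i, j] <- shift_distance(pool[i], pool[j])
  trip <- cbind(sample(m, 12000, TRUE), sample(m, 12000, TRUE), sample(m, 12000, TRUE))
  trip <- trip[trip[, 1] != trip[, 2] & trip[, 2] != trip[, 3] & trip[, 1] != trip[, 3], ]
  ac <- d[trip[, c(1, 3)]]
  ab <- d[trip[, c(1, 2)]]
  bc <- d[trip[, c(2, 3)]]
  expect_true(all(ac <= ab + bc))
})

test_that("reverse complement is an involution and matches the DNA table", {
  expect_identical(reverse_complement("AGC"), "GCT")
  expect_identical(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_identical(reverse_complement("A"), "T")
  set.seed(104)
  for (i in 1:50) {
    s <- random_string(sample(1:12, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ANC"), "complement")
})

test_that("site collections validate their invariants", {
  expect_error(site_collection(character(0)), "at least one")
  expect_error(site_collection(c("AGC", "")), "non-empty")
  expect_error(site_collection(c("AGC", "AXC")), "outside the alphabet")
  expect_error(site_collection(c("A", "C"), ids = c("s", "s")), "unique")
  expect_error(site_collection("AGC", complement = c(A = "C", C = "A", G = "T", T = "A")),
               "involution")
  coll <- site_collection(c("agc", "cag"))
  expect_identical(coll$sites$seq, c("AGC", "CAG"))  # upper-cased
})

test_that("the overlap graph has the documented shape and distances", {
  coll <- toy_collection()
  g1 <- build_graph(coll, "single")
  expect_identical(nrow(g1$vertices), 3L)
  expect_identical(unname(g1$d["site1", "site3"]), 1L)  # AGC -> GCA
  expect_identical(unname(g1$d["site3", "site2"]), 1L)  # GCA -> CAG
  expect_identical(unname(g1$d["site1", "site2"]), 2L)  # AGC -> CAG
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      expect_identical(g1$d[i, j],
                       shift_by_enumeration(g1$vertices$seq[i], g1$vertices$seq[j]))
    }
  }
  g2 <- build_graph(coll, "double")
  expect_identical(nrow(g2$vertices), 6L)  # forward + reverse per site
  rev <- g2$vertices[g2$vertices$orientation == "rev", ]
  expect_setequal(rev$seq, reverse_complement(coll$sites$seq))
  nocomp <- site_collection(c("AB", "BA"), alphabet = c("A", "B"))
  expect_error(build_graph(nocomp, "double"), "complement")
  expect_identical(nrow(build_graph(nocomp, "single")$vertices), 2L)
})

test_that("duplicate sequences stay distinct vertices with zero distance", {
  coll <- site_collection(c("AGCA", "AGCA"))
  g <- build_graph(coll, "single")
  expect_identical(nrow(g$vertices), 2L)
  expect_identical(unname(g$d[1, 2]), 0L)
})
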