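test_that("a three-site collection packs perfectly into five bases", {
  m <- build_model(build_graph(toy_collection(), "single"), 5)
  res <- solve_once(m)
  expect_identical(res$report$status, "optimal")
  expect_identical(res$report$base_score, 3L)
})

test_that("unknown backends raise a configuration error naming the options", {
  m <- build_model(build_graph(toy_collection(), "single"), 5)
  expect_error(solve_once(m, backend = "gurobi"), "unknown backend")
})

test_that("enumeration returns exactly the oracle's optimal sequences", {
  oracle <- brute_force_pack(toy_collection(), 5, "single")
  m <- build_model(build_graph(toy_collection(), "single"), 5)
  en <- enumerate_optimal(m, "solver", limit = Inf)
  expect_identical(en$S_star, oracle$score)
  expect_identical(en$termination, "exhausted")
  expect_setequal(vapply(en$packings, function(p) p$sequence, ""),
                  oracle$sequences)
})

test_that("a limit of one returns the single solve_once packing", {
  m <- build_model(build_graph(toy_collection(), "single"), 5)
  en <- enumerate_optimal(m, "solver", limit = 1)
  expect_identical(length(en$packings), 1L)
  expect_identical(en$termination, "limit")
  expect_identical(en$packings[[1]]$base_score, solve_once(m)$report$base_score)
})

test_that("every enumerated packing re-verifies against the shift metric", {
  set.seed(31)
  for (s in 1:4) {
    coll <- random_collection(4, c(3, 6), seed = s)
    for (strands in c("single", "double")) {
      g <- build_graph(coll, strands)
      en <- enumerate_optimal(build_model(g, 14), "solver", limit = Inf)
      for (pk in en$packings) {
        expect_lte(pk$used_length, 14)
        pl <- pk$placements
        if (nrow(pl) > 1) {
          # offsets are exactly the cumulative shift distances
          vidx <- vapply(seq_len(nrow(pl)), function(t) {
            which(g$vertices$site_id == pl$site_id[t] &
                  g$vertices$orientation == pl$orientation[t])
          }, 0L)
          for (t in 2:nrow(pl)) {
            expect_identical(pl$offset[t] - pl$offset[t - 1],
                             g$d[vidx[t - 1], vidx[t]])
          }
        }
        occ <- verify_occurrences(pk$sequence, coll, strands)
        expect_gte(sum(occ), pk$base_score)
      }
    }
  }
})

test_that("optimal base scores equal the brute-force oracle on random instances", {
  # the acceptance suite runs the full 50-instance sweep; this is the
  # per-module smoke version
  set.seed(32)
  for (s in 1:6) {
    n <- sample(3:5, 1)
    strands <- sample(c("single", "double"), 1)
    if (strands == "double") n <- min(n, 4L)
    L <- sample(10:22, 1)
    coll <- random_collection(n, c(3, 6), seed = 100 + s)
    oracle <- brute_force_pack(coll, L, strands)
    m <- build_model(build_graph(coll, strands), L)
    res <- solve_once(m)
    expect_identical(res$report$base_score, oracle$score)
  }
})

test_that("base score is monotone in the budget and in constraints", {
  coll <- random_collection(5, c(4, 7), seed = 41)
  scores <- vapply(c(8, 14, 20, 30), function(L) {
    solve_once(build_model(build_graph(coll, "double"), L))$report$base_score
  }, 0L)
  expect_true(all(diff(scores) >= 0))
  # adding a fixed element cannot raise the number of free sites packed
  free <- pack_sites(coll, 25, strands = "double")$S_star
  con <- pack_sites(coll, 25, strands = "double",
                    elements = list(fixed_element("TTGACA", c(0, 10))))
  if (con$termination != "infeasible") {
    pl <- con$packings[[1]]$placements
    expect_lte(sum(!grepl("^element", pl$site_id)), free)
  }
})

test_that("a budget covering the concatenation packs every site", {
  for (s in 1:3) {
    coll <- random_collection(4, c(3, 6), seed = 600 + s)
    L <- sum(coll$sites$length)
    res <- solve_once(build_model(build_graph(coll, "single"), L))
    expect_identical(res$report$base_score, 4L)
  }
})

test_that("usage entropy matches the closed-form cases", {
  expect_equal(usage_entropy(rep(3, 10)), log(10))
  expect_equal(usage_entropy(c(7, 0, 0)), 0)
  expect_equal(usage_entropy(c(1, 1)), log(2))
  expect_error(usage_entropy(c(0, 0)), "all-zero")
  expect_error(usage_entropy(c(-1, 2)), "non-negative")
  # cross-check against the community ecology implementation
  set.seed(5)
  x <- rpois(12, 4) + 1
  expect_equal(usage_entropy(x), unname(vegan::diversity(x, index = "shannon")))
})

test_that("diversity order balances usage on a partitioned instance", {
  # two disjoint optimal pairs: {AAAA+AAAC} and {GGGG+GGGT} both fit L = 5;
  # after the first solution uses one pair, reweighting must steer the next
  # solution to the other pair before any repeat
  coll <- site_collection(c("AAAA", "AAAC", "GGGG", "GGGT"))
  m <- build_model(build_graph(coll, "single"), 5)
  en <- enumerate_optimal(m, "diversity", limit = 2)
  expect_identical(en$S_star, 2L)
  used1 <- unique(en$packings[[1]]$placements$site_id)
  used2 <- unique(en$packings[[2]]$placements$site_id)
  expect_length(intersect(used1, used2), 0)
  expect_true(all(en$counts[c("site1", "site2", "site3", "site4")] == 1))
})

test_that("solver reports carry the seed and solver identity", {
  m <- build_model(build_graph(toy_collection(), "single"), 5)
  en <- enumerate_optimal(m, "solver", limit = 1, seed = 99L)
  expect_identical(en$reports[[1]]$solver, "glpk")
  expect_identical(en$reports[[1]]$seed, 99L)
})
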