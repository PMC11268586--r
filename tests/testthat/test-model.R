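test_that("variable and MTZ constraint counts match the closed formulas", {
  set.seed(11)
  for (n in c(1:6, 10, 15, 20)) {
    coll <- random_collection(n, c(3, 6), seed = n)
    m <- build_model(build_graph(coll, "single"), 12)
    expect_equal(m$n_edge_vars, n^2 + n + 1L)
    expect_equal(sum(m$var$type == "B"), n^2 + n + 1L)
    expect_equal(m$n_mtz, n * (n - 1L))
    expect_equal(sum(grepl("^mtz_", vapply(m$con, `[[`, "", "name"))),
                     n * (n - 1L))
  }
})

test_that("a budget below every site is feasible with the start-end edge", {
  fit <- pack_sites(site_collection("AGC"), L = 2, strands = "single")
  expect_identical(fit$S_star, 0L)
  expect_identical(fit$packings[[1]]$sequence, "")
  expect_identical(fit$packings[[1]]$base_score, 0L)
})

test_that("position variables follow the cumulative shifts along the path", {
  coll <- site_collection(c("AGC", "CAG"))
  g <- build_graph(coll, "single")
  m <- attach_positions(build_model(g, 5))
  res <- solve_once(m)
  expect_identical(res$report$base_score, 2L)
  path <- densepack:::extract_path(m, res$assignment)
  pk <- reconstruct(path, g, 5)
  expect_identical(pk$sequence, "AGCAG")
  expect_identical(pk$used_length, 5L)
  # solver positions of path vertices agree with the reconstruction offsets
  pos <- res$assignment[m$var$name[m$pidx[path]]]
  expect_identical(unname(pos), as.numeric(pk$placements$offset))
  expect_identical(unname(res$assignment[m$var$name[m$pidx[path[1]]]]), 0)
})

test_that("a pinned fixed element forces the array to begin with it", {
  fit <- pack_sites(c("AGCAG", "TTGACAGT", "CATTG"), L = 20, strands = "single",
                    elements = list(fixed_element("TTGACA", c(0, 0))))
  expect_gt(length(fit$packings), 0)
  expect_true(startsWith(fit$packings[[1]]$sequence, "TTGACA"))
  el <- fit$packings[[1]]$placements
  expect_identical(el$offset[el$site_id == "element1"], 0L)
})

test_that("a paired element honors the exact spacer window", {
  fit <- pack_sites(c("AGCAGTAGC", "CATGA", "GGATCC"), L = 40, strands = "single",
                    elements = list(fixed_element("TTGACA", c(0, 0),
                                                  pair = list(seq = "TATAAT",
                                                              spacer = c(17, 17)))))
  pl <- fit$packings[[1]]$placements
  up <- pl$offset[pl$site_id == "element1"]
  dn <- pl$offset[pl$site_id == "element1_pair"]
  expect_identical(dn - up, 6L + 17L)  # upstream length 6 plus the spacer
})

test_that("printed and gap spacer conventions differ by the length asymmetry", {
  # upstream 7 bp, downstream 5 bp: the gap convention measures the spacer
  # from the end of the upstream element, the printed formula uses the
  # downstream element's length instead
  build <- function(conv) {
    densepack:::build_packing_model(
      site_collection("GGTACAT"), 30, strands = "single",
      elements = list(fixed_element("TGGCAGG", c(0, 0),
                                    pair = list(seq = "TTGCA", spacer = c(4, 4)))),
      spacer_convention = conv)$model
  }
  rhs_of <- function(m, nm) {
    names <- vapply(m$con, `[[`, "", "name")
    m$con[[which(names == nm)]]$rhs
  }
  expect_equal(rhs_of(build("gap"), "spacer_lo_element1"), 4 + 7)
  expect_equal(rhs_of(build("printed"), "spacer_lo_element1"), 4 + 5)
  # equal-length elements: the two conventions coincide
  build6 <- function(conv) {
    densepack:::build_packing_model(
      site_collection("GGTACAT"), 40, strands = "single",
      elements = list(fixed_element("TTGACA", c(0, 0),
                                    pair = list(seq = "TATAAT", spacer = c(17, 17)))),
      spacer_convention = conv)$model
  }
  expect_equal(rhs_of(build6("gap"), "spacer_lo_element1"),
                   rhs_of(build6("printed"), "spacer_lo_element1"))
  # and the gap convention solves to the documented geometry: the bridge
  # site GGTACAT chains TGGCAGG(0) -> GGTACAT(5) -> TTGCA(11)
  fit <- pack_sites(site_collection("GGTACAT"), L = 30, strands = "single",
                    elements = list(fixed_element("TGGCAGG", c(0, 0),
                                                  pair = list(seq = "TTGCA",
                                                              spacer = c(4, 4)))))
  pl <- fit$packings[[1]]$placements
  expect_identical(pl$offset[pl$site_id == "element1_pair"], 11L)
})

test_that("an element window overrunning the budget is infeasible", {
  fit <- pack_sites(c("AGC"), L = 10, strands = "single",
                    elements = list(fixed_element("TTGACAT", c(4, 4))))
  expect_identical(fit$termination, "infeasible")
  expect_identical(length(fit$packings), 0L)
})

test_that("diversity weights follow the strictly-below-mean rule", {
  coll <- site_collection(c("AGCT", "TTAA"))
  m <- build_model(build_graph(coll, "single"), 10)
  eps <- m$epsilon
  m2 <- set_diversity_weights(m, c(site1 = 2, site2 = 0))
  expect_identical(m2$cvert, c(1, 1 + eps))
  rows_s2 <- stats::na.omit(m2$xidx[, 3])
  expect_true(all(m2$var$obj[rows_s2] == 1 + eps))
  rows_s1 <- stats::na.omit(m2$xidx[, 2])
  expect_true(all(m2$var$obj[rows_s1] == 1))
  # equal counts: no site strictly below the mean
  m3 <- set_diversity_weights(m, c(site1 = 3, site2 = 3))
  expect_identical(m3$cvert, c(1, 1))
  expect_error(set_diversity_weights(m, c(site1 = 1), epsilon = 0.6), "1/n")
  expect_error(set_diversity_weights(m, c(site1 = 1)), "cover")
})

test_that("the side-bias perturbation bound holds for the default K", {
  n <- 10; L <- 50
  K <- 2 * n * (L - 1)
  expect_lte(n * (L - 1) / K, 0.5)  # m <= n biased sites, offsets <= L-1
  coll <- random_collection(4, c(3, 5), seed = 7)
  m <- attach_positions(build_model(build_graph(coll, "single"), 20))
  m <- add_side_bias(m, c(site1 = "upstream", site2 = "downstream"))
  expect_identical(m$K, 2 * 4 * 19)
  expect_lt(sum(abs(m$var$obj[m$pidx])) * (m$L - 1), 0.5 + 1e-12)
  expect_error(add_side_bias(m, c(nosite = "upstream")), "unknown site")
})

test_that("objective values stay within the base-score recovery band", {
  coll <- random_collection(5, c(3, 6), seed = 21)
  built <- densepack:::build_packing_model(
    coll, 18, strands = "single",
    bias = c(site1 = "upstream", site2 = "downstream"), diversity = TRUE)
  m <- set_diversity_weights(built$model,
                             c(site1 = 1, site2 = 0, site3 = 0, site4 = 2,
                               site5 = 0))
  res <- solve_once(m)
  expect_identical(res$report$status, "optimal")
  k <- res$report$base_score
  expect_identical(recover_base_score(res$report$objective), k)
  expect_gte(res$report$objective, k - 0.5)
  expect_lte(res$report$objective, k + 0.5)
})
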