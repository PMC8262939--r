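test_that("rm_set has set semantics and well-defined algebra", {
  expect_equal(rm_size(rm_set()), 0)
  expect_equal(rm_size(rm_set("a", "a", "b")), 2)
  expect_equal(unclass(rm_diff(rm_set("a", "b"), rm_set("a"))), "b")
  expect_equal(rm_size(rm_intersect(rm_set("a", "b"), rm_set("b", "c"))), 1)
  # equality by label, not position
  expect_true(setequal(rm_set("x", "y"), rm_set("y", "x")))
  expect_error(rm_set(NA_character_), "NA")
})

test_that("RM costs are linear in set size and a cost of one is rejected", {
  expect_equal(total_cost(rm_set(), 0.05), 0)
  expect_equal(total_cost(rm_set("A"), 0.05), 0.05)
  expect_equal(total_cost(rm_set("A", "B"), 0.05), 0.10)
  expect_error(total_cost(rm_set(paste0("r", 1:20)), 0.05), "must be < 1")
  expect_error(total_cost(rm_set("A"), -0.01), ">= 0")
})

test_that("susceptibility is multiplicative across RM systems", {
  expect_equal(gamma_coefficient(rm_set(), 100), 1)
  expect_equal(gamma_coefficient(rm_set("A"), 100), 0.01)
  expect_equal(gamma_coefficient(rm_set("A", "B"), 100), 1e-4)
  # two systems at 100-fold each give a 10,000-fold infection reduction
  expect_equal(1 / gamma_coefficient(rm_set("A", "B"), 100), 1e4)
  expect_error(gamma_coefficient(rm_set("A"), 0.5), ">= 1")
})

test_that("methylation-aware susceptibility matrix follows the set algebra", {
  # unshared RM restricts fully; shared-and-methylated not at all
  G <- gamma_matrix(list(rm_set("A", "B")), list(rm_set("A")),
                    r_e = 100, m_v = 1)
  expect_equal(G[1, 1], 0.01)
  # half-methylated shared system: exponent 0.5
  G <- gamma_matrix(list(rm_set("A")), list(rm_set("A")), r_e = 100, m_v = 0.5)
  expect_equal(G[1, 1], 100^-0.5)
  expect_error(gamma_matrix(list(rm_set()), list(rm_set()), 100, 1.5), "m_v")
})

test_that("with m_v = 0 the matrix collapses to the plain coefficient for
           every phage set (exhaustive small-set enumeration)", {
  universe <- c("a", "b", "c")
  subsets <- lapply(0:7, function(k) {
    rm_set(universe[c(bitwAnd(k, 1) > 0, bitwAnd(k, 2) > 0,
                      bitwAnd(k, 4) > 0)])
  })
  for (r_e in c(2, 100)) {
    G <- gamma_matrix(subsets, subsets, r_e = r_e, m_v = 0)
    expected <- vapply(subsets, gamma_coefficient, numeric(1), r_e = r_e)
    for (j in seq_along(subsets)) expect_equal(G[, j], expected)
  }
})

test_that("matrix entries lie in (0,1], shrink with unshared RMs and grow
           with virion methylation", {
  universe <- c("a", "b", "c")
  subsets <- lapply(0:7, function(k) {
    rm_set(universe[c(bitwAnd(k, 1) > 0, bitwAnd(k, 2) > 0,
                      bitwAnd(k, 4) > 0)])
  })
  mvs <- c(0, 0.25, 0.5, 0.75, 1)
  Gs <- lapply(mvs, function(mv) gamma_matrix(subsets, subsets, 50, mv))
  for (G in Gs) {
    expect_true(all(G > 0 & G <= 1))
  }
  # non-decreasing in m_v entrywise
  for (k in seq_len(length(mvs) - 1)) {
    expect_true(all(Gs[[k + 1]] >= Gs[[k]] - 1e-15))
  }
  # non-increasing in |b - p|: compare nested hosts against a fixed phage
  for (mv in mvs) {
    G <- gamma_matrix(list(rm_set("a"), rm_set("a", "b"),
                           rm_set("a", "b", "c")),
                      list(rm_set("a")), 50, mv)
    expect_true(all(diff(G[, 1]) <= 1e-15))
  }
})

test_that("under the subset arrangement with full methylation every phage is
           immune to its own source host", {
  cm <- build_community(4, "subset", "memory")
  G <- gamma_matrix(lapply(cm$hosts, `[[`, "rm_set"),
                    lapply(cm$phages, `[[`, "methylation"),
                    r_e = 100, m_v = 1)
  expect_equal(diag(G), rep(1, 4))
  # and phages from better-defended hosts are immune to less-defended ones
  expect_true(all(G[upper.tri(G)] == 1))
})
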