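test_that("model construction validates structure", {
  h <- list(host_spec("C", rm_set("r1")), host_spec("D", rm_set("r1", "r2")))
  expect_error(rm_model("general", h, phages = list(phage_spec("P1"),
                                                    phage_spec("P2"))),
               "exactly one phage")
  expect_error(rm_model("memory", h,
                        phages = list(phage_spec("P1", rm_set("zz"), 1L),
                                      phage_spec("P2", rm_set("r1", "r2"), 2L))),
               "methylation")
  m <- rm_model("memory", h)
  expect_equal(length(m$phages), 2)
  expect_true(setequal(m$phages[[2]]$methylation, rm_set("r1", "r2")))
  expect_output(print(m), "memory")
})

test_that("an empty system only accumulates nutrients", {
  m <- default_pair("general", S = 123)
  d <- derivatives(m, community_state(0, c(0, 0), 0))
  expect_equal(d$dN, 123)
  expect_equal(d$dB, c(0, 0))
  expect_equal(d$dP, 0)
})

test_that("derivatives match a naive term-by-term oracle on random states", {
  set.seed(7)
  for (kind in c("general", "parallel", "memory")) {
    cm <- build_community(3, "subset", kind)
    params <- model_params(S = 3e6, m_v = 0.6)
    m <- rm_model(kind, cm$hosts, cm$phages, params)
    np <- if (kind == "general") 1 else 3
    for (r in 1:25) {
      N <- 10^runif(1, 0, 8)
      B <- 10^runif(3, 0, 9)
      P <- 10^runif(np, 0, 10)
      got <- derivatives(m, community_state(N, B, P))
      ref <- oracle_derivatives(kind, N, B, P, cm$hosts, cm$phages, params)
      expect_equal(got$dN, ref$dN, tolerance = 1e-12)
      expect_equal(got$dB, ref$dB, tolerance = 1e-12)
      expect_equal(got$dP, ref$dP, tolerance = 1e-12)
    }
  }
})

test_that("memory-model phage reproduction is credited to the source host's
           phage even though all phage infect all hosts", {
  cm <- build_community(2, "unique", "memory")
  m <- rm_model("memory", cm$hosts, cm$phages, model_params(m_v = 1))
  # host 2 present, phage 1 present, phage 2 absent: infections of host 2 by
  # phage 1 must produce phage 2, not phage 1
  d <- derivatives(m, community_state(0, c(0, 1e6), c(1e4, 0)))
  expect_gt(d$dP[2], 0)
  expect_lt(d$dP[1], 0)   # only decay
})

test_that("derivatives reject dimension mismatches and negative states", {
  m <- default_pair("general")
  expect_error(derivatives(m, community_state(1, c(1, 1, 1), 1)), "dimensions")
  expect_error(community_state(1, c(-1, 1), 1), ">= 0")
})

test_that("closed-form equilibria are consistent with the derivatives", {
  h <- host_spec("C", rm_set("r1"), per_rm_cost = 0.05)
  # virus-free fixed point
  p <- model_params(S = 1e6)
  eq <- analytic_equilibria(p, h, with_virus = FALSE)
  expect_equal(eq$state$N, p$delta_b / (p$alpha * 0.95))
  expect_equal(eq$state$B, p$S / p$delta_b)
  m <- rm_model("general", list(h), params = p)
  d <- derivatives(m, eq$state)
  expect_lt(max(abs(c(d$dN, d$dB, d$dP))) /
              max(abs(c(eq$state$N, eq$state$B))), 1e-12)
  # cost-free case
  h0 <- host_spec("C0", rm_set(), per_rm_cost = 0.05)
  expect_equal(analytic_equilibria(p, h0)$state$N, p$delta_b / p$alpha)
  # with-virus fixed point at several supplies
  set.seed(3)
  for (r in 1:10) {
    p2 <- model_params(S = 10^runif(1, 7.5, 10), phi = 10^runif(1, -8.5, -7.5),
                       beta = runif(1, 20, 100))
    eqv <- analytic_equilibria(p2, h, with_virus = TRUE)
    m2 <- rm_model("general", list(h), params = p2)
    d <- derivatives(m2, eqv$state)
    scale <- max(eqv$state$N, eqv$state$B, eqv$state$P)
    expect_lt(max(abs(c(d$dN, d$dB, d$dP))) / scale, 1e-12)
  }
})

test_that("the viral persistence threshold marks exactly where the phage
           population vanishes", {
  h <- host_spec("C", rm_set("r1"))
  p <- model_params(S = 1e6)
  S_crit <- analytic_equilibria(p, h)$S_crit
  gam <- gamma_coefficient(h$rm_set, p$r_e)
  expect_equal(S_crit, p$delta_b * p$delta_p / (p$beta * p$phi * gam))
  p_at <- model_params(S = S_crit)
  eq <- analytic_equilibria(p_at, h, with_virus = TRUE)
  expect_equal(eq$state$P, 0, tolerance = 1e-9)
  p_below <- model_params(S = S_crit * 0.99)
  expect_error(analytic_equilibria(p_below, h, with_virus = TRUE),
               "not sustainable")
})
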