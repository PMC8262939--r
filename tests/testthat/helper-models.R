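# shared fixtures for the model tests: a 1-RM competition specialist vs a
# 2-RM defense specialist under the package default rates
default_pair <- function(kind, m_v = 0.75, S = 1e6) {
  cm <- build_community(2, "subset", kind)
  rm_model(kind, cm$hosts, cm$phages, model_params(S = S, m_v = m_v))
}

test_S_grid <- function(n = 11, lo = 5, hi = 10) 10^seq(lo, hi, length.out = n)

# term-by-term reference evaluation of the model right-hand sides, written
# naively with explicit loops and scalar arithmetic, independent of the
# package's implementation
oracle_derivatives <- function(kind, N, B, P, hosts, phages, params) {
  n <- length(B)
  alpha <- vapply(hosts, function(h) {
    if (is.null(h$alpha)) params$alpha else h$alpha
  }, numeric(1))
  cost <- vapply(hosts, function(h) h$per_rm_cost * length(h$rm_set),
                 numeric(1))
  dN <- params$S
  for (i in seq_len(n)) dN <- dN - alpha[i] * (1 - cost[i]) * B[i] * N
  dB <- numeric(n)
  if (kind == "general") {
    dP <- 0
    for (i in seq_len(n)) {
      gi <- params$r_e^(-length(hosts[[i]]$rm_set))
      dB[i] <- alpha[i] * (1 - cost[i]) * B[i] * N -
        params$phi * gi * B[i] * P[1] - params$delta_b * B[i]
      dP <- dP + params$beta * params$phi * gi * B[i] * P[1]
    }
    dP <- dP - params$delta_p * P[1]
  } else if (kind == "parallel") {
    dP <- numeric(n)
    for (i in seq_len(n)) {
      gi <- params$r_e^(-length(hosts[[i]]$rm_set))
      dB[i] <- alpha[i] * (1 - cost[i]) * B[i] * N -
        params$phi * gi * B[i] * P[i] - params$delta_b * B[i]
      dP[i] <- params$beta * params$phi * gi * B[i] * P[i] -
        params$delta_p * P[i]
    }
  } else {
    dP <- numeric(n)
    for (i in seq_len(n)) {
      inf_i <- 0
      for (j in seq_len(n)) {
        b <- unclass(hosts[[i]]$rm_set)
        p <- unclass(phages[[j]]$methylation)
        expo <- length(setdiff(b, p)) +
          (1 - params$m_v) * length(intersect(b, p))
        gij <- params$r_e^(-expo)
        inf_i <- inf_i + params$phi * gij * B[i] * P[j]
      }
      dB[i] <- alpha[i] * (1 - cost[i]) * B[i] * N - inf_i -
        params$delta_b * B[i]
      dP[i] <- params$beta * inf_i - params$delta_p * P[i]
    }
  }
  list(dN = dN, dB = dB, dP = dP)
}
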