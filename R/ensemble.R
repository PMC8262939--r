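#' Parameter ranges for Latin hypercube ensembles
#'
#' A range table for [lhs_sample()]: one row per parameter with lower and
#' upper bounds and a scale tag. Defaults span a factor of a few around the
#' package's default rates; the per-endonuclease resistance `r_e` and the
#' infection-rate constant `phi` vary over orders of magnitude and default to
#' log-uniform scales.
#'
#' @param ... named length-2 numeric vectors overriding defaults, e.g.
#'   `phi = c(1e-9, 1e-7)`.
#' @param log_params parameters drawn log-uniformly.
#' @return A data frame with columns `param`, `lower`, `upper`, `scale`.
#' @export
lhs_ranges <- function(..., log_params = c("r_e", "phi")) {
  defaults <- list(alpha = c(5e-8, 2e-7),
                   phi = c(2e-9, 5e-8),
                   r_e = c(20, 500),
                   beta = c(25, 100),
                   delta_b = c(0.05, 0.2),
                   delta_p = c(0.05, 0.2),
                   per_rm_cost = c(0.02, 0.08))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  rng <- data.frame(param = names(defaults),
                    lower = vapply(defaults, `[`, numeric(1), 1L),
                    upper = vapply(defaults, `[`, numeric(1), 2L),
                    scale = ifelse(names(defaults) %in% log_params,
                                   "log-uniform", "uniform"),
                    stringsAsFactors = FALSE)
  rownames(rng) <- NULL
  if (any(rng$lower >= rng$upper)) stop("range bounds must satisfy lower < upper")
  if (any(rng$scale == "log-uniform" & rng$lower <= 0)) {
    stop("log-uniform ranges need positive bounds")
  }
  rng
}

#' Latin hypercube sample of model parameters
#'
#' Stratified sampling: for every parameter, each of the `n_draws`
#' equal-probability strata of its (log-)uniform range contains exactly one
#' draw. Fully reproducible from the seed.
#'
#' @param n_draws number of parameter draws.
#' @param ranges a range table from [lhs_ranges()].
#' @param seed integer seed.
#' @return A data frame with `n_draws` rows, one column per parameter, plus a
#'   `draw` index column.
#' @export
lhs_sample <- function(n_draws, ranges = lhs_ranges(), seed = 1L) {
  stopifnot(n_draws >= 1, all(c("param", "lower", "upper", "scale") %in%
                                names(ranges)))
  if (any(ranges$lower >= ranges$upper)) {
    stop("range bounds must satisfy lower < upper")
  }
  k <- nrow(ranges)
  set.seed(seed)
  u <- lhs::randomLHS(n_draws, k)
  out <- as.data.frame(matrix(NA_real_, n_draws, k))
  names(out) <- ranges$param
  for (j in seq_len(k)) {
    lo <- ranges$lower[j]; hi <- ranges$upper[j]
    out[[j]] <- if (ranges$scale[j] == "log-uniform") {
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      lo + u[, j] * (hi - lo)
    }
  }
  cbind(draw = seq_len(n_draws), out)
}

#' Run a supply-sweep ensemble over a Latin hypercube of parameters
#'
#' For each parameter draw, rebuilds the community (costs depend on
#' `per_rm_cost`), runs [sweep_supply()] over the shared grid, and collects
#' host steady abundances. The community structure (number of levels,
#' arrangement, model kind, `m_v`) is held fixed across draws.
#'
#' @param kind model kind.
#' @param S_grid ascending supply-rate grid shared by all draws.
#' @param n_draws ensemble size.
#' @param n_levels,arrangement,include_zero community structure, see
#'   [build_community()].
#' @param m_v virion methylation (memory model).
#' @param ranges parameter ranges ([lhs_ranges()]).
#' @param seed root seed for the hypercube.
#' @param ... passed to [sweep_supply()] (tolerances, thresholds).
#' @return An object of class `rm_ensemble`: a data frame of host rows
#'   (`draw`, `S`, `population`, `rm_count`, `abundance`, `persists`) with
#'   the parameter table in `attr(, "params")`.
#' @export
run_ensemble <- function(kind = c("general", "parallel", "memory"),
                         S_grid, n_draws = 100, n_levels = 2,
                         arrangement = "subset", include_zero = FALSE,
                         m_v = 0.99, ranges = lhs_ranges(), seed = 1L, ...) {
  kind <- match.arg(kind)
  draws <- lhs_sample(n_draws, ranges, seed = seed)
  res <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    pr <- draws[d, ]
    cm <- build_community(n_levels, arrangement, kind,
                          per_rm_cost = pr$per_rm_cost,
                          include_zero = include_zero)
    params <- model_params(S = S_grid[1], alpha = pr$alpha, phi = pr$phi,
                           r_e = pr$r_e, m_v = m_v, beta = pr$beta,
                           delta_b = pr$delta_b, delta_p = pr$delta_p)
    model <- rm_model(kind, cm$hosts, cm$phages, params)
    sw <- sweep_supply(model, S_grid, ...)
    hosts <- sw[sw$type == "host",
                c("S", "population", "rm_count", "abundance", "persists")]
    hosts$draw <- d
    res[[d]] <- hosts
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "params") <- draws
  attr(out, "kind") <- kind
  class(out) <- c("rm_ensemble", "data.frame")
  out
}

#' Quantile summary of an ensemble of sweeps
#'
#' Per supply rate and population: the median and the 25th/75th quantiles of
#' steady abundance across draws (the ribbon statistics of ensemble plots).
#'
#' @param ensemble an [run_ensemble()] result, or a list of [sweep_supply()]
#'   results sharing one S grid.
#' @return A data frame with columns `S`, `population`, `q25`, `median`,
#'   `q75`, `n_draws`.
#' @export
ensemble_summary <- function(ensemble) {
  if (inherits(ensemble, "rm_ensemble")) {
    hosts <- as.data.frame(ensemble)
  } else if (is.list(ensemble) &&
             all(vapply(ensemble, inherits, logical(1), "rm_sweep"))) {
    grids <- lapply(ensemble, function(s) unique(s$S))
    if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
      stop("all sweeps must share the same S grid")
    }
    hosts <- do.call(rbind, lapply(seq_along(ensemble), function(d) {
      h <- ensemble[[d]][ensemble[[d]]$type == "host", ]
      h$draw <- d
      as.data.frame(h)
    }))
  } else {
    stop("ensemble must be an rm_ensemble or a list of rm_sweep objects")
  }
  key <- interaction(hosts$S, hosts$population, drop = TRUE)
  out <- do.call(rbind, lapply(split(hosts, key), function(d) {
    q <- stats::quantile(d$abundance, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(S = d$S[1], population = d$population[1],
               q25 = q[1], median = q[2], q75 = q[3], n_draws = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$S, out$population), ]
  rownames(out) <- NULL
  out
}
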