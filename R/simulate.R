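pack_state <- function(state) c(N = state$N, B = state$B, P = state$P)

unpack_state <- function(model, y, t = 0) {
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  community_state(N = max(y[1L], 0),
                  B = pmax(y[1L + seq_len(n)], 0),
                  P = pmax(y[1L + n + seq_len(np)], 0),
                  t = t)
}

# parameter vector for the compiled right-hand side (see src/rmdefense_ode.c)
model_parms_vec <- function(model) {
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  p <- model$params
  alpha_eff <- host_alpha(model) * (1 - host_cost(model))
  G <- model$Gamma
  Gmat <- switch(model$kind,
                 general = matrix(G, nrow = n, ncol = 1L),
                 parallel = diag(G, nrow = n),
                 memory = G)
  pv <- c(n, np, p$S, p$phi, p$beta, p$delta_b, p$delta_p, alpha_eff,
          as.numeric(Gmat))
  if (length(pv) > 2048) stop("community too large for the compiled solver")
  # the compiled initializer expects a fixed-length parameter block
  c(pv, numeric(2048 - length(pv)))
}

rm_lsoda <- function(y, times, model, maxsteps = 20000) {
  suppressWarnings(
    deSolve::lsoda(y, times = times, func = "rm_derivs",
                   dllname = "rmdefense", initfunc = "rm_initmod",
                   parms = model_parms_vec(model),
                   rtol = 1e-8, atol = 1e-6, maxsteps = maxsteps))
}

model_rhs <- function(model) {
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  p <- model$params
  alpha_eff <- host_alpha(model) * (1 - host_cost(model))
  G <- model$Gamma
  kind <- model$kind
  function(t, y, parms) {
    N <- y[1L]
    B <- y[1L + seq_len(n)]
    P <- y[1L + n + seq_len(np)]
    # the integrator may probe slightly negative values; evaluate on the
    # clipped state so fluxes stay physical
    N <- max(N, 0); B <- pmax(B, 0); P <- pmax(P, 0)
    growth <- alpha_eff * B * N
    dN <- p$S - sum(growth)
    if (kind == "general") {
      infections <- p$phi * G * B * P
      dB <- growth - infections - p$delta_b * B
      dP <- p$beta * sum(infections) - p$delta_p * P
    } else if (kind == "parallel") {
      infections <- p$phi * G * B * P
      dB <- growth - infections - p$delta_b * B
      dP <- p$beta * infections - p$delta_p * P
    } else {
      flux <- p$phi * G * outer(B, P)
      dB <- growth - rowSums(flux) - p$delta_b * B
      dP <- p$beta * rowSums(flux) - p$delta_p * P
    }
    list(c(dN, dB, dP))
  }
}

# Newton refinement of a steady state on the support of the current state.
# Populations at exactly zero stay zero (a valid invariant set of the ODE).
# The positive components are solved in log space, which preserves
# positivity across iterations, equalizes the wildly different state
# magnitudes, and keeps the iteration on the root whose support matches the
# trajectory (roots with a vanishing component sit at -Inf and cannot be
# crossed). Residuals are per-capita rates, so the convergence criterion is
# the same relative-derivative criterion the integrator uses. A component
# driven below an absolute floor is removed from the support and the solve
# restarted. The candidate is accepted only if it is locally stable (all
# Jacobian eigenvalues of the original system have negative real part) and
# no zeroed population regrows from it.
newton_equilibrium <- function(rhs, y, rel_tol) {
  m <- length(y)
  support <- which(y > 0)
  restart <- 0L
  while (length(support) > 0L && restart < m) {
    restart <- restart + 1L
    g <- function(w) {
      yy <- numeric(m)
      yy[support] <- exp(w)
      unlist(rhs(0, yy, NULL))[support] / exp(w)   # per-capita residuals
    }
    w <- log(y[support])
    gw <- g(w)
    if (any(!is.finite(gw))) return(NULL)
    dropped <- FALSE
    for (iter in 1:80) {
      J <- matrix(0, length(w), length(w))
      for (k in seq_along(w)) {
        h <- 1e-6
        wp <- w; wp[k] <- wp[k] + h
        wm <- w; wm[k] <- wm[k] - h
        J[, k] <- (g(wp) - g(wm)) / (2 * h)
      }
      step <- tryCatch(solve(J, gw), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damped update: halve until the residual norm decreases
      lambda <- 1
      repeat {
        w_new <- w - lambda * step
        g_new <- g(w_new)
        if (all(is.finite(g_new)) && sum(g_new^2) < sum(gw^2)) break
        lambda <- lambda / 2
        if (lambda < 1e-4) return(NULL)
      }
      w <- w_new
      gw <- g_new
      if (any(w < log(1e-12))) {       # component heading to extinction
        support <- support[w >= log(1e-12)]
        dropped <- TRUE
        break
      }
      if (max(abs(gw)) < 1e-3 * rel_tol) break
      if (iter == 80) return(NULL)
    }
    if (dropped) next
    if (max(abs(gw)) >= 1e-3 * rel_tol) return(NULL)
    y_eq <- numeric(m)
    y_eq[support] <- exp(w)
    d_full <- unlist(rhs(0, y_eq, NULL))
    # zeroed populations must not regrow materially from the candidate state
    # (a production flux of 1e-2 /ml/day sustains << 1 virion or cell per ml)
    if (length(support) < m &&
        any(abs(d_full[-support]) > 1e-2)) return(NULL)
    # stability of the full (untransformed) system at the candidate
    Jf <- matrix(0, m, m)
    for (k in seq_len(m)) {
      h <- 1e-7 * max(y_eq[k], 1e-2)
      yp <- y_eq; yp[k] <- yp[k] + h
      ym <- y_eq; ym[k] <- max(ym[k] - h, 0)
      Jf[, k] <- (unlist(rhs(0, yp, NULL)) - unlist(rhs(0, ym, NULL))) /
        (yp[k] - ym[k])
    }
    ev <- eigen(Jf, only.values = TRUE)$values
    if (max(Re(ev)) > -1e-10) return(NULL)   # unstable or marginal: reject
    return(y_eq)
  }
  NULL
}

#' Integrate a model to its equilibrium steady state
#'
#' Integrates the ODE system with a stiffness-switching adaptive integrator
#' (`deSolve::lsoda`) in doubling time chunks until the equilibrium criterion
#' `max_i |dx_i/dt| / (|x_i| + eps)` drops below `rel_tol`, or `t_max` is
#' reached. After an initial transient, each chunk additionally attempts a
#' Newton refinement of the steady state on the support of the current
#' trajectory; the refined state is accepted only when it is non-negative,
#' locally stable and consistent with the excluded populations, which
#' resolves the slowly damped predator-prey oscillations that would
#' otherwise take very long to satisfy the derivative criterion.
#' Populations that decay below an absolute extinction floor
#' (1e-10 of a cell or virion per ml) are clipped to exactly zero between
#' chunks; without the floor an exponentially decaying population keeps a
#' relative derivative of `delta_b` forever and the criterion could never be
#' met. If no equilibrium is certified by `t_max` (e.g. sustained
#' oscillation) the returned state is the time average over the final 10%
#' of the horizon and `converged` is `FALSE`.
#'
#' @param model an [rm_model()].
#' @param init initial [community_state()]; defaults to 1e4 cells (and
#'   virions) per ml with nutrients at 1e4 cellular equivalents per ml.
#' @param rel_tol equilibrium criterion on the maximum relative derivative.
#' @param t_max integration horizon in days.
#' @return A list with `state` (the equilibrium [community_state()]),
#'   `converged` (logical) and `t` (days integrated).
#' @examples
#' m <- rm_model("general", list(host_spec("C", rm_set("r1"))),
#'               params = model_params(S = 1e6))
#' integrate_to_equilibrium(m)$state$B  # ~ S / delta_b = 1e7
#' @export
integrate_to_equilibrium <- function(model, init = NULL, rel_tol = 1e-6,
                                     t_max = 1e5) {
  stopifnot(inherits(model, "rm_model"), rel_tol > 0)
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  if (is.null(init)) {
    init <- community_state(1e4, rep(1e4, n), rep(1e4, np))
  }
  if (length(init$B) != n || length(init$P) != np) {
    stop("init dimensions do not match the model")
  }
  rhs <- model_rhs(model)
  eps <- 1e-30
  floor_abund <- 1e-10
  transient <- 50           # days before Newton refinement is attempted
  max_calls <- 60           # integrator-call budget before declaring
                            # sustained oscillation
  y <- pack_state(init)
  t_now <- 0
  chunk <- 50
  n_calls <- 0L
  newton_tries <- 0L
  traj <- NULL
  repeat {
    t_end <- min(t_now + chunk, t_max)
    sol <- rm_lsoda(y, seq(t_now, t_end, length.out = 25), model)
    n_calls <- n_calls + 1L
    t_reached <- sol[nrow(sol), 1L]
    y_new <- sol[nrow(sol), -1L]
    if (any(!is.finite(y_new))) {
      stop("integration failed (non-finite state) at t = ", t_now,
           "; last valid state: ", paste(signif(y, 4), collapse = ", "))
    }
    y <- y_new
    # extinction floor: treat vanishing populations as exactly absent
    y[-1L][y[-1L] < floor_abund] <- 0
    y[y < 0] <- 0
    traj <- pmax(sol[, -1L, drop = FALSE], 0)
    if (t_reached < t_end) {       # step budget hit: retry in smaller chunks
      t_now <- t_reached
      chunk <- max(chunk / 4, 25)
    } else {
      t_now <- t_end
    }
    d <- unlist(rhs(t_now, y, NULL))
    crit <- max(abs(d) / (abs(y) + eps))
    if (crit < rel_tol) {
      return(list(state = unpack_state(model, y, t_now), converged = TRUE,
                  t = t_now))
    }
    if (t_now >= transient) {
      # seed Newton from the chunk's geometric time average, which centers
      # any residual predator-prey oscillation near the fixed point, then
      # fall back to the final state
      newton_tries <- newton_tries + 1L
      y_bar <- exp(colMeans(log(traj + floor_abund))) - floor_abund
      y_bar[y <= 0] <- 0
      y_bar[y_bar < 0] <- 0
      for (seed_state in list(y_bar, y)) {
        y_eq <- newton_equilibrium(rhs, seed_state, rel_tol)
        if (!is.null(y_eq)) {
          return(list(state = unpack_state(model, y_eq, t_now),
                      converged = TRUE, t = t_now))
        }
      }
    }
    # repeated Newton failures past the transient indicate no stable
    # positive steady state is reachable from here (sustained oscillation):
    # stop early rather than resolving the cycle over the full horizon
    if (t_now >= t_max || n_calls >= max_calls ||
        (newton_tries >= 8 && t_now >= 1000)) break
    chunk <- min(chunk * 2, 6400)
  }
  # non-converged: report the time average over the final integration window
  y_avg <- colMeans(traj)
  y_avg[y_avg < 0] <- 0
  list(state = unpack_state(model, y_avg, t_now), converged = FALSE,
       t = t_now)
}

#' Simulate a model trajectory
#'
#' `simulate()` on an [rm_model()] returns the time-dependent solution as a
#' data frame, one row per saved time point.
#'
#' @param object an [rm_model()].
#' @param nsim number of saved time points.
#' @param seed ignored (the dynamics are deterministic); present for the
#'   generic's signature.
#' @param init initial [community_state()].
#' @param t_max horizon in days.
#' @param ... unused.
#' @return A data frame with columns `time`, `N`, one `B_<id>` per host and
#'   one `P_<id>` per phage.
#' @export
simulate.rm_model <- function(object, nsim = 200, seed = NULL, init = NULL,
                              t_max = 1000, ...) {
  n <- length(object$hosts)
  np <- if (object$kind == "general") 1L else n
  if (is.null(init)) init <- community_state(1e4, rep(1e4, n), rep(1e4, np))
  times <- seq(0, t_max, length.out = nsim)
  sol <- rm_lsoda(pack_state(init), times, object, maxsteps = 100000)
  out <- as.data.frame(sol)
  names(out) <- c("time", "N",
                  paste0("B_", vapply(object$hosts, `[[`, character(1), "id")),
                  paste0("P_", vapply(object$phages, `[[`, character(1), "id")))
  out
}

#' Classify equilibrium community composition
#'
#' A population persists if its steady abundance is at or above the
#' extinction threshold. The community label summarizes the persistence
#' pattern of the host populations: `"monoculture of <id>"` when one
#' persists, `"coexistence"` when all do, `"exclusion of <ids>"` otherwise,
#' and `"collapse"` when none do.
#'
#' @param state a [community_state()].
#' @param hosts list of [host_spec()] matching `state$B`.
#' @param threshold extinction threshold (cells ml^-1), default 1.
#' @return A list with logical vectors `host_persists`, `phage_persists` and
#'   a character `label`.
#' @export
classify_outcome <- function(state, hosts = NULL, threshold = 1) {
  stopifnot(threshold > 0)
  ids <- if (is.null(hosts)) {
    as.character(seq_along(state$B))
  } else {
    vapply(hosts, `[[`, character(1), "id")
  }
  bp <- state$B >= threshold
  pp <- state$P >= threshold
  label <- if (!any(bp)) {
    "collapse"
  } else if (all(bp)) {
    if (length(bp) == 1L) paste0("monoculture of ", ids[1]) else "coexistence"
  } else if (sum(bp) == 1L) {
    paste0("monoculture of ", ids[bp])
  } else {
    paste0("exclusion of ", paste(ids[!bp], collapse = ", "))
  }
  list(host_persists = stats::setNames(bp, ids), phage_persists = pp,
       label = label)
}

#' Build a ladder community of increasingly defended hosts
#'
#' Host `i` carries `i` RM systems. Under the `"subset"` arrangement each
#' set nests the previous one (`{r1} \subset {r1,r2} \subset ...`), the
#' scenario where defense specialists arose by successive gene gain. Under
#' the `"unique"` arrangement the sets are pairwise disjoint, the endpoint of
#' repeated gene gain *and* loss. A 0-RM host can be prepended with
#' `include_zero`.
#'
#' @param n_levels number of host populations (host `i` has `i` RMs).
#' @param arrangement `"subset"` or `"unique"`.
#' @param kind model kind; controls the phage complement (see [rm_model()]).
#' @param per_rm_cost cost fraction per RM system.
#' @param include_zero prepend an undefended (0-RM) host.
#' @return A list with `hosts` and `phages` ready for [rm_model()].
#' @examples
#' cm <- build_community(3, "subset", "memory")
#' vapply(cm$hosts, function(h) rm_size(h$rm_set), integer(1))  # 1 2 3
#' @export
build_community <- function(n_levels, arrangement = c("subset", "unique"),
                            kind = c("general", "parallel", "memory"),
                            per_rm_cost = 0.05, include_zero = FALSE) {
  arrangement <- match.arg(arrangement)
  kind <- match.arg(kind)
  stopifnot(n_levels >= 1)
  sizes <- seq_len(n_levels)
  if (include_zero) sizes <- c(0L, sizes)
  sets <- vector("list", length(sizes))
  next_id <- 1L
  for (k in seq_along(sizes)) {
    sz <- sizes[k]
    if (arrangement == "subset") {
      sets[[k]] <- rm_set(if (sz > 0) paste0("r", seq_len(sz)) else character(0))
    } else {
      ids <- if (sz > 0) paste0("r", seq(next_id, length.out = sz)) else character(0)
      next_id <- next_id + sz
      sets[[k]] <- rm_set(ids)
    }
  }
  hosts <- lapply(seq_along(sizes), function(k) {
    host_spec(paste0("H", sizes[k]), sets[[k]], per_rm_cost = per_rm_cost)
  })
  list(hosts = hosts, phages = default_phages(kind, hosts))
}

#' Sweep the nutrient supply rate to steady state
#'
#' For each supply rate in the ascending grid, integrates the model to
#' equilibrium. With `warm_start` (the default) the previous steady state
#' seeds the next integration, with extinct populations reseeded at a small
#' floor abundance so that invasion at higher supply remains possible.
#'
#' @param model an [rm_model()]; its `params$S` is overridden by the grid.
#' @param S_grid ascending vector of supply rates
#'   (cellular equivalents ml^-1 day^-1).
#' @param warm_start seed each run from the previous steady state.
#' @param init initial state for the first (or every, if `warm_start =
#'   FALSE`) integration.
#' @param extinction_threshold abundance below which a population is scored
#'   extinct (cells or virions per ml).
#' @param reseed_floor abundance at which extinct populations are reseeded
#'   under warm starts.
#' @param rel_tol,t_max passed to [integrate_to_equilibrium()].
#' @return An object of class `rm_sweep`: a data frame with one row per
#'   supply rate and population (`S`, `population`, `type`, `rm_count`,
#'   `abundance`, `persists`, `converged`, `label`), plus the nutrient
#'   concentration rows (`type = "nutrient"`).
#' @export
sweep_supply <- function(model, S_grid, warm_start = TRUE, init = NULL,
                         extinction_threshold = 1, reseed_floor = 1e-2,
                         rel_tol = 1e-6, t_max = 1e5) {
  stopifnot(inherits(model, "rm_model"), length(S_grid) >= 1)
  if (is.unsorted(S_grid, strictly = TRUE)) {
    stop("S_grid must be strictly increasing")
  }
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  host_ids <- vapply(model$hosts, `[[`, character(1), "id")
  phage_ids <- vapply(model$phages, `[[`, character(1), "id")
  rm_counts <- vapply(model$hosts, function(h) rm_size(h$rm_set), integer(1))
  state <- init
  rows <- vector("list", length(S_grid))
  for (k in seq_along(S_grid)) {
    params_k <- model$params
    params_k$S <- S_grid[k]
    model_k <- model
    model_k$params <- params_k
    res <- tryCatch(
      integrate_to_equilibrium(model_k, init = state, rel_tol = rel_tol,
                               t_max = t_max),
      error = function(e) stop("sweep failed at S = ", format(S_grid[k]),
                               ": ", conditionMessage(e)))
    eq <- res$state
    out <- classify_outcome(eq, model$hosts,
                            threshold = extinction_threshold)
    rows[[k]] <- data.frame(
      S = S_grid[k],
      population = c("N", host_ids, phage_ids),
      type = c("nutrient", rep("host", n), rep("phage", np)),
      rm_count = c(NA_integer_, rm_counts, rep(NA_integer_, np)),
      abundance = c(eq$N, eq$B, eq$P),
      persists = c(NA, out$host_persists, out$phage_persists),
      converged = res$converged,
      label = out$label,
      stringsAsFactors = FALSE)
    if (warm_start) {
      state <- community_state(eq$N, pmax(eq$B, reseed_floor),
                               pmax(eq$P, reseed_floor))
    } else {
      state <- init
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "kind") <- model$kind
  attr(out, "extinction_threshold") <- extinction_threshold
  class(out) <- c("rm_sweep", "data.frame")
  out
}

#' @export
print.rm_sweep <- function(x, ...) {
  cat("Supply-rate sweep (", attr(x, "kind"), " model): ",
      length(unique(x$S)), " supply rates, ",
      sum(x$type == "host") / length(unique(x$S)), " hosts\n", sep = "")
  labels <- unique(x[, c("S", "label")])
  for (i in seq_len(nrow(labels))) {
    cat(sprintf("  S = %-10.4g %s\n", labels$S[i], labels$label[i]))
  }
  invisible(x)
}

#' @export
plot.rm_sweep <- function(x, log = "xy", ...) {
  hosts <- x[x$type == "host", ]
  pops <- unique(hosts$population)
  floor_plot <- 1e-2
  plot(NA, xlim = range(hosts$S), ylim = range(pmax(hosts$abundance, floor_plot)),
       log = log, xlab = "nutrient supply rate (C.E. / ml / day)",
       ylab = "steady abundance (cells / ml)", ...)
  for (i in seq_along(pops)) {
    sub <- hosts[hosts$population == pops[i], ]
    graphics::lines(sub$S, pmax(sub$abundance, floor_plot), col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = pops, col = seq_along(pops), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Total community abundance against the dominant population's RM count
#'
#' For each supply rate, sums host abundance and records the RM count of the
#' most abundant host, tracing how community carrying capacity scales as
#' better-defended genotypes take over along the nutrient gradient.
#'
#' @param sweep an [sweep_supply()] result.
#' @return A data frame with columns `S`, `dominant_rmpg`, `total_abundance`.
#' @export
total_abundance_curve <- function(sweep) {
  stopifnot(inherits(sweep, "rm_sweep"))
  hosts <- sweep[sweep$type == "host", ]
  out <- do.call(rbind, lapply(split(hosts, hosts$S), function(d) {
    data.frame(S = d$S[1],
               dominant_rmpg = d$rm_count[which.max(d$abundance)],
               total_abundance = sum(d$abundance))
  }))
  out <- out[order(out$S), ]
  rownames(out) <- NULL
  out
}
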