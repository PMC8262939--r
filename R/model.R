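#' Specify a bacterial host population
#'
#' @param id character label for the population.
#' @param rm_set the population's RM complement ([rm_set()] or character).
#' @param per_rm_cost fraction of nutrient utilization lost per RM system;
#'   total cost `c = per_rm_cost * |rm_set|` must stay below 1.
#' @param alpha optional per-population nutrient utilization rate
#'   (ml cell^-1 day^-1) overriding the shared value in [model_params()].
#' @return An object of class `host_spec`.
#' @export
host_spec <- function(id, rm_set = rmdefense::rm_set(), per_rm_cost = 0.05,
                      alpha = NULL) {
  rm_set <- as_rm_set(rm_set)
  cost <- total_cost(rm_set, per_rm_cost)  # validates c < 1
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0")
  structure(list(id = as.character(id), rm_set = rm_set,
                 per_rm_cost = per_rm_cost, cost = cost, alpha = alpha),
            class = "host_spec")
}

#' Specify a phage population
#'
#' In the general model there is a single phage with no methylation state.
#' In the parallel and memory models each phage emerges from exactly one host
#' population (`host_index`); in the memory model its methylation pattern is
#' that host's RM set.
#'
#' @param id character label.
#' @param methylation virion methylation pattern as an [rm_set()] (empty for
#'   the general and parallel models).
#' @param host_index index of the sole host population whose bursts produce
#'   this phage (`NA` for the general model's shared phage).
#' @return An object of class `phage_spec`.
#' @export
phage_spec <- function(id, methylation = rm_set(), host_index = NA_integer_) {
  structure(list(id = as.character(id), methylation = as_rm_set(methylation),
                 host_index = as.integer(host_index)),
            class = "phage_spec")
}

#' Model rate constants and structural parameters
#'
#' @param S nutrient supply rate (cellular equivalents ml^-1 day^-1).
#' @param alpha nutrient utilization rate (ml cell^-1 day^-1).
#' @param phi baseline infection rate constant (ml virus^-1 day^-1).
#' @param r_e fold-resistance conferred per RM endonuclease (dimensionless,
#'   `>= 1`).
#' @param m_v virion methylation fraction in `[0, 1]` (memory model only).
#' @param beta burst size (virus cell^-1, `>= 1`).
#' @param delta_b host loss rate (day^-1).
#' @param delta_p phage loss rate (day^-1).
#' @return An object of class `model_params` (a validated named list).
#' @details Defaults give a system in which, for a 1-RM vs 2-RM host pair,
#'   the three supply regimes (competition-specialist monoculture,
#'   coexistence, defense-specialist dominance) unfold across
#'   `S` from 1e5 to 1e10 cellular equivalents ml^-1 day^-1.
#' @export
model_params <- function(S = 1e6, alpha = 1e-7, phi = 1e-8, r_e = 100,
                         m_v = 0.75, beta = 50, delta_b = 0.1, delta_p = 0.1) {
  vals <- list(S = S, alpha = alpha, phi = phi, r_e = r_e, m_v = m_v,
               beta = beta, delta_b = delta_b, delta_p = delta_p)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("parameter '", nm, "' must be a single finite non-negative number")
    }
  }
  if (vals$r_e < 1) stop("r_e must be >= 1")
  if (vals$m_v > 1) stop("m_v must be in [0, 1]")
  if (vals$beta < 1) stop("beta must be >= 1")
  structure(vals, class = "model_params")
}

#' Community state at a time point
#'
#' @param N nutrient concentration (cellular equivalents ml^-1).
#' @param B vector of host abundances (cells ml^-1), one per host population.
#' @param P vector of phage abundances (virus ml^-1): length 1 in the general
#'   model, one per host in the parallel and memory models.
#' @param t time in days.
#' @return An object of class `community_state`.
#' @export
community_state <- function(N, B, P, t = 0) {
  if (any(!is.finite(c(N, B, P)))) stop("state entries must be finite")
  if (N < 0 || any(B < 0) || any(P < 0)) stop("state entries must be >= 0")
  structure(list(N = N, B = as.numeric(B), P = as.numeric(P), t = t),
            class = "community_state")
}

#' Construct a host-phage interaction model
#'
#' Binds a model kind, host and phage specifications and parameters into a
#' single classed object. Three kinds are supported:
#' \describe{
#'   \item{general}{one phage infects every host; host `i` is attacked at
#'     rate `phi * gamma_i * B_i * P` with `gamma_i = r_e^-|b_i|`.}
#'   \item{parallel}{one phage per host; phage `i` infects and reproduces
#'     only on host `i`.}
#'   \item{memory}{one phage per host; every phage infects every host at
#'     rates given by the methylation-aware matrix [gamma_matrix()], but the
#'     progeny of all infections of host `i` join phage population `i`
#'     (they inherit host `i`'s methylation pattern).}
#' }
#'
#' @param kind one of `"general"`, `"parallel"`, `"memory"`.
#' @param hosts list of [host_spec()] objects.
#' @param phages list of [phage_spec()] objects, or `NULL` to build the
#'   canonical phage complement for `kind` (a single naive phage for
#'   general; one phage per host, methylated with its host's RM set for
#'   memory, unmethylated for parallel).
#' @param params a [model_params()] object.
#' @return An object of class `rm_model`.
#' @examples
#' m <- rm_model("general",
#'               hosts = list(host_spec("C", rm_set("r1")),
#'                            host_spec("D", rm_set("r1", "r2"))),
#'               params = model_params(S = 1e7))
#' m
#' @export
rm_model <- function(kind = c("general", "parallel", "memory"),
                     hosts, phages = NULL, params = model_params()) {
  kind <- match.arg(kind)
  stopifnot(is.list(hosts), length(hosts) >= 1)
  if (!all(vapply(hosts, inherits, logical(1), "host_spec"))) {
    stop("hosts must be a list of host_spec objects")
  }
  if (!inherits(params, "model_params")) stop("params must be model_params()")
  if (is.null(phages)) phages <- default_phages(kind, hosts)
  if (!all(vapply(phages, inherits, logical(1), "phage_spec"))) {
    stop("phages must be a list of phage_spec objects")
  }
  n <- length(hosts)
  if (kind == "general") {
    if (length(phages) != 1L) stop("general model has exactly one phage")
  } else {
    if (length(phages) != n) {
      stop(kind, " model needs one phage per host population")
    }
    idx <- vapply(phages, function(p) p$host_index, integer(1))
    if (!identical(sort(idx), seq_len(n))) {
      stop("each phage must emerge from exactly one host population")
    }
    if (kind == "memory") {
      ok <- vapply(seq_len(n), function(j) {
        setequal(phages[[j]]$methylation, hosts[[phages[[j]]$host_index]]$rm_set)
      }, logical(1))
      if (!all(ok)) {
        stop("memory model: phage methylation must equal its source host's RM set")
      }
    }
  }
  obj <- structure(list(kind = kind, hosts = hosts, phages = phages,
                        params = params),
                   class = "rm_model")
  obj$Gamma <- model_gamma(obj)
  obj
}

default_phages <- function(kind, hosts) {
  if (kind == "general") {
    return(list(phage_spec("P")))
  }
  lapply(seq_along(hosts), function(i) {
    meth <- if (kind == "memory") hosts[[i]]$rm_set else rm_set()
    phage_spec(paste0("P", i), methylation = meth, host_index = i)
  })
}

# Infection-coefficient structure for a model: a vector gamma_i for general
# and parallel kinds, the full host-by-phage matrix for the memory kind.
model_gamma <- function(model) {
  host_sets <- lapply(model$hosts, `[[`, "rm_set")
  if (model$kind == "memory") {
    phage_sets <- lapply(model$phages, `[[`, "methylation")
    gamma_matrix(host_sets, phage_sets, model$params$r_e, model$params$m_v)
  } else {
    vapply(host_sets, gamma_coefficient, numeric(1), r_e = model$params$r_e)
  }
}

host_alpha <- function(model) {
  vapply(model$hosts, function(h) {
    if (is.null(h$alpha)) model$params$alpha else h$alpha
  }, numeric(1))
}

host_cost <- function(model) {
  vapply(model$hosts, `[[`, numeric(1), "cost")
}

#' Time derivatives of a community state
#'
#' Pure evaluation of the model right-hand side. Nutrients follow
#' `dN/dt = S - sum_i alpha_i (1 - c_i) B_i N`; hosts grow on nutrients, are
#' lost at `delta_b` and to infection; phage reproduce with burst size `beta`
#' from the infections they cause (general, parallel) or from all infections
#' of their source host (memory) and are lost at `delta_p`.
#'
#' @param model an [rm_model()].
#' @param state a [community_state()] with dimensions matching the model.
#' @return A list with elements `dN`, `dB`, `dP`.
#' @export
derivatives <- function(model, state) {
  stopifnot(inherits(model, "rm_model"), inherits(state, "community_state"))
  n <- length(model$hosts)
  np <- if (model$kind == "general") 1L else n
  if (length(state$B) != n || length(state$P) != np) {
    stop("state dimensions do not match the model")
  }
  if (state$N < 0 || any(state$B < 0) || any(state$P < 0)) {
    stop("negative abundances are not allowed")
  }
  p <- model$params
  alpha <- host_alpha(model)
  cost <- host_cost(model)
  growth <- alpha * (1 - cost) * state$B * state$N
  dN <- p$S - sum(growth)
  if (model$kind == "general") {
    g <- model$Gamma
    infections <- p$phi * g * state$B * state$P   # per-host infection flux
    dB <- growth - infections - p$delta_b * state$B
    dP <- p$beta * sum(infections) - p$delta_p * state$P
  } else if (model$kind == "parallel") {
    g <- model$Gamma
    infections <- p$phi * g * state$B * state$P
    dB <- growth - infections - p$delta_b * state$B
    dP <- p$beta * infections - p$delta_p * state$P
  } else {
    G <- model$Gamma                              # hosts x phages
    flux <- p$phi * G * outer(state$B, state$P)   # flux[i, j]
    dB <- growth - rowSums(flux) - p$delta_b * state$B
    dP <- p$beta * rowSums(flux) - p$delta_p * state$P
  }
  list(dN = dN, dB = dB, dP = dP)
}

#' Closed-form single-host equilibria and viral persistence threshold
#'
#' For a single host population (general-model structure) the steady states
#' are available in closed form. Without virus: `N* = delta_b / (alpha (1-c))`
#' and `B* = S / delta_b`. With virus the host is checked by phage at
#' `B* = delta_p / (beta phi gamma)`, nutrients satisfy
#' `N* = S / (alpha (1-c) B*)` and
#' `P* = (alpha (1-c) N* - delta_b) / (phi gamma)`. The virus persists only
#' above the critical supply `S_crit = delta_b delta_p / (beta phi gamma)`.
#'
#' @param params a [model_params()].
#' @param host a [host_spec()].
#' @param with_virus logical: return the coexistence equilibrium (requires
#'   `S > S_crit`) or the virus-free one.
#' @return A list with the equilibrium [community_state()] (`state`) and the
#'   viral persistence threshold `S_crit`.
#' @export
analytic_equilibria <- function(params, host, with_virus = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(host, "host_spec"))
  alpha <- if (is.null(host$alpha)) params$alpha else host$alpha
  cs <- host$cost
  gam <- gamma_coefficient(host$rm_set, params$r_e)
  S_crit <- params$delta_b * params$delta_p / (params$beta * params$phi * gam)
  if (!with_virus) {
    Nstar <- params$delta_b / (alpha * (1 - cs))
    Bstar <- params$S / params$delta_b
    state <- community_state(Nstar, Bstar, 0)
  } else {
    if (params$S < S_crit) {
      stop("virus not sustainable: S <= S_crit = ", format(S_crit))
    }
    Bstar <- params$delta_p / (params$beta * params$phi * gam)
    Nstar <- params$S / (alpha * (1 - cs) * Bstar)
    Pstar <- (alpha * (1 - cs) * Nstar - params$delta_b) / (params$phi * gam)
    state <- community_state(Nstar, Bstar, Pstar)
  }
  list(state = state, S_crit = S_crit)
}

#' @export
print.rm_model <- function(x, ...) {
  cat("Host-phage interaction model (", x$kind, ")\n", sep = "")
  cat("  hosts:", length(x$hosts), "| phages:",
      if (x$kind == "general") 1 else length(x$phages), "\n")
  for (h in x$hosts) {
    cat(sprintf("    %-8s |b| = %d  cost = %.3f\n", h$id, rm_size(h$rm_set),
                h$cost))
  }
  p <- x$params
  cat(sprintf("  S = %.3g, alpha = %.3g, phi = %.3g, r_e = %.3g, beta = %.3g\n",
              p$S, p$alpha, p$phi, p$r_e, p$beta))
  cat(sprintf("  delta_b = %.3g, delta_p = %.3g", p$delta_b, p$delta_p))
  if (x$kind == "memory") cat(sprintf(", m_v = %.3g", p$m_v))
  cat("\n")
  invisible(x)
}

#' @export
summary.rm_model <- function(object, ...) {
  G <- object$Gamma
  cat("Infection susceptibility structure:\n")
  if (is.matrix(G)) {
    dimnames(G) <- list(vapply(object$hosts, `[[`, character(1), "id"),
                        vapply(object$phages, `[[`, character(1), "id"))
  } else {
    names(G) <- vapply(object$hosts, `[[`, character(1), "id")
  }
  print(signif(G, 4))
  invisible(print(object))
}
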