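#' Construct a set of restriction-modification system identifiers
#'
#' An `rm_set` is an immutable mathematical set of opaque RM-system labels.
#' It represents either the RM complement of a bacterial host population
#' (`b_i`) or, as a methylation pattern, the set of host RM systems whose
#' recognition motifs are methylated on a virion's genome (`p_j`). Equality of
#' members is by label; duplicates are dropped and order is irrelevant.
#'
#' @param ... character vectors of RM identifiers (may be empty).
#' @return An object of class `rm_set`: a sorted character vector of unique
#'   identifiers.
#' @examples
#' rm_set("r1", "r2")
#' rm_set()                    # an undefended host / unmethylated virion
#' rm_size(rm_set("a", "a"))   # 1 -- set semantics
#' @export
rm_set <- function(...) {
  members <- unlist(list(...), use.names = FALSE)
  if (is.null(members)) members <- character(0)
  if (length(members) > 0 && !is.character(members)) {
    members <- as.character(members)
  }
  if (anyNA(members)) stop("RM identifiers must not be NA")
  structure(sort(unique(members)), class = "rm_set")
}

#' @export
print.rm_set <- function(x, ...) {
  if (length(x) == 0) {
    cat("<rm_set> {}\n")
  } else {
    cat("<rm_set> {", paste(unclass(x), collapse = ", "), "}\n")
  }
  invisible(x)
}

as_rm_set <- function(x) {
  if (inherits(x, "rm_set")) x else rm_set(x)
}

#' Cardinality, difference and intersection of RM sets
#'
#' Thin set-algebra helpers used by the infection-coefficient machinery.
#' `rm_size` is `|b|`, `rm_diff` is `b \ p` and `rm_intersect` is the set of
#' RM systems shared between a host complement and a virion methylation
#' pattern.
#'
#' @param x,y `rm_set` objects (or character vectors, coerced).
#' @return `rm_size`: a count; `rm_diff`, `rm_intersect`: `rm_set` objects.
#' @export
rm_size <- function(x) length(as_rm_set(x))

#' @rdname rm_size
#' @export
rm_diff <- function(x, y) rm_set(setdiff(as_rm_set(x), as_rm_set(y)))

#' @rdname rm_size
#' @export
rm_intersect <- function(x, y) rm_set(intersect(as_rm_set(x), as_rm_set(y)))

#' Total nutrient-utilization cost of a host's RM complement
#'
#' RM systems are assumed to carry identical, linearly additive costs: each
#' system removes a fixed fraction `per_rm_cost` of the host's nutrient
#' utilization, so a host with `|b|` systems pays `c = per_rm_cost * |b|` and
#' grows at rate `alpha * (1 - c) * N`. A total cost of 1 or more would mean
#' zero or negative utilization and is rejected as a configuration error
#' rather than clamped.
#'
#' @param rm_set an [rm_set()] (or character vector) of RM identifiers.
#' @param per_rm_cost dimensionless fraction in `[0, 1)` paid per RM system.
#' @return The total cost `c`, a fraction in `[0, 1)`.
#' @examples
#' total_cost(rm_set("A"), 0.05)       # 0.05
#' total_cost(rm_set("A", "B"), 0.05)  # 0.10
#' @export
total_cost <- function(rm_set, per_rm_cost) {
  stopifnot(is.numeric(per_rm_cost), length(per_rm_cost) == 1L)
  if (per_rm_cost < 0) stop("per_rm_cost must be >= 0")
  cost <- per_rm_cost * rm_size(rm_set)
  if (cost >= 1) {
    stop("total RM cost must be < 1 (got ", format(cost),
         " for ", rm_size(rm_set), " systems at ", per_rm_cost, " each)")
  }
  cost
}

#' Susceptibility of a defended host to unmethylated phage
#'
#' Each RM system independently reduces the probability that an infecting,
#' unmethylated phage genome escapes restriction, so protection multiplies
#' across systems: a host carrying the set `b` is infected at
#' `gamma = r_e^-|b|` times the baseline rate, where `r_e >= 1` is the
#' fold-resistance conferred by a single endonuclease.
#'
#' @param b host RM set ([rm_set()] or character vector).
#' @param r_e fold-resistance per RM system (dimensionless, `>= 1`).
#' @return Susceptibility coefficient in `(0, 1]`.
#' @examples
#' gamma_coefficient(rm_set(), 100)          # 1: undefended
#' gamma_coefficient(rm_set("A"), 100)       # 0.01
#' gamma_coefficient(rm_set("A", "B"), 100)  # 1e-4
#' @export
gamma_coefficient <- function(b, r_e) {
  stopifnot(is.numeric(r_e), length(r_e) == 1L)
  if (r_e < 1) stop("r_e must be >= 1")
  r_e^(-rm_size(b))
}

#' Host-by-phage susceptibility matrix with virion methylation memory
#'
#' In the memory model a virion released from host `j` carries that host's
#' methylation pattern `p_j`. When it next infects host `i`, only the host RM
#' systems whose motifs are unmethylated on the virion genome restrict at
#' full strength; systems shared between `b_i` and `p_j` restrict only the
#' unmethylated fraction `1 - m_v` of sites. The susceptibility of host `i`
#' to phage `j` is therefore
#' \deqn{\Gamma_{ij} = r_e^{-(|b_i \setminus p_j| + (1 - m_v)\,|b_i \cap p_j|)}}
#' With `m_v = 0` (no methylation carried over) every column reduces to
#' [gamma_coefficient()], i.e. the general model; with `m_v = 1` a phage is
#' fully immune to the RM systems of its last host.
#'
#' @param host_sets list of host RM sets (`b_i`).
#' @param phage_sets list of virion methylation sets (`p_j`).
#' @param r_e fold-resistance per RM system (`>= 1`).
#' @param m_v virion methylation in `[0, 1]`: fraction of restriction sites in
#'   progeny virions carrying the host's methylation.
#' @return Numeric matrix with `length(host_sets)` rows and
#'   `length(phage_sets)` columns, entries in `(0, 1]`.
#' @examples
#' gamma_matrix(list(rm_set("A", "B")), list(rm_set("A")), r_e = 100, m_v = 1)
#' @export
gamma_matrix <- function(host_sets, phage_sets, r_e, m_v) {
  stopifnot(is.list(host_sets), is.list(phage_sets))
  if (r_e < 1) stop("r_e must be >= 1")
  if (m_v < 0 || m_v > 1) stop("m_v must be in [0, 1]")
  host_sets <- lapply(host_sets, as_rm_set)
  phage_sets <- lapply(phage_sets, as_rm_set)
  G <- matrix(NA_real_, nrow = length(host_sets), ncol = length(phage_sets))
  for (i in seq_along(host_sets)) {
    for (j in seq_along(phage_sets)) {
      b <- host_sets[[i]]
      p <- phage_sets[[j]]
      expo <- rm_size(rm_diff(b, p)) + (1 - m_v) * rm_size(rm_intersect(b, p))
      G[i, j] <- r_e^(-expo)
    }
  }
  G
}
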