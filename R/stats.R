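#' Aggregate an isolate table to genus level
#'
#' Overrepresented taxa would otherwise dominate prokaryote-wide summaries,
#' so RM counts are averaged within each genus before any distribution
#' statistic is computed.
#'
#' @param isolates data frame with columns `assembly_id`, `genus`,
#'   `genome_size` (bp) and one or more count columns (default `rm_total`,
#'   `rm_total_no_iig`); a `phylum` column is carried through if present.
#' @param response count column to summarize as `mean_rmpg`.
#' @return A data frame with columns `genus`, `n_isolates`, `mean_rmpg`,
#'   `sd_rmpg`, `mean_genome_size` (bp) and, if available, `phylum`.
#' @export
aggregate_genus <- function(isolates, response = "rm_total") {
  req <- c("genus", "genome_size", response)
  if (!all(req %in% names(isolates))) {
    stop("isolate table lacks column(s): ",
         paste(setdiff(req, names(isolates)), collapse = ", "))
  }
  if (nrow(isolates) == 0) stop("empty isolate table")
  g <- factor(isolates$genus)
  out <- data.frame(
    genus = levels(g),
    n_isolates = as.integer(tabulate(g)),
    mean_rmpg = as.numeric(tapply(isolates[[response]], g, mean)),
    sd_rmpg = as.numeric(tapply(isolates[[response]], g, stats::sd)),
    mean_genome_size = as.numeric(tapply(isolates$genome_size, g, mean)),
    phylum = if ("phylum" %in% names(isolates)) {
      as.character(tapply(isolates$phylum, g, `[`, 1L))
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Distribution summary of genus-mean RM counts
#'
#' @param genus_table a table from [aggregate_genus()] (columns `genus`,
#'   `n_isolates`, `mean_rmpg`).
#' @param min_isolates keep only genera with at least this many sequenced
#'   isolates.
#' @return A list with `mean`, `median`, `q05`, `q95` and `n_genera`.
#'   Quantiles use linear interpolation of order statistics
#'   (`stats::quantile` type 7).
#' @export
summarize_rmpg <- function(genus_table, min_isolates = 1) {
  stopifnot(min_isolates >= 1)
  keep <- genus_table$n_isolates >= min_isolates
  if (!any(keep)) stop("no genera left after the n_isolates filter")
  x <- genus_table$mean_rmpg[keep]
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(mean = mean(x), median = q[2], q05 = q[1], q95 = q[3],
       n_genera = sum(keep))
}

#' Regress genus-mean RM counts on genome size
#'
#' Fits RM systems per genome against mean genome size in Mbp, either by
#' ordinary least squares (`kind = "linear"`) or by negative-binomial
#' regression with a log link (`kind = "negbin"`). Genus means are
#' non-integer, so the default NB fit maximizes the negative-binomial
#' log-likelihood in its gamma-function (continuous pseudo-count) form
#' directly; `nb_response = "round"` instead rounds the response and uses
#' `MASS::glm.nb`. Fit quality is R-squared (linear) or McFadden
#' pseudo-R-squared, `1 - logLik(fit)/logLik(intercept-only)` (NB).
#'
#' @param genus_table a table from [aggregate_genus()].
#' @param kind `"linear"` or `"negbin"`.
#' @param min_isolates genus inclusion filter, as in [summarize_rmpg()].
#' @param nb_response `"continuous"` (default) or `"round"`.
#' @return An object of class `rmpg_fit` with components `kind`,
#'   `coefficients` (intercept and slope per Mbp), `r_squared` or
#'   `pseudo_r_squared`, `p_value` (two-sided, for the slope), `dispersion`
#'   (NB), `logLik`, `n`, and the filtered data.
#' @examples
#' gt <- data.frame(genus = letters[1:6], n_isolates = 5,
#'                  mean_rmpg = c(1, 2, 2, 3, 3, 4),
#'                  mean_genome_size = c(2, 3, 4, 5, 6, 7) * 1e6)
#' fit <- rmpg_fit(gt, kind = "linear")
#' coef(fit)
#' @export
rmpg_fit <- function(genus_table, kind = c("linear", "negbin"),
                     min_isolates = 1, nb_response = c("continuous", "round")) {
  kind <- match.arg(kind)
  nb_response <- match.arg(nb_response)
  keep <- genus_table$n_isolates >= min_isolates
  d <- genus_table[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 genera to fit")
  x <- d$mean_genome_size / 1e6   # Mbp
  y <- d$mean_rmpg
  if (stats::sd(x) == 0) stop("degenerate (constant) genome-size predictor")
  if (kind == "linear") {
    lmfit <- stats::lm(y ~ x)
    sm <- summary(lmfit)
    out <- list(kind = "linear",
                coefficients = c(intercept = unname(stats::coef(lmfit)[1]),
                                 slope = unname(stats::coef(lmfit)[2])),
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4],
                logLik = as.numeric(stats::logLik(lmfit)),
                n = length(y), data = d, lm = lmfit)
  } else if (nb_response == "round") {
    yr <- round(y)
    nb <- MASS::glm.nb(yr ~ x)
    nb0 <- MASS::glm.nb(yr ~ 1)
    sm <- summary(nb)
    out <- list(kind = "negbin",
                coefficients = c(intercept = unname(stats::coef(nb)[1]),
                                 slope = unname(stats::coef(nb)[2])),
                pseudo_r_squared = 1 - as.numeric(stats::logLik(nb)) /
                  as.numeric(stats::logLik(nb0)),
                p_value = sm$coefficients[2, 4],
                dispersion = nb$theta,
                logLik = as.numeric(stats::logLik(nb)),
                n = length(y), data = d, nb_response = "round")
  } else {
    fit <- nb_continuous_ml(x, y)
    fit0 <- nb_continuous_ml(x * 0, y)   # intercept-only
    out <- list(kind = "negbin",
                coefficients = c(intercept = fit$par[1], slope = fit$par[2]),
                pseudo_r_squared = 1 - fit$logLik / fit0$logLik,
                p_value = fit$p_slope,
                dispersion = fit$theta,
                logLik = fit$logLik,
                n = length(y), data = d, nb_response = "continuous")
  }
  class(out) <- "rmpg_fit"
  out
}

# Negative-binomial log-likelihood with a log link, evaluated through the
# gamma function so non-integer responses are admissible:
#   l(y; mu, theta) = lgamma(y + theta) - lgamma(theta) - lgamma(y + 1)
#                     + theta log(theta/(theta+mu)) + y log(mu/(theta+mu))
nb_continuous_loglik <- function(b0, b1, log_theta, x, y) {
  theta <- exp(log_theta)
  mu <- exp(b0 + b1 * x)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

nb_continuous_ml <- function(x, y) {
  if (stats::sd(x) == 0) {
    # intercept-only fit (the null model of the pseudo-R-squared)
    negll0 <- function(par) -nb_continuous_loglik(par[1], 0, par[2], 0, y)
    opt <- stats::optim(c(log(mean(y) + 0.1), 0), negll0, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    return(list(par = c(opt$par[1], 0), theta = exp(opt$par[2]),
                logLik = -opt$value, se_slope = NA_real_,
                p_slope = NA_real_))
  }
  # start from a log-linear least-squares fit
  start_lm <- stats::lm(log(y + 0.5) ~ x)
  start <- c(stats::coef(start_lm), log_theta = 0)
  negll <- function(par) -nb_continuous_loglik(par[1], par[2], par[3], x, y)
  opt <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("negative-binomial fit did not converge (optim code ",
         opt$convergence, ")")
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se_slope <- if (is.null(vc)) NA_real_ else sqrt(max(vc[2, 2], 0))
  z <- opt$par[2] / se_slope
  list(par = unname(opt$par[1:2]), theta = exp(opt$par[3]),
       logLik = -opt$value, se_slope = se_slope,
       p_slope = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.rmpg_fit <- function(x, ...) {
  cat("RM-per-genome vs genome-size regression (", x$kind, ")\n", sep = "")
  cat(sprintf("  n genera = %d\n", x$n))
  cat(sprintf("  intercept = %.5g, slope = %.5g per Mbp\n",
              x$coefficients["intercept"], x$coefficients["slope"]))
  if (x$kind == "linear") {
    cat(sprintf("  R^2 = %.4g, slope p = %.3g\n", x$r_squared, x$p_value))
  } else {
    cat(sprintf("  McFadden pseudo-R^2 = %.4g, slope p = %.3g, theta = %.4g\n",
                x$pseudo_r_squared, x$p_value, x$dispersion))
  }
  invisible(x)
}

#' @export
summary.rmpg_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood = %.4f\n", object$logLik))
  cat(sprintf("  genome size to gain one RM from a 2-Mbp baseline: %.2f Mbp\n",
              delta_size_for_one_rm(object, baseline_size = 2)))
  invisible(object)
}

#' @export
coef.rmpg_fit <- function(object, ...) object$coefficients

#' @export
logLik.rmpg_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$kind == "linear") 3 else 3,
            class = "logLik")
}

#' @export
predict.rmpg_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$mean_genome_size / 1e6
  } else if (is.data.frame(newdata)) {
    newdata$mean_genome_size / 1e6
  } else {
    as.numeric(newdata)   # genome sizes already in Mbp
  }
  eta <- object$coefficients["intercept"] + object$coefficients["slope"] * x
  unname(if (object$kind == "negbin") exp(eta) else eta)
}

#' @export
residuals.rmpg_fit <- function(object, ...) {
  object$data$mean_rmpg - predict(object)
}

#' Genome expansion needed to gain one RM system
#'
#' How much larger would a genome of `baseline_size` Mbp have to grow for
#' the fitted expectation to rise by one RM system? For a linear fit this is
#' `1 / slope`, independent of the baseline; for a log-link NB fit it solves
#' `exp(a + b (x + delta)) = exp(a + b x) + 1`.
#'
#' @param fit an [rmpg_fit()] object, or a bare numeric slope (treated as a
#'   linear fit's slope per Mbp).
#' @param baseline_size starting genome size in Mbp (NB only).
#' @return Genome expansion in Mbp.
#' @examples
#' delta_size_for_one_rm(0.145)       # 1 / 0.145 = 6.90 Mbp
#' @export
delta_size_for_one_rm <- function(fit, baseline_size = 2) {
  stopifnot(baseline_size > 0)
  if (is.numeric(fit)) {
    slope <- fit
    kind <- "linear"
  } else {
    stopifnot(inherits(fit, "rmpg_fit"))
    slope <- unname(fit$coefficients["slope"])
    kind <- fit$kind
  }
  if (slope <= 0) stop("non-positive slope: gaining an RM is not reachable")
  if (kind == "linear") {
    1 / slope
  } else {
    a <- unname(fit$coefficients["intercept"])
    eta <- a + slope * baseline_size
    (log(exp(eta) + 1) - eta) / slope
  }
}

#' Wilcoxon rank-sum (Mann-Whitney) test with exact tied enumeration
#'
#' Two-sided rank-sum test using midranks for ties. For small samples
#' (`n_a + n_b <= 20`) the null distribution of the Mann-Whitney U statistic
#' is enumerated exactly over all group assignments, which remains valid
#' under ties; larger samples use the normal approximation with tie-corrected
#' variance and continuity correction (matching `stats::wilcox.test`).
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return A list with `statistic` (U for `group_a`) and `p_value`.
#' @examples
#' rank_sum_test(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value  # 2/70, exact
#' @export
rank_sum_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))   # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= 20) {
    idx <- utils::combn(n, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    mid <- na * nb / 2
    # permutation distribution of U is symmetric about n_a n_b / 2
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - na * nb / 2
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p_value = p)
}
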