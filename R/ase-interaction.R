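# Sex-interacting allele-specific expression QTL test.
#
# Model, per gene: for individual i with aggregated transcribed-site counts
# (alt_i out of n_i), phased regulatory contrast h_i in {-1,0,+1} and sex s_i,
#   alt_i ~ Binomial(n_i, logistic(alpha + gamma*h_i + delta*h_i*s_i + u_i)),
#   u_i ~ N(0, tau^2).
# The random intercept absorbs individual-level allelic-ratio shifts
# (mapping bias, cis background). The likelihood integrates u_i by adaptive
# Gauss-Hermite quadrature (integrand re-centered at its per-individual
# mode); the sex-interaction test is a likelihood-ratio test of delta = 0
# against chi-square(1).

gauss_hermite <- function(n) {
  # Golub-Welsch: nodes/weights for integral of f(x) exp(-x^2)
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = sqrt(pi) * eg$vectors[1, ]^2)
}

#' Aggregate ASE sites within gene x individual
#'
#' Sums ref/alt counts across transcribed sites for each (individual, gene)
#' unit and drops units with total read depth below `min_total`.
#'
#' @param ase an [ase_table].
#' @param min_total minimum total reads per unit (default 10).
#' @return data.frame per kept unit: `gene_id`, `individual`, `ref`, `alt`,
#'   `n`, `h`, `sex`; attribute `n_dropped` counts discarded units.
#' @export
aggregate_sites <- function(ase, min_total = 10) {
  if (!nrow(ase)) {
    out <- data.frame(gene_id = character(0), individual = character(0),
                      ref = integer(0), alt = integer(0), n = integer(0),
                      h = integer(0), sex = integer(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  key <- interaction(ase$gene_id, ase$individual, drop = TRUE)
  agg <- data.frame(
    gene_id = tapply(as.character(ase$gene_id), key, `[`, 1),
    individual = tapply(as.character(ase$individual), key, `[`, 1),
    ref = as.integer(tapply(ase$ref_count, key, sum)),
    alt = as.integer(tapply(ase$alt_count, key, sum)),
    h = as.integer(tapply(ase$h, key, `[`, 1)),
    sex = as.integer(tapply(ase$sex, key, `[`, 1)),
    stringsAsFactors = FALSE)
  agg$n <- agg$ref + agg$alt
  keep <- agg$n >= min_total
  out <- agg[keep, c("gene_id", "individual", "ref", "alt", "n", "h", "sex")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Marginal log-likelihood: one aggregated binomial observation per
# individual, random intercept integrated by adaptive GH quadrature.
ase_loglik <- function(theta, k, n, h, s, gh, family, tau_fixed = NULL) {
  alpha <- theta[1]; gamma <- theta[2]; delta <- theta[3]
  tau <- if (is.null(tau_fixed)) exp(theta[4]) else tau_fixed
  rho <- if (family == "betabinomial") stats::plogis(theta[length(theta)]) else 0
  eta0 <- alpha + gamma * h + delta * h * s
  cond_ll <- function(eta) {
    p <- stats::plogis(eta)
    if (family == "betabinomial" && rho > 1e-10) {
      a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
      lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
    } else {
      stats::dbinom(k, n, p, log = TRUE)
    }
  }
  if (tau < 1e-8) return(sum(cond_ll(eta0)))
  # per-individual mode and curvature of log integrand (Newton, vectorized)
  u <- rep(0, length(k))
  for (it in 1:15) {
    p <- stats::plogis(eta0 + u)
    g1 <- (k - n * p) - u / tau^2
    g2 <- -n * p * (1 - p) - 1 / tau^2
    step <- g1 / g2
    u <- u - pmax(pmin(step, 2), -2)
    if (max(abs(step)) < 1e-9) break
  }
  p <- stats::plogis(eta0 + u)
  sigma <- 1 / sqrt(n * p * (1 - p) + 1 / tau^2)
  # adaptive GH: integral of exp(cond_ll(u) + log dnorm(u;0,tau)) du
  ll_i <- rep(-Inf, length(k))
  M <- matrix(NA_real_, length(k), length(gh$nodes))
  for (j in seq_along(gh$nodes)) {
    uj <- u + sqrt(2) * sigma * gh$nodes[j]
    M[, j] <- cond_ll(eta0 + uj) + stats::dnorm(uj, 0, tau, log = TRUE) +
      gh$nodes[j]^2 + log(gh$weights[j]) + 0.5 * log(2) + log(sigma)
  }
  mx <- apply(M, 1, max)
  sum(mx + log(rowSums(exp(M - mx))))
}

fit_ase_optim <- function(k, n, h, s, gh, family, null_delta = FALSE,
                          tau_fixed = NULL) {
  # starting values from a plain logistic fit
  X <- if (null_delta) cbind(1, h) else cbind(1, h, h * s)
  glm0 <- suppressWarnings(stats::glm.fit(X, cbind(k, n - k),
                                          family = stats::binomial()))
  start_fe <- stats::coef(glm0)
  mk_theta <- function(fe, ltau) {
    th <- c(fe[1], fe[2], if (null_delta) 0 else fe[3])
    if (is.null(tau_fixed)) th <- c(th, ltau)
    if (family == "betabinomial") th <- c(th, -2)
    th
  }
  obj <- function(th) {
    full <- th
    if (null_delta) {
      # drop delta from the optimized vector
      full <- c(th[1], th[2], 0, th[-(1:2)])
    }
    -ase_loglik(full, k, n, h, s, gh, family, tau_fixed)
  }
  strip <- function(th) if (null_delta) th[-3] else th
  best <- NULL
  # warm glm start usually suffices; extra tau starts only on failure
  for (ltau0 in c(log(0.3), log(0.05), log(1))) {
    init <- strip(mk_theta(start_fe, ltau0))
    fit <- try(stats::optim(init, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$convergence == 0) { best <- fit; break }
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value - 1e-9)) best <- fit
    if (!is.null(tau_fixed)) break
  }
  if (is.null(best)) return(NULL)
  th <- if (null_delta) c(best$par[1], best$par[2], 0, best$par[-(1:2)]) else best$par
  th <- unname(th)
  list(alpha = th[1], gamma = th[2], delta = th[3],
       tau = if (is.null(tau_fixed)) exp(th[4]) else tau_fixed,
       loglik = -best$value, converged = best$convergence == 0)
}

#' Fit the sex-interacting ASE GLMM for one gene
#'
#' @param units aggregated units for one gene (see [aggregate_sites]);
#'   needs columns `alt`, `n`, `h`, `sex`. Units with `h = 0` contribute to
#'   the baseline and overdispersion only.
#' @param nodes number of Gauss-Hermite quadrature nodes (>= 9).
#' @param family `"binomial"` or `"betabinomial"` (adds an overdispersion
#'   parameter to the conditional likelihood).
#' @param tau_fixed fix the random-intercept SD (e.g. 0 reduces the model to
#'   a logistic regression); NULL (default) estimates it.
#' @param min_per_sex minimum informative (`h != 0`) individuals per sex.
#' @return list: estimates `alpha`, `gamma`, `delta`, `tau`, log-likelihoods,
#'   `lrt` statistic and `p` for delta = 0, `converged`. Non-convergence
#'   yields NA estimates with `converged = FALSE`.
#' @export
fit_ase_glmm <- function(units, nodes = 9, family = c("binomial", "betabinomial"),
                         tau_fixed = NULL, min_per_sex = 5) {
  family <- match.arg(family)
  stopifnot(nodes >= 9)
  inf <- units$h != 0
  if (sum(inf & units$sex == 0) < min_per_sex ||
      sum(inf & units$sex == 1) < min_per_sex)
    stop("need >= ", min_per_sex, " informative individuals per sex")
  gh <- gauss_hermite(nodes)
  k <- units$alt; n <- units$n; h <- units$h; s <- units$sex
  full <- fit_ase_optim(k, n, h, s, gh, family, FALSE, tau_fixed)
  red <- fit_ase_optim(k, n, h, s, gh, family, TRUE, tau_fixed)
  if (is.null(full) || is.null(red) || !full$converged || !red$converged)
    return(list(alpha = NA_real_, gamma = NA_real_, delta = NA_real_,
                tau = NA_real_, loglik = NA_real_, loglik0 = NA_real_,
                lrt = NA_real_, p = NA_real_, converged = FALSE))
  lrt <- max(0, 2 * (full$loglik - red$loglik))
  list(alpha = full$alpha, gamma = full$gamma, delta = full$delta,
       tau = full$tau, loglik = full$loglik, loglik0 = red$loglik,
       lrt = lrt, p = stats::pchisq(lrt, 1, lower.tail = FALSE),
       converged = TRUE)
}

#' Sex-interacting aseQTL scan across genes
#'
#' @param ase an [ase_table].
#' @param min_total read-depth filter for [aggregate_sites].
#' @inheritParams fit_ase_glmm
#' @return data.frame per testable gene with the GLMM estimates, LRT p and
#'   BH q.
#' @export
ase_scan <- function(ase, min_total = 10, nodes = 9, family = "binomial",
                     min_per_sex = 5) {
  agg <- aggregate_sites(ase, min_total)
  out <- list()
  for (gid in unique(agg$gene_id)) {
    u <- agg[agg$gene_id == gid, , drop = FALSE]
    inf <- u$h != 0
    if (sum(inf & u$sex == 0) < min_per_sex ||
        sum(inf & u$sex == 1) < min_per_sex) next
    f <- fit_ase_glmm(u, nodes, family, min_per_sex = min_per_sex)
    out[[gid]] <- data.frame(gene_id = gid, n_units = nrow(u),
                             alpha = f$alpha, gamma = f$gamma,
                             delta = f$delta, tau = f$tau, lrt = f$lrt,
                             p = f$p, converged = f$converged,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(NULL)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}
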