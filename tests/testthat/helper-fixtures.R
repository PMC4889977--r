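# Shared fixtures and independent oracles, built in code at test time.

# --- brute-force enumeration oracles ------------------------------------

# Two-sided Fisher p by direct table enumeration (probability mass <=
# observed, with the standard floating-point tie guard).
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  obs <- probs[(lo:hi) == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Two-sided exact binomial p by outcome enumeration.
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  probs <- vapply(0:n, function(x) {
    exp(lchoose(n, x) + x * log(p0) + (n - x) * log1p(-p0))
  }, numeric(1))
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# Conditional NB exact test p by naive (non-log-space) enumeration of all
# splits of the total, mirroring the conditioned-sum construction.
oracle_nb_exact <- function(ka, ks, sf, groups, alpha) {
  glev <- sort(unique(groups))
  s1 <- sf[groups == glev[1]]; s2 <- sf[groups == glev[2]]
  qhat <- ks / sum(sf)
  mom <- function(s) {
    mu <- qhat * sum(s)
    v <- sum(s * qhat + alpha * (s * qhat)^2)
    if (v > mu * (1 + 1e-8)) list(mu = mu, size = mu^2 / (v - mu)) else
      list(mu = mu, size = Inf)
  }
  A <- mom(s1); B <- mom(s2)
  dens <- function(x, m) {
    if (is.finite(m$size)) dnbinom(x, mu = m$mu, size = m$size) else
      dpois(x, m$mu)
  }
  probs <- dens(0:ks, A) * dens(ks - (0:ks), B)
  obs <- probs[ka + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]) / sum(probs))
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  r <- y - X %*% beta
  s2 <- sum(r^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = drop(beta), se = se)
}

# --- small simulated data builders --------------------------------------

tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(n_male = 40, n_female = 80, n_genes_auto = 8, n_genes_x = 4,
                   variants_per_gene = 3,
                   ase = list(n_genes = 3, n_het_per_sex = 10, lambda = 50,
                              gamma_sd = 0.3, delta_prop = 0.3, delta = 0.8,
                              tau = 0.2),
                   peaks = list(n_background = 30, n_per_sex = 5, lfc = 1.5,
                                sex_specific_prop = 0.1, link_prop = 0.3,
                                base_log_mean = log(100), lib_sd = 0.2),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

sim_ase_units <- function(n_per_sex, gamma, delta, tau, lambda = 50,
                          alpha = 0) {
  n <- 2 * n_per_sex
  sex <- rep(c(0L, 1L), each = n_per_sex)
  h <- sample(c(-1L, 1L), n, TRUE)
  tot <- stats::rpois(n, lambda) + 1L
  p <- stats::plogis(alpha + gamma * h + delta * h * sex +
                       stats::rnorm(n, 0, tau))
  alt <- stats::rbinom(n, tot, p)
  data.frame(individual = sprintf("i%03d", seq_len(n)), gene_id = "g",
             ref = tot - alt, alt = alt, n = tot, h = h, sex = sex,
             stringsAsFactors = FALSE)
}

is_x_rows <- function(g) g$chrom %in% c(g$x_chrom, "X", "chrX")
gene_start_site <- sexqtl:::gene_start_site

# genotype matrix from explicit dosage rows
gm_from <- function(dosage, chrom, pos, sex, x_coding = "full_dosage") {
  si <- sample_info(sprintf("s%02d", seq_along(sex)), sex)
  genotype_matrix(dosage, chrom, pos, si, x_coding)
}
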