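# shared fixtures: small simulated trials and closed-form oracles

# trait used for parameter-recovery experiments: sigma_g^2 = 1,
# sigma_ge^2 = 0.5, sigma_e^2 = 2 at the trial scale (67 genotypes,
# 8 environments, 2 reps)
recovery_trait <- function(sensitivity_sd = 0, missing_rate = 0) {
  trait_spec("y", mu = 10, var_g = 1, var_ge = 0.5, var_rep_env = 0.2,
             var_e = 2, env_effect_sd = 2, sensitivity_sd = sensitivity_sd,
             missing_rate = missing_rate)
}

recovery_sim <- function(seed, ...) {
  simulate_met(sim_config(seed = seed, traits = list(y = recovery_trait(...))))
}

# balanced genotype x environment x replicate table, no design effects
balanced_ger <- function(seed, n_g = 15, n_e = 6, r = 3, mu = 10,
                         s2g = 1, s2e_env = 4, s2ge = 0.8, s2res = 1.5) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sqrt(s2g))
  E <- rnorm(n_e, 0, sqrt(s2e_env))
  ge <- matrix(rnorm(n_g * n_e, 0, sqrt(s2ge)), n_g, n_e)
  d <- expand.grid(genotype = sprintf("G%02d", 1:n_g),
                   environment = sprintf("E%d", 1:n_e),
                   rep = 1:r, stringsAsFactors = FALSE)
  i <- match(d$genotype, sprintf("G%02d", 1:n_g))
  j <- match(d$environment, sprintf("E%d", 1:n_e))
  d$y <- mu + g[i] + E[j] + ge[cbind(i, j)] + rnorm(nrow(d), 0, sqrt(s2res))
  d$set <- "S1"
  list(data = d, g = g, E = E, ge = ge)
}

# ANOVA method-of-moments components for the balanced two-way model
mom_components <- function(d) {
  n_g <- length(unique(d$genotype))
  n_e <- length(unique(d$environment))
  r <- length(unique(d$rep))
  mu <- mean(d$y)
  gm <- tapply(d$y, d$genotype, mean)
  em <- tapply(d$y, d$environment, mean)
  cm <- tapply(d$y, list(d$genotype, d$environment), mean)
  ss_g <- n_e * r * sum((gm - mu)^2)
  ss_e <- n_g * r * sum((em - mu)^2)
  ss_ge <- r * sum((cm - outer(gm - mu, em - mu, `+`) - mu)^2)
  ss_res <- sum((d$y - cm[cbind(d$genotype, d$environment)])^2)
  ms_g <- ss_g / (n_g - 1); ms_e <- ss_e / (n_e - 1)
  ms_ge <- ss_ge / ((n_g - 1) * (n_e - 1))
  ms_res <- ss_res / (n_g * n_e * (r - 1))
  c(genotype = (ms_g - ms_ge) / (n_e * r),
    environment = (ms_e - ms_ge) / (n_g * r),
    genotype_env = (ms_ge - ms_res) / r,
    residual = ms_res)
}

# random complete two-way table at the trial dimensions
random_table <- function(seed, n_g = 67, n_e = 8, positive = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n_g * n_e, mean = if (positive) 20 else 0, sd = 3),
              n_g, n_e,
              dimnames = list(sprintf("G%02d", 1:n_g), sprintf("E%d", 1:n_e)))
  two_way_table(X)
}

# purely additive table mu + g_i + e_j
additive_table <- function(seed, n_g = 10, n_e = 6, mu = 20) {
  set.seed(seed)
  g <- rnorm(n_g, 0, 2); e <- rnorm(n_e, 0, 3)
  X <- outer(g, e, `+`) + mu
  dimnames(X) <- list(sprintf("G%02d", 1:n_g), sprintf("E%d", 1:n_e))
  two_way_table(X)
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  scale <- max(abs(expected), 1e-10)
  testthat::expect_lt(max(abs(actual - expected)) / scale, tol)
}
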