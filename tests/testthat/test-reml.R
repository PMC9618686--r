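test_that("REML equals ANOVA method-of-moments on balanced complete data", {
  bal <- balanced_ger(seed = 2)
  mom <- mom_components(bal$data)
  fit <- fit_reml(bal$data,
                  spec = model_spec("y", fixed = character(0),
                                    random = c("genotype", "environment",
                                               "genotype_env")),
                  control = reml_control(tol = 1e-12))
  est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
  for (term in names(mom)) {
    expect_lt(abs(est[term] - mom[term]) / max(abs(mom[term]), 1), 1e-6)
  }
})

test_that("engine agrees with lme4 on an unbalanced trial fit", {
  skip_if_not_installed("lme4")
  sim <- recovery_sim(seed = 42, missing_rate = 0.08)
  fit <- fit_reml(sim$pheno, spec = model_spec("y", fixed = character(0)))
  d <- as.data.frame(sim$pheno)
  d <- d[!is.na(d$y), ]
  lf <- lme4::lmer(
    y ~ 1 + (1 | genotype) + (1 | environment) + (1 | environment:rep) +
      (1 | genotype:environment), data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
  expect_equal(est[["genotype"]], ref[["genotype"]], tolerance = 1e-4)
  expect_equal(est[["genotype_env"]], ref[["genotype:environment"]],
               tolerance = 1e-4)
  expect_equal(est[["residual"]], ref[["Residual"]], tolerance = 1e-4)
  # BLUPs from the mixed-model equations match lme4's conditional modes
  rr <- lme4::ranef(lf)$genotype
  expect_equal(fit$predictions$blup[match(rownames(rr),
                                          fit$predictions$genotype)],
               rr[["(Intercept)"]], tolerance = 1e-4)
})

test_that("null genotype variance pins at the boundary with zero BLUPs", {
  tr <- trait_spec("y", mu = 10, var_g = 0, var_ge = 0.5, var_rep_env = 0.2,
                   var_e = 2, env_effect_sd = 2)
  sim <- simulate_met(sim_config(seed = 8, traits = list(y = tr)))
  fit <- fit_reml(sim$pheno, trait = "y", control = reml_control(se = FALSE))
  vc <- fit$varcomp
  expect_true(vc$pinned[vc$term == "genotype"])
  expect_equal(vc$estimate[vc$term == "genotype"], 0)
  expect_lt(max(abs(fit$predictions$blup)), 1e-3)
})

test_that("EM warm-up log-likelihood trace is non-decreasing", {
  sim <- recovery_sim(seed = 13)
  fit <- fit_reml(sim$pheno, trait = "y",
                  control = reml_control(se = FALSE, em_iter = 12L))
  expect_gte(length(fit$loglik_trace), 12L)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$convergence)
})

test_that("BLUPs centre at zero and are shrunk below the genetic variance", {
  for (s in c(5, 6)) {
    sim <- recovery_sim(seed = s)
    fit <- fit_reml(sim$pheno, trait = "y",
                    control = reml_control(se = FALSE))
    b <- fit$predictions$blup
    expect_lt(abs(sum(b)) / max(sum(abs(b)), 1), 1e-6)
    expect_lt(var(b), fit$sigma2[["genotype"]])
    # reliabilities are proper fractions for an estimable design
    expect_true(all(fit$predictions$reliability > 0 &
                      fit$predictions$reliability < 1))
  }
})

test_that("variance components carry one-sided z-tests and %-explained", {
  sim <- recovery_sim(seed = 31)
  fit <- fit_reml(sim$pheno, trait = "y")
  vc <- fit$varcomp
  expect_equal(sum(vc$pct_explained), 100, tolerance = 1e-9)
  free <- !vc$pinned & !is.na(vc$SE)
  expect_true(all(vc$SE[free] > 0))
  expect_equal(vc$z[free], vc$estimate[free] / vc$SE[free])
  expect_equal(vc$p_value[free], 1 - pnorm(vc$z[free]))
  # genotype variance simulated well away from zero must be significant
  expect_lt(vc$p_value[vc$term == "genotype"], 0.01)
})

test_that("degenerate model inputs fail with informative errors", {
  sim <- recovery_sim(seed = 1)
  expect_error(fit_reml(sim$pheno, trait = "nope"), "not found")
  d <- as.data.frame(sim$pheno)
  d1 <- d[d$environment == "AG17", ]
  expect_error(fit_reml(d1, spec = model_spec("y", fixed = character(0))),
               "fewer than 2 levels")
  # duplicated covariate -> singular fixed design named in the error
  d$cov1 <- d$row; d$cov2 <- d$row
  expect_error(fit_reml(d, spec = model_spec("y", fixed = c("cov1", "cov2"),
                                             random = "genotype")),
               "singular.*cov2")
})
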