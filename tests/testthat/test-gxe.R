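test_that("Finlay-Wilkinson slopes behave at their null and average cases", {
  t0 <- additive_table(seed = 1)
  fw <- fit_fw(t0)
  # additive table: every genotype tracks the environment index exactly
  expect_equal(fw$genotypes$sensitivity, rep(1, nrow(t0)), tolerance = 1e-12)
  expect_equal(fw$genotypes$ms_dev, rep(0, nrow(t0)), tolerance = 1e-20)
  expect_equal(mean(fw$genotypes$sensitivity), 1, tolerance = 1e-12)

  # a genotype whose row equals the column means has slope 1, MSdev 0:
  # appending the column-mean row leaves the column means unchanged
  tr <- random_table(seed = 2, n_g = 14, n_e = 6)
  X <- rbind(unclass(tr), Gavg = colMeans(tr))
  fw2 <- fit_fw(two_way_table(X))
  i <- match("Gavg", fw2$genotypes$genotype)
  expect_equal(fw2$genotypes$sensitivity[i], 1, tolerance = 1e-10)
  expect_lt(fw2$genotypes$ms_dev[i], 1e-16)
  expect_error(fit_fw(two_way_table(X[, 1:2])), ">= 3 environments")
})

test_that("FW slopes are invariant to shifts, positive scaling, and standardisation", {
  t0 <- random_table(seed = 7, n_g = 25, n_e = 8)
  fw <- fit_fw(t0)
  shifted <- two_way_table(unclass(t0) + 13.7)
  scaled <- two_way_table(unclass(t0) * 2.5)
  expect_equal(fit_fw(shifted)$genotypes$sensitivity,
               fw$genotypes$sensitivity, tolerance = 1e-10)
  expect_equal(fit_fw(scaled)$genotypes$sensitivity,
               fw$genotypes$sensitivity, tolerance = 1e-10)
  std <- fit_fw(scale_table(t0))
  expect_equal(std$genotypes$sensitivity, fw$genotypes$sensitivity,
               tolerance = 1e-10)
  # MSdev rescales by 1/variance of the cells
  expect_equal(std$genotypes$ms_dev,
               fw$genotypes$ms_dev / sd(unclass(t0))^2, tolerance = 1e-10)
})

test_that("AMMI decomposition conserves and orders the interaction SS", {
  t0 <- random_table(seed = 11)
  am <- fit_ammi(t0, k_max = 3)
  pt_int <- sum((unclass(t0) - outer(rowMeans(t0) - mean(t0),
                                     colMeans(t0) - mean(t0), `+`) -
                   mean(t0))^2)
  expect_equal(sum(am$svalues^2), pt_int, tolerance = 1e-10)
  # symmetric scores: Gram matrix of genotype scores = diag(singular values)
  G <- crossprod(am$gen_scores)
  expect_lt(max(abs(G - diag(am$svalues))), 1e-8)
  # Gollob df: (n_g - 1) + (n_e - 1) - (2k - 1)
  expect_equal(am$anova$df[am$anova$term == "IPCA1"], 66 + 7 - 1)
  expect_equal(am$anova$df[am$anova$term == "IPCA2"], 66 + 7 - 3)
  # scores reconstruct the double-centred interaction at full rank
  k <- length(am$svalues)
  D_rec <- am$gen_scores[, 1:k] %*% t(am$env_scores[, 1:k])
  D <- unclass(t0) - outer(am$gen_effects, am$env_effects, `+`) - am$mu
  expect_lt(max(abs(D_rec - D)), 1e-8)
  expect_warning(fit_ammi(t0, k_max = 10), "truncated")
})

test_that("rank-1 interaction loads entirely on IPCA1", {
  t0 <- additive_table(seed = 4, n_g = 12, n_e = 6)
  set.seed(9)
  a <- rnorm(12); a <- a - mean(a)
  b <- rnorm(6); b <- b - mean(b)
  X <- unclass(t0) + 2 * outer(a, b)
  am <- fit_ammi(two_way_table(X))
  expect_equal(am$svalues[1]^2 / sum(am$svalues^2), 1, tolerance = 1e-10)
})

test_that("GGE absorbs the genotype main effect and conserves G+GE", {
  t0 <- random_table(seed = 13)
  gg <- fit_gge(t0)
  am <- fit_ammi(t0)
  Xc <- unclass(t0) - matrix(colMeans(t0), nrow(t0), ncol(t0), byrow = TRUE)
  expect_equal(sum(gg$svalues^2), sum(Xc^2), tolerance = 1e-10)
  # G+GE SS = AMMI genotype SS + interaction SS (algebraic identity)
  expect_equal(gg$ss_gge,
               am$anova$ss[am$anova$term == "genotype"] + am$ss_interaction,
               tolerance = 1e-8)
  # full-rank coordinates reconstruct the centred matrix
  k <- length(gg$svalues)
  expect_lt(max(abs(gg$gen_coords[, 1:k] %*% t(gg$env_coords[, 1:k]) - Xc)),
            1e-8)
  # environment-vector cosines are proper
  expect_equal(diag(gg$env_cosines), rep(1, ncol(t0)), ignore_attr = TRUE)
  expect_true(all(abs(gg$env_cosines) <= 1 + 1e-12))

  # null G+GE: no genotype effect, no interaction
  e <- rnorm(6)
  Xn <- matrix(e, 8, 6, byrow = TRUE,
               dimnames = list(paste0("g", 1:8), paste0("e", 1:6)))
  expect_lt(max(fit_gge(two_way_table(Xn))$svalues), 1e-10)
})

test_that("the three models partition one corrected total SS consistently", {
  t0 <- random_table(seed = 17)
  fw <- fit_fw(t0); am <- fit_ammi(t0); gg <- fit_gge(t0)
  ss <- function(f, term) f$anova$ss[f$anova$term == term]
  expect_equal(ss(fw, "environment"), ss(am, "environment"))
  expect_equal(ss(am, "environment"), ss(gg, "environment"))
  expect_equal(ss(fw, "genotype"), ss(am, "genotype"))
  # FW splits the same interaction SS that AMMI decomposes
  expect_equal(ss(fw, "sensitivity") + ss(fw, "residual"),
               am$ss_interaction, tolerance = 1e-10)
  for (f in list(fw, am, gg)) {
    p <- partition_tss(f)
    expect_equal(sum(p$pct_tss), 100, tolerance = 1e-6)
  }
  # additive table: all interaction shares vanish
  ta <- additive_table(seed = 19)
  pa <- partition_tss(fit_ammi(ta))
  expect_lt(sum(pa$pct_tss[grepl("IPCA|residual", pa$term)]), 1e-8)
})

test_that("environment winners lie on the GGE PC1-PC2 hull under crossover GEI", {
  # strong low-rank crossover interaction (spread of sensitivity slopes),
  # little residual noise, so PC1-PC2 capture the G+GE structure
  tr <- trait_spec("y", mu = 20, var_g = 1, var_ge = 0.02, var_rep_env = 0.1,
                   var_e = 0.2, env_effect_sd = 2, sensitivity_sd = 0.5)
  on_hull <- crossover <- logical(0)
  for (s in c(23, 24, 25)) {
    sim <- simulate_met(sim_config(seed = s, traits = list(y = tr)))
    tw <- complete_table(two_way_means(sim$pheno, "y"))
    gg <- fit_gge(tw)
    crossover <- c(crossover,
                   any(gg$gen_coords[, 1] > 0) && any(gg$gen_coords[, 1] < 0))
    win <- gge_winners(tw, gg)
    on_hull <- c(on_hull, win$winner_on_hull)
  }
  expect_true(all(crossover))
  expect_gte(mean(on_hull), 0.9)
})
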