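test_that("design skeleton matches the two-set trial layout", {
  cfg <- sim_config(seed = 3)
  des <- make_design(cfg)
  # 36 entries/set x 2 sets x 2 reps x 8 environments
  expect_equal(nrow(des), 36 * 2 * 2 * 8)
  expect_equal(length(unique(des$genotype)), 67L)
  # checks appear in both sets, lines in exactly one
  by_set <- table(unique(des[, c("genotype", "set")])$genotype)
  expect_equal(sum(by_set == 2L), 5L)
  expect_equal(sum(by_set == 1L), 62L)
  # (genotype, env, rep, set) unique; every genotype n_reps times per env
  expect_false(anyDuplicated(des[, c("genotype", "environment", "rep",
                                     "set")]) > 0)
  cnt <- table(des$genotype, des$environment)
  expect_true(all(cnt[rownames(cnt) %in% sprintf("CHK%d", 1:5), ] == 4L))
  expect_true(all(cnt[!rownames(cnt) %in% sprintf("CHK%d", 1:5), ] == 2L))
  # no plot coordinate reused within a set x rep x environment
  key <- with(des, paste(environment, set, rep, row, col))
  expect_false(anyDuplicated(key) > 0)
  # capacity check
  expect_error(sim_config(grid = c(5, 5)), "cannot hold")
})

test_that("simulation is reproducible and respects its seed", {
  a <- simulate_met(sim_config(seed = 11))
  b <- simulate_met(sim_config(seed = 11))
  expect_identical(as.data.frame(a$pheno), as.data.frame(b$pheno))
  c <- simulate_met(sim_config(seed = 12))
  expect_false(identical(a$pheno$gari_pct, c$pheno$gari_pct))
})

test_that("no-interaction, no-noise limit is exactly additive", {
  tr <- trait_spec("y", mu = 5, var_g = 1, var_ge = 0, var_rep_env = 0.3,
                   var_e = 0, env_effect_sd = 2, sensitivity_sd = 0)
  sim <- simulate_met(sim_config(seed = 4, traits = list(y = tr)))
  d <- as.data.frame(sim$pheno)
  cm <- tapply(d$y, list(d$genotype, d$environment), mean)
  D <- cm - outer(rowMeans(cm) - mean(cm), colMeans(cm) - mean(cm), `+`) -
    mean(cm)
  expect_lt(max(abs(D)), 1e-9)
})

test_that("all variances zero leaves only the mean plus fixed spatial trend", {
  tr <- trait_spec("y", mu = 7, var_g = 0, var_ge = 0, var_rep_env = 0,
                   var_e = 0, env_effect_sd = 0, sensitivity_sd = 0,
                   spatial_sd = 0.5)
  sim <- simulate_met(sim_config(seed = 9, traits = list(y = tr)))
  d <- as.data.frame(sim$pheno)
  tru <- sim$truth$traits$y
  se <- paste(d$set, d$environment, sep = ":")
  pred <- 7 + tru$spatial_row[se] * (d$row - mean(d$row)) +
    tru$spatial_col[se] * (d$col - mean(d$col))
  expect_equal(d$y, unname(pred), tolerance = 1e-12)
  # and with no trend either, y is identically mu
  tr0 <- trait_spec("y", mu = 7, var_g = 0, var_ge = 0, var_rep_env = 0,
                    var_e = 0, env_effect_sd = 0, spatial_sd = 0)
  sim0 <- simulate_met(sim_config(seed = 9, traits = list(y = tr0)))
  expect_equal(unique(sim0$pheno$y), 7)
})

test_that("genetic values hit their variance and correlation targets", {
  # 200 replicate draws of 500 genetic values; single tiny environment so
  # only the genetic sub-stream is exercised
  cfg_of <- function(seed) sim_config(
    n_genotypes = 500, n_checks = 0, environments = "E1", n_reps = 1,
    n_sets = 2, grid = c(16, 16), seed = seed,
    traits = list(a = trait_spec("a", var_g = 2, var_e = 0.01),
                  b = trait_spec("b", var_g = 1, var_e = 0.01)))
  R <- genetic_correlation(c("a", "b"), list(c("a", "b", 0.8)))
  vars <- cors <- numeric(200)
  for (s in seq_len(200)) {
    tt <- simulate_met(cfg_of(1000 + s), correlations = R)$truth$traits
    vars[s] <- var(tt$a$g)
    cors[s] <- cor(tt$a$g, tt$b$g)
  }
  # sampling SE of a variance at n=500: sqrt(2/(n-1)) * var = 0.127
  expect_lt(abs(mean(vars) - 2), 3 * sqrt(2 / 499) * 2 / sqrt(200))
  expect_lt(abs(mean(cors) - 0.8), 0.05)
  expect_lt(max(abs(cors - 0.8)), 0.15)
})

test_that("a non-repairable correlation matrix is rejected", {
  expect_error(genetic_correlation(c("a", "b", "c"),
                                   list(c("a", "b", 0.9), c("b", "c", 0.9),
                                        c("a", "c", -0.9))),
               "positive semidefinite")
  # mild violation is repaired
  R <- genetic_correlation(c("a", "b", "c"),
                           list(c("a", "b", 0.9), c("b", "c", 0.9),
                                c("a", "c", 0.65)))
  expect_true(all(eigen(R, symmetric = TRUE)$values > -1e-10))
})

test_that("raw-measure emission round-trips through derive_traits", {
  sim <- simulate_met(sim_config(seed = 21), emit_raw = TRUE)
  expect_false("gari_pct" %in% names(sim$pheno))
  der <- derive_traits(sim$pheno)
  sim2 <- simulate_met(sim_config(seed = 21), emit_raw = FALSE)
  ok <- !is.na(sim2$pheno$gari_pct)
  expect_equal(der$gari_pct[ok], sim2$pheno$gari_pct[ok], tolerance = 1e-12)
  ok <- !is.na(sim2$pheno$fyld)
  expect_equal(der$fyld[ok], sim2$pheno$fyld[ok], tolerance = 1e-12)
})
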