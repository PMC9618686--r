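test_that("deregressed-BLUP correlations are proper and self-consistent", {
  set.seed(61)
  g <- sprintf("G%02d", 1:30)
  pa <- data.frame(genotype = g, drblup = rnorm(30))
  pb <- data.frame(genotype = g, drblup = pa$drblup * 0.9 + rnorm(30, 0, 0.3))
  cm <- correlate_drblups(list(a = pa, b = pb, a2 = pa))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(cm$r["a", "a2"], 1)           # trait against itself
  expect_lt(cm$p["a", "b"], 1e-6)
  expect_equal(cm$n["a", "b"], 30)
  # below the minimum shared-genotype count the pair is reported missing
  pc <- data.frame(genotype = g[1:2], drblup = rnorm(2))
  cm2 <- correlate_drblups(list(a = pa, c = pc))
  expect_true(is.na(cm2$r["a", "c"]))
  expect_equal(cm2$n["a", "c"], 2)
})

test_that("independent traits yield near-null DRBLUP correlations", {
  # small trials, two uncorrelated traits; |r| should concentrate near 0
  rs <- sapply(1:25, function(s) {
    cfg <- sim_config(n_genotypes = 41, n_checks = 5,
                      environments = paste0("E", 1:4), grid = c(5, 5),
                      seed = 700 + s,
                      traits = list(a = recovery_trait(), b = recovery_trait()))
    sim <- simulate_met(cfg)
    pr <- lapply(c(a = "a", b = "b"), function(tr) {
      deregress(fit_reml(sim$pheno, spec = model_spec(tr, fixed = character(0)),
                         control = reml_control(se = FALSE, em_iter = 0L)))
    })
    correlate_drblups(pr)$r["a", "b"]
  })
  expect_lt(abs(mean(rs)), 0.12)
  expect_gte(mean(abs(rs) < 0.3), 0.8)
})

test_that("the pipeline writes a complete, reproducible output set", {
  cfg <- list(seed = 5,
              design = list(n_genotypes = 21, n_checks = 3, n_reps = 2,
                            n_sets = 2, grid = c(4, 3)),
              traits = list(
                gari_pct = list(mu = 19, var_g = 0.9, var_ge = 1.2,
                                var_rep_env = 0.2, var_e = 3,
                                env_effect_sd = 2, sensitivity_sd = 0.2,
                                missing_rate = 0.03),
                dm = list(mu = 37, var_g = 1.5, var_ge = 2, var_rep_env = 0.3,
                          var_e = 2, env_effect_sd = 2.2)),
              correlations = NULL, emit_raw = FALSE)
  out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
  res <- suppressMessages(run_pipeline(cfg, out1))
  files <- list.files(out1)
  for (f in c("pheno.csv", "heritability.csv", "drblup_correlations.csv",
              "manifest.json", "varcomp_gari_pct.csv", "varcomp_dm.csv",
              "predictions_gari_pct.csv", "gxe_tss_gari_pct.csv",
              "fw_genotypes_dm.csv", "gge_biplot_gari_pct.csv",
              "stability_dm.csv")) {
    expect_true(f %in% files, label = paste("missing output:", f))
  }
  h <- read.csv(file.path(out1, "heritability.csv"))
  expect_true(all(c("standard", "cullis") %in% h$method))
  expect_true(all(h$value <= 1 + 1e-9, na.rm = TRUE))

  # byte-identical rerun under the same seed and config
  suppressMessages(run_pipeline(cfg, out2))
  csvs <- grep("\\.csv$", files, value = TRUE)
  for (f in csvs) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("non-reproducible:", f))
  }
  expect_s3_class(res$stability$gari_pct, "stability_table")
  expect_equal(res$manifest$seed, 5)
})

test_that("config validation fails fast on unknown traits or entries", {
  expect_error(run_pipeline(list(analyze = "nope")), "unknown trait")
  expect_error(run_pipeline(list(bogus_knob = 1)), "unknown config entries")
  expect_error(run_pipeline(list(simulate = FALSE)), "pheno_csv")
})

test_that("YAML configs drive the pipeline", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9",
               "emit_raw: false",
               "design:",
               "  n_genotypes: 13",
               "  n_checks: 3",
               "  n_reps: 2",
               "  n_sets: 1",
               "  grid: [4, 4]",
               "traits:",
               "  dm:",
               "    mu: 37.0",
               "    var_g: 1.5",
               "    env_effect_sd: 2.0"), yml)
  out <- file.path(tempdir(), "run_yaml")
  res <- suppressMessages(run_pipeline(yml, out))
  expect_true(file.exists(file.path(out, "stability_dm.csv")))
  expect_equal(res$manifest$seed, 9)
})
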