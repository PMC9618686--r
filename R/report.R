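## Cross-trait correlations and the end-to-end pipeline -----------------------

#' Pearson correlations of deregressed BLUPs across traits
#'
#' Pairwise-complete Pearson correlations of per-genotype deregressed
#' BLUPs between traits, with two-sided t-tests (`df = n - 2`) and, as a
#' convenience for users, Bonferroni-adjusted p-values. Pairs with fewer
#' than `min_n` genotypes in common are reported missing.
#'
#' @param predictions named list (by trait) of prediction data.frames from
#'   [deregress()] (columns `genotype`, `drblup`).
#' @param min_n minimum shared genotypes per pair (default 3).
#' @return A `corr_matrix` list: `$r`, `$n`, `$t`, `$p`, `$p_bonferroni`
#'   (trait x trait matrices).
#' @export
correlate_drblups <- function(predictions, min_n = 3L) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  traits <- names(predictions)
  genos <- sort(unique(unlist(lapply(predictions, `[[`, "genotype"))))
  M <- matrix(NA_real_, length(genos), length(traits),
              dimnames = list(genos, traits))
  for (tr in traits) {
    p <- predictions[[tr]]
    M[p$genotype, tr] <- p$drblup
  }
  nt <- length(traits)
  r <- nmat <- tstat <- pval <- matrix(NA_real_, nt, nt,
                                       dimnames = list(traits, traits))
  diag(r) <- 1
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) { nmat[i, j] <- sum(!is.na(M[, i])); next }
      ok <- stats::complete.cases(M[, c(i, j)])
      nmat[i, j] <- sum(ok)
      if (sum(ok) >= min_n) {
        rr <- stats::cor(M[ok, i], M[ok, j])
        r[i, j] <- rr
        tt <- rr * sqrt((sum(ok) - 2) / max(1 - rr^2, 1e-12))
        tstat[i, j] <- tt
        pval[i, j] <- 2 * stats::pt(-abs(tt), df = sum(ok) - 2)
      }
    }
  }
  n_tests <- nt * (nt - 1) / 2
  structure(list(r = r, n = nmat, t = tstat, p = pval,
                 p_bonferroni = pmin(pval * n_tests, 1)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("deregressed-BLUP trait correlations:\n")
  print(round(x$r, 3))
  invisible(x)
}

default_pipeline_config <- function() {
  list(seed = 1L,
       simulate = TRUE,
       pheno_csv = NULL,
       emit_raw = TRUE,
       design = list(n_genotypes = 67L, n_checks = 5L, n_reps = 2L,
                     n_sets = 2L, grid = c(6L, 6L)),
       traits = NULL,        # NULL -> cassava_uyt_traits()
       correlations = NULL,  # NULL -> cassava_uyt_correlations()
       analyze = NULL,       # NULL -> all configured traits
       k_max = 2L, top_k = 5L, reliability_floor = 0.1)
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_cfg("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop_cfg("unknown config entries: %s",
                                paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  if (is.null(cfg$traits)) cfg$traits <- cassava_uyt_traits()
  if (is.list(cfg$traits) && !inherits(cfg$traits[[1]], "trait_spec")) {
    cfg$traits <- lapply(names(cfg$traits), function(nm) {
      do.call(trait_spec, c(list(name = nm), cfg$traits[[nm]]))
    })
    names(cfg$traits) <- vapply(cfg$traits, `[[`, "", "name")
  }
  if (is.null(cfg$correlations)) {
    cfg$correlations <- if (setequal(names(cfg$traits),
                                     names(cassava_uyt_traits()))) {
      cassava_uyt_correlations()
    } else NULL
  }
  if (is.null(cfg$analyze)) cfg$analyze <- names(cfg$traits)
  bad <- setdiff(cfg$analyze, names(cfg$traits))
  if (length(bad) && isTRUE(cfg$simulate)) {
    stop_cfg("analyze names unknown trait(s): %s", paste(bad, collapse = ", "))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) plot data, derive product traits, then for each
#' analysed trait: REML variance components with z-tests, both
#' heritability estimators, per-trial Cullis heritabilities, BLUPs and
#' deregressed BLUPs; cross-trait correlations of the deregressed BLUPs;
#' the genotype x environment BLUE table; Finlay-Wilkinson (on the scaled
#' table), AMMI and GGE fits with %TSS partitions and biplot coordinates;
#' and Wricke/GAI stability with the above-mean top-k selection. Every
#' table is written as CSV under `out_dir` together with a JSON run
#' manifest; a rerun with the same config and seed is bit-identical.
#'
#' @param config a config list, or path to a YAML/JSON file; see
#'   `validate_pipeline_config` entries (`seed`, `simulate`, `pheno_csv`,
#'   `design`, `traits`, `analyze`, `k_max`, `top_k`, ...). Defaults
#'   reproduce the trial conditions the generator emulates.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`pheno`, `truth`,
#'   `fits`, `heritability`, `correlations`, `two_way`, `gxe`,
#'   `stability`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("metgxe_run_")) {
  t0 <- Sys.time()
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); warns <- character(0)
  wh <- function(w) { warns <<- c(warns, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(withCallingHandlers(expr, warning = wh),
                    error = function(e) {
      stop_cfg("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    res
  }

  ## ingest or simulate
  truth <- NULL
  pheno <- stage("data", {
    if (isTRUE(cfg$simulate)) {
      sc <- do.call(sim_config, c(cfg$design,
                                  list(traits = cfg$traits,
                                       seed = cfg$seed)))
      sim <- simulate_met(sc, correlations = cfg$correlations,
                          emit_raw = isTRUE(cfg$emit_raw))
      truth <- sim$truth
      sim$pheno
    } else {
      if (is.null(cfg$pheno_csv)) stop("simulate=FALSE needs pheno_csv")
      read_pheno(cfg$pheno_csv)
    }
  })
  pheno <- stage("derive", derive_traits(pheno))
  write_table(pheno, file.path(out_dir, "pheno.csv"))

  traits <- intersect(cfg$analyze, trait_registry(pheno)$trait)
  if (!length(traits)) stop_cfg("no analyzable trait present after derivation")

  fits <- list(); herit <- list(); preds <- list()
  for (tr in traits) {
    fit <- stage(paste0("reml/", tr), fit_reml(pheno, trait = tr))
    fits[[tr]] <- fit
    e <- length(unique(pheno$environment))
    r <- max(pheno$rep)
    hs <- h2_standard(fit, e = e, r = r)
    hc <- h2_cullis(fit)
    htrial <- stage(paste0("trial_h2/", tr), per_trial_h2(pheno, tr))
    herit[[tr]] <- cbind(trait = tr, rbind(hs, hc, htrial))
    preds[[tr]] <- stage(paste0("deregress/", tr),
                         deregress(fit,
                                   reliability_floor = cfg$reliability_floor))
    vc <- fit$varcomp
    write_table(cbind(trait = tr, vc),
                file.path(out_dir, paste0("varcomp_", tr, ".csv")))
    write_table(cbind(trait = tr, preds[[tr]]),
                file.path(out_dir, paste0("predictions_", tr, ".csv")))
  }
  write_table(do.call(rbind, herit), file.path(out_dir, "heritability.csv"))

  corr <- stage("correlations", correlate_drblups(preds))
  write_table(corr$r, file.path(out_dir, "drblup_correlations.csv"))

  two_way <- list(); gxe <- list(); stab <- list()
  for (tr in traits) {
    tw <- stage(paste0("two_way/", tr), {
      complete_table(two_way_means(pheno, tr))
    })
    two_way[[tr]] <- tw
    fw <- stage(paste0("fw/", tr), fit_fw(scale_table(tw)))
    am <- stage(paste0("ammi/", tr), fit_ammi(tw, k_max = cfg$k_max))
    gg <- stage(paste0("gge/", tr), fit_gge(tw))
    gxe[[tr]] <- list(fw = fw, ammi = am, gge = gg)
    tss <- rbind(cbind(model = "FW", partition_tss(fw)),
                 cbind(model = "AMMI", partition_tss(am)),
                 cbind(model = "GGE", partition_tss(gg)))
    write_table(cbind(trait = tr, tss),
                file.path(out_dir, paste0("gxe_tss_", tr, ".csv")))
    write_table(cbind(trait = tr, fw$genotypes),
                file.path(out_dir, paste0("fw_genotypes_", tr, ".csv")))
    coords <- rbind(
      data.frame(mode = "genotype", label = rownames(gg$gen_coords),
                 PC1 = gg$gen_coords[, 1], PC2 = gg$gen_coords[, 2],
                 stringsAsFactors = FALSE),
      data.frame(mode = "environment", label = rownames(gg$env_coords),
                 PC1 = gg$env_coords[, 1], PC2 = gg$env_coords[, 2],
                 stringsAsFactors = FALSE))
    write_table(cbind(trait = tr, coords),
                file.path(out_dir, paste0("gge_biplot_", tr, ".csv")))
    st <- stage(paste0("stability/", tr), {
      s <- stability_table(tw)
      rank_and_select(s, "gai_top_k", k = cfg$top_k, above_mean = TRUE)
    })
    stab[[tr]] <- st
    write_table(cbind(trait = tr, as.data.frame(st)),
                file.path(out_dir, paste0("stability_", tr, ".csv")))
  }

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg),
                                           c("traits", "correlations"))],
                               auto_unbox = TRUE)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metgxe")),
    seed = cfg$seed,
    config_digest = unname(tools::md5sum(cfg_file)),
    input_digests = as.list(tools::md5sum(file.path(out_dir, "pheno.csv"))),
    traits = traits,
    stage_seconds = timings,
    warnings = warns,
    finished = format(t0, tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(pheno = pheno, truth = truth, fits = fits,
                 heritability = do.call(rbind, herit),
                 predictions = preds, correlations = corr,
                 two_way = two_way, gxe = gxe, stability = stab,
                 manifest = manifest, out_dir = out_dir))
}
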