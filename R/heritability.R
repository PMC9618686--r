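## Broad-sense heritability and deregressed BLUPs -----------------------------

vc_get <- function(vc, term) {
  if (inherits(vc, "reml_fit")) vc <- vc$varcomp
  i <- match(term, vc$term)
  if (is.na(i)) NA_real_ else vc$estimate[i]
}

#' Entry-mean (standard) broad-sense heritability
#'
#' `H2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2/e + sigma_e^2/(e r))` with `e`
#' environments and `r` replicates per environment.
#'
#' @param vc a `reml_fit` or its `$varcomp` table (terms `genotype`,
#'   `genotype_env`, `residual`).
#' @param e number of environments.
#' @param r number of replicates per environment.
#' @return data.frame row: method, scope, value, e, r.
#' @export
h2_standard <- function(vc, e, r) {
  stopifnot(e >= 1, r >= 1)
  s2g <- vc_get(vc, "genotype")
  s2ge <- vc_get(vc, "genotype_env")
  s2e <- vc_get(vc, "residual")
  if (is.na(s2ge)) s2ge <- 0
  denom <- s2g + s2ge / e + s2e / (e * r)
  value <- if (denom <= 0) {
    warning("all variance components are zero; heritability undefined",
            call. = FALSE)
    NA_real_
  } else s2g / denom
  data.frame(method = "standard", scope = "overall", value = value,
             e = e, r = r, vbar_delta = NA_real_,
             stringsAsFactors = FALSE)
}

#' Cullis broad-sense heritability
#'
#' `H2 = 1 - vbar_Delta / (2 sigma_g^2)`, with `vbar_Delta` the mean
#' variance of a difference of genotype BLUPs. The default computes the
#' exact mean over all genotype pairs of
#' `Var(BLUP_i - BLUP_j) = PEV_i + PEV_j - 2 Cov_ij` from the genotype
#' block of the inverse mixed-model coefficient matrix;
#' `method = "mean_pev"` uses the common approximation `2 mean(PEV)`
#' (which ignores BLUP covariances).
#'
#' @param fit a `reml_fit` with a random genotype term.
#' @param method `"pairwise"` (exact) or `"mean_pev"`.
#' @param scope label recorded in the output (e.g. an environment id).
#' @return data.frame row: method, scope, value, vbar_delta.
#' @export
h2_cullis <- function(fit, method = c("pairwise", "mean_pev"),
                      scope = "overall") {
  method <- match.arg(method)
  stopifnot(inherits(fit, "reml_fit"), !is.null(fit$vg_cov))
  s2g <- vc_get(fit, "genotype")
  if (is.na(s2g) || s2g <= 0) {
    warning("genotype variance is zero; Cullis heritability undefined",
            call. = FALSE)
    vbar <- NA_real_
    value <- NA_real_
  } else {
    V <- fit$vg_cov
    ng <- nrow(V)
    vbar <- if (method == "pairwise") {
      (ng * sum(diag(V)) - sum(V)) / (ng * (ng - 1) / 2)
    } else {
      2 * mean(diag(V))
    }
    value <- 1 - vbar / (2 * s2g)
  }
  data.frame(method = "cullis", scope = scope, value = value,
             e = NA_real_, r = NA_real_, vbar_delta = vbar,
             stringsAsFactors = FALSE)
}

#' Deregress genotype BLUPs by their reliability
#'
#' `DRBLUP = BLUP / reliability` with `reliability = 1 - PEV/sigma_g^2`.
#' Deregression removes the shrinkage of BLUPs so that downstream
#' correlation analyses are not attenuated by unequal information across
#' genotypes. Genotypes with reliability at or below `reliability_floor`
#' get a missing deregressed value (their BLUP carries too little
#' information to de-shrink stably); the count is reported in a message.
#'
#' @param fit a `reml_fit` (or its `$predictions` data.frame, in which case
#'   `var_g` must be given).
#' @param var_g genotype variance; defaults to the fit's estimate.
#' @param reliability_floor minimum reliability for deregression.
#' @return The predictions data.frame with `reliability` and `drblup`
#'   filled in.
#' @export
deregress <- function(fit, var_g = NULL, reliability_floor = 0.1) {
  if (inherits(fit, "reml_fit")) {
    pred <- fit$predictions
    if (is.null(var_g)) var_g <- vc_get(fit, "genotype")
  } else {
    pred <- fit
  }
  stopifnot(is.data.frame(pred), !is.null(var_g))
  if (var_g <= 0) stop_cfg("deregression needs var_g > 0")
  rel <- 1 - pred$pev / var_g
  pred$reliability <- rel
  ok <- !is.na(rel) & rel > reliability_floor
  pred$drblup <- ifelse(ok, pred$blup / rel, NA_real_)
  if (any(!ok)) {
    message(sprintf("%d genotype(s) below reliability floor %.2f: drblup set missing",
                    sum(!ok), reliability_floor))
  }
  pred
}

#' Within-trial Cullis heritability, one fit per environment
#'
#' For each environment, fits the single-trial model (genotype and
#' replication random, row/column spatial trends fixed when coordinates
#' are available) and returns the Cullis heritability. Environments whose
#' fit fails are reported with a missing value.
#'
#' @param table a [pheno_table()].
#' @param trait trait column.
#' @param control a [reml_control()].
#' @return data.frame with one row per environment (scope = environment).
#' @export
per_trial_h2 <- function(table, trait, control = reml_control(se = FALSE)) {
  df <- as.data.frame(table)
  envs <- sort(unique(df$environment))
  out <- list()
  for (env in envs) {
    d <- df[df$environment == env, , drop = FALSE]
    fx <- if (all(c("row", "col") %in% names(d))) "row_col_trend"
          else character(0)
    sp <- model_spec(trait, fixed = fx, random = c("genotype", "rep"))
    h <- tryCatch({
      fit <- fit_reml(d, spec = sp, control = control)
      h2_cullis(fit, scope = env)
    }, error = function(e) {
      warning(sprintf("trial %s: %s", env, conditionMessage(e)),
              call. = FALSE)
      data.frame(method = "cullis", scope = env, value = NA_real_,
                 e = NA_real_, r = NA_real_, vbar_delta = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out[[env]] <- h
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
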