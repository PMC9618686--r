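## Synthetic multi-environment trial generator --------------------------------
##
## Emulates the trial structure the estimators assume: 67 genotypes (62
## advanced lines split over two overlapping trial sets plus 5 shared
## checks) evaluated in 8 location-year environments, alpha-lattice-like
## layout with 2 replications and recorded row/column coordinates, and a
## phenotype model
##
##   y = mu + g_i + E_j + (b_i - 1) E_j + ge_ij + rep_k(j) + spatial + eps
##
## with genetic values g drawn jointly across traits from a specified
## genetic correlation matrix, Finlay-Wilkinson sensitivity slopes b_i
## spread around 1, residual (non-regression) interaction ge_ij, and fixed
## linear row/column spatial trends. A truth record stores every drawn
## effect for parameter-recovery testing.

#' Specify one simulated trait
#'
#' @param name trait label (column name in the generated table).
#' @param mu grand mean (trait units).
#' @param var_g genetic variance.
#' @param var_ge residual genotype-by-environment interaction variance,
#'   over and above the sensitivity-slope term.
#' @param var_rep_env replication-within-environment variance.
#' @param var_e plot residual variance.
#' @param env_effect_sd SD of environment main effects.
#' @param sensitivity_sd SD of Finlay-Wilkinson slopes `b_i` around 1.
#' @param spatial_sd SD of the per-trial linear row/column trend
#'   coefficients (trait units per plot position).
#' @param missing_rate proportion of plot values deleted at random.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, mu = 0, var_g = 1, var_ge = 0.5,
                       var_rep_env = 0.2, var_e = 2, env_effect_sd = 4,
                       sensitivity_sd = 0, spatial_sd = 0,
                       missing_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            var_g >= 0, var_ge >= 0, var_rep_env >= 0, var_e >= 0,
            env_effect_sd >= 0, sensitivity_sd >= 0, spatial_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(name = name, mu = mu, var_g = var_g, var_ge = var_ge,
                 var_rep_env = var_rep_env, var_e = var_e,
                 env_effect_sd = env_effect_sd,
                 sensitivity_sd = sensitivity_sd, spatial_sd = spatial_sd,
                 missing_rate = missing_rate),
            class = "trait_spec")
}

#' Trait presets for a cassava uniform-yield-trial network
#'
#' Four traits with means, variance shares and sensitivity spreads chosen
#' to echo the reported ranges for cassava processed-product trials:
#' entry-mean heritability around 0.7 for the conversion rates, environment
#' carrying the largest share of phenotypic variance, strong genetic
#' correlation between dry matter and the conversion rates, and near-zero
#' genetic correlation of conversion rates with fresh yield.
#'
#' @return Named list of [trait_spec()] objects
#'   (`gari_pct`, `fufu_pct`, `dm`, `fyld`).
#' @export
cassava_uyt_traits <- function() {
  list(
    gari_pct = trait_spec("gari_pct", mu = 19.23, var_g = 0.86,
                          var_ge = 1.24, var_rep_env = 0.2, var_e = 3.1,
                          env_effect_sd = 2.1, sensitivity_sd = 0.2,
                          spatial_sd = 0.05, missing_rate = 0.05),
    fufu_pct = trait_spec("fufu_pct", mu = 19.68, var_g = 0.94,
                          var_ge = 0.87, var_rep_env = 0.2, var_e = 3.6,
                          env_effect_sd = 1.9, sensitivity_sd = 0.4,
                          spatial_sd = 0.05, missing_rate = 0.05),
    dm = trait_spec("dm", mu = 36.94, var_g = 1.5, var_ge = 2.0,
                    var_rep_env = 0.3, var_e = 2.0, env_effect_sd = 2.2,
                    sensitivity_sd = 0.1, spatial_sd = 0.05,
                    missing_rate = 0.05),
    fyld = trait_spec("fyld", mu = 33.03, var_g = 14, var_ge = 18,
                      var_rep_env = 3, var_e = 30, env_effect_sd = 6,
                      sensitivity_sd = 0.3, spatial_sd = 0.2,
                      missing_rate = 0.05)
  )
}

#' Genetic correlations emulating the study's trait structure
#'
#' Dry matter correlates strongly with both conversion rates (0.80, 0.82),
#' the conversion rates with each other (0.84), and fresh yield is close
#' to uncorrelated (slightly negative) with all three.
#'
#' @return A `genetic_correlation` matrix for the [cassava_uyt_traits()].
#' @export
cassava_uyt_correlations <- function() {
  genetic_correlation(
    traits = c("gari_pct", "fufu_pct", "dm", "fyld"),
    pairs = list(c("gari_pct", "fufu_pct", 0.84),
                 c("gari_pct", "dm", 0.80),
                 c("fufu_pct", "dm", 0.82),
                 c("gari_pct", "fyld", -0.10),
                 c("fufu_pct", "fyld", -0.10),
                 c("dm", "fyld", -0.05)))
}

#' Assemble a genetic correlation matrix
#'
#' Builds a symmetric trait-by-trait correlation matrix from pairwise
#' entries (unspecified pairs default to 0) and repairs mild
#' non-positive-semidefiniteness by eigenvalue clipping; if the repair
#' moves any entry by more than `repair_tol` the input is rejected.
#'
#' @param traits character vector of trait names.
#' @param pairs list of `c(trait_a, trait_b, r)` triples.
#' @param repair_tol maximum entrywise change allowed in the PSD repair.
#' @return A `genetic_correlation` matrix.
#' @export
genetic_correlation <- function(traits, pairs = list(), repair_tol = 0.05) {
  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  for (p in pairs) {
    a <- p[[1]]; b <- p[[2]]; r <- as.numeric(p[[3]])
    if (!a %in% traits || !b %in% traits) {
      stop_cfg("correlation names unknown trait: %s / %s", a, b)
    }
    if (abs(r) > 1) stop_cfg("correlation out of [-1, 1]: %s-%s", a, b)
    R[a, b] <- R[b, a] <- r
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 1e-8)
    R2 <- ev$vectors %*% diag(lam, length(lam)) %*% t(ev$vectors)
    s <- 1 / sqrt(diag(R2))
    R2 <- R2 * tcrossprod(s)
    if (max(abs(R2 - R)) > repair_tol) {
      stop_cfg("correlation matrix is not positive semidefinite and the PSD repair moves entries by %.3f > %.3f",
               max(abs(R2 - R)), repair_tol)
    }
    R <- R2
    dimnames(R) <- list(traits, traits)
  }
  structure(R, class = c("genetic_correlation", "matrix"))
}

#' Configure a simulated multi-environment trial
#'
#' Defaults reproduce the study design: 67 genotypes (5 checks shared
#' between two trial sets of 36 entries), 8 location-year environments,
#' 2 replications, a 6x6 plot grid per set and replicate.
#'
#' @param n_genotypes total unique genotypes (checks included).
#' @param n_checks number of check genotypes shared by both sets.
#' @param environments character vector of environment labels.
#' @param n_reps replications per set and environment.
#' @param n_sets number of overlapping trial sets (1 or 2).
#' @param grid `c(rows, cols)` per set and replicate.
#' @param traits named list of [trait_spec()]s.
#' @param seed master integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 67L, n_checks = 5L,
                       environments = c("AG17", "AG18", "AG19", "IB18",
                                        "IB19", "IK17", "IK19", "UB19"),
                       n_reps = 2L, n_sets = 2L, grid = c(6L, 6L),
                       traits = cassava_uyt_traits(), seed = 1L) {
  stopifnot(n_reps >= 1L, n_sets %in% c(1L, 2L), length(grid) == 2L,
            n_checks >= 0L, n_genotypes > n_checks, length(environments) >= 1L)
  n_lines <- n_genotypes - n_checks
  if (n_sets == 2L && n_lines %% 2L != 0L) {
    stop_cfg("n_genotypes - n_checks must be even for two sets")
  }
  per_set <- n_lines / n_sets + n_checks
  if (prod(grid) < per_set) {
    stop_cfg("grid %dx%d cannot hold %d entries per set",
             grid[1], grid[2], per_set)
  }
  if (is.null(names(traits))) {
    names(traits) <- vapply(traits, `[[`, "", "name")
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_checks = as.integer(n_checks),
                 environments = as.character(environments),
                 n_reps = as.integer(n_reps), n_sets = as.integer(n_sets),
                 grid = as.integer(grid), traits = traits,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_genotype_names <- function(config) {
  n_lines <- config$n_genotypes - config$n_checks
  lines <- sprintf("G%02d", seq_len(n_lines))
  checks <- if (config$n_checks > 0L) {
    sprintf("CHK%d", seq_len(config$n_checks))
  } else character()
  list(lines = lines, checks = checks, all = c(lines, checks))
}

#' Lay out the field design skeleton (no phenotypes)
#'
#' Every genotype appears `n_reps` times per environment within its set;
#' checks appear in every set; within a set and replicate the entries are
#' randomised over a rows x cols grid without duplication (replicates are
#' stacked in the row direction, so row numbers run over
#' `n_reps * grid[1]` values within a set).
#'
#' @param config a [sim_config()].
#' @return A [pheno_table()] with design columns only.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- sim_genotype_names(config)
  n_lines <- length(g$lines)
  set_members <- if (config$n_sets == 2L) {
    list(setA = c(g$lines[seq_len(n_lines / 2)], g$checks),
         setB = c(g$lines[(n_lines / 2 + 1):n_lines], g$checks))
  } else {
    list(setA = g$all)
  }
  nr <- config$grid[1]; nc <- config$grid[2]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, "design"))
  rows <- list()
  for (env in config$environments) {
    for (set_id in names(set_members)) {
      members <- set_members[[set_id]]
      for (rep_k in seq_len(config$n_reps)) {
        cells <- sample.int(nr * nc, length(members))
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = members, environment = env, rep = rep_k,
          set = set_id,
          row = (rep_k - 1L) * nr + ((cells - 1L) %/% nc) + 1L,
          col = ((cells - 1L) %% nc) + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, rows)
  pheno_table(d)
}

#' Simulate a multi-environment trial with known truth
#'
#' Generates plot-level phenotypes for every trait in the configuration
#' under the additive + sensitivity-slope interaction model described in
#' the package vignette, with genetic values drawn jointly across traits
#' from `correlations`. Fully reproducible from `config$seed`; every drawn
#' effect is returned in the truth record.
#'
#' @param config a [sim_config()].
#' @param correlations a [genetic_correlation()] matrix covering the
#'   configured traits, or `NULL` for independent traits.
#' @param emit_raw if `TRUE`, also emit the raw parent measurements
#'   (processing weights, `RTWT`, plant counts) from which
#'   [derive_traits()] reconstructs `gari_pct`, `fufu_pct`, `fyld`, `dyld`;
#'   the derived columns themselves are then not included.
#' @return List with elements `pheno` (a [pheno_table()]) and `truth`
#'   (a `met_truth` list: per trait `g`, `E`, `b`, `ge`, `rep_effects`,
#'   `spatial`, variance components; plus the seed).
#' @export
simulate_met <- function(config, correlations = NULL, emit_raw = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  design <- make_design(config)
  d <- as.data.frame(design)
  g <- sim_genotype_names(config)
  n_g <- length(g$all)
  envs <- config$environments
  n_e <- length(envs)
  trait_names <- names(config$traits)
  n_t <- length(trait_names)

  R <- if (is.null(correlations)) {
    genetic_correlation(trait_names)
  } else {
    if (!all(trait_names %in% rownames(correlations))) {
      stop_cfg("correlation matrix does not cover all configured traits")
    }
    correlations[trait_names, trait_names, drop = FALSE]
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # joint genetic values: standard normals x chol(R), scaled per trait
  set.seed(substream_seed(config$seed, "genetic"))
  Zg <- matrix(stats::rnorm(n_g * n_t), n_g, n_t) %*% chol(R)
  dimnames(Zg) <- list(g$all, trait_names)

  truth <- list(seed = config$seed, genotypes = g$all,
                environments = envs, correlations = R, traits = list())
  pheno <- d
  set_env <- paste(d$set, d$environment, sep = ":")

  for (tn in trait_names) {
    ts <- config$traits[[tn]]
    gv <- Zg[, tn] * sqrt(ts$var_g)
    set.seed(substream_seed(config$seed, paste0("trait/", tn)))
    E <- stats::rnorm(n_e, 0, ts$env_effect_sd)
    names(E) <- envs
    b <- 1 + stats::rnorm(n_g, 0, ts$sensitivity_sd)
    names(b) <- g$all
    ge <- matrix(stats::rnorm(n_g * n_e, 0, sqrt(ts$var_ge)), n_g, n_e,
                 dimnames = list(g$all, envs))
    rep_lab <- as.vector(outer(envs, seq_len(config$n_reps),
                               function(e, k) paste(e, k, sep = ":")))
    rep_eff <- stats::rnorm(length(rep_lab), 0, sqrt(ts$var_rep_env))
    names(rep_eff) <- rep_lab
    se_lab <- sort(unique(set_env))
    sp_row <- stats::rnorm(length(se_lab), 0, ts$spatial_sd)
    sp_col <- stats::rnorm(length(se_lab), 0, ts$spatial_sd)
    names(sp_row) <- names(sp_col) <- se_lab

    i <- match(d$genotype, g$all)
    j <- match(d$environment, envs)
    k <- match(paste(d$environment, d$rep, sep = ":"), rep_lab)
    se <- match(set_env, se_lab)
    y <- ts$mu + gv[i] + E[j] + (b[i] - 1) * E[j] + ge[cbind(i, j)] +
      rep_eff[k] +
      sp_row[se] * (d$row - mean(d$row)) + sp_col[se] * (d$col - mean(d$col)) +
      stats::rnorm(nrow(d), 0, sqrt(ts$var_e))
    if (ts$missing_rate > 0) {
      y[stats::runif(nrow(d)) < ts$missing_rate] <- NA
    }
    pheno[[tn]] <- y
    truth$traits[[tn]] <- list(
      g = gv, E = E, b = b, ge = ge, rep_effects = rep_eff,
      spatial_row = sp_row, spatial_col = sp_col,
      var_g = ts$var_g, var_ge = ts$var_ge,
      var_rep_env = ts$var_rep_env, var_e = ts$var_e, mu = ts$mu)
  }

  if (emit_raw) pheno <- emit_raw_measures(pheno, trait_names, config)
  list(pheno = pheno_table(pheno),
       truth = structure(truth, class = "met_truth"))
}

## replace simulated analysis traits by the raw measurements they derive from
emit_raw_measures <- function(pheno, trait_names, config) {
  set.seed(substream_seed(config$seed, "raw"))
  n <- nrow(pheno)
  pheno$n_plants_harvested <- 20L - stats::rbinom(n, 4, 0.1)
  if ("gari_pct" %in% trait_names) {
    pheno$starting_root_weight_gari <- 20
    pheno$gari_weight <- pheno$gari_pct * 20 / 100
    pheno$gari_pct <- NULL
  }
  if ("fufu_pct" %in% trait_names) {
    pheno$starting_root_weight_fufu <- 20
    pheno$fufu_weight <- pheno$fufu_pct * 20 / 100
    pheno$fufu_pct <- NULL
  }
  if ("fyld" %in% trait_names) {
    pheno$RTWT <- pheno$fyld * (pheno$n_plants_harvested * 0.8) / 10
    pheno$fyld <- NULL
  }
  pheno
}
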