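## Finlay-Wilkinson, AMMI and GGE models on the two-way table -----------------
##
## All three operate on a complete genotype x environment table of adjusted
## means and partition the same corrected total sum of squares:
##   FW:   y_ij = mu + G_i + E_j + (b_i - 1) E_j + d_ij
##   AMMI: y_ij = mu + g_i + e_j + sum_k lambda_k a_ik c_jk + r_ij
##   GGE:  y_ij = mu + e_j + sum_k lambda_k a_ik c_jk + r_ij
## FW splits the interaction SS into slope heterogeneity + deviation; AMMI
## decomposes it by SVD of the double-centred matrix; GGE absorbs the
## genotype main effect into the SVD of the environment-centred matrix.

tw_parts <- function(t) {
  X <- unclass(t)
  if (anyNA(X)) stop_cfg("model needs a complete table; run complete_table()")
  mu <- mean(X)
  g <- rowMeans(X) - mu
  e <- colMeans(X) - mu
  D <- X - outer(g, e, `+`) - mu # double-centred interaction
  list(X = X, mu = mu, g = g, e = e, D = D,
       ss_gen = ncol(X) * sum(g^2), ss_env = nrow(X) * sum(e^2),
       ss_int = sum(D^2), tss = sum((X - mu)^2))
}

#' Finlay-Wilkinson joint regression
#'
#' Regresses each genotype's adjusted means on the environmental index
#' (environment mean minus grand mean, the two-step estimator, exact for a
#' complete equally weighted table). The reported sensitivity is the OLS
#' slope, so an averagely responsive genotype has sensitivity 1 and the
#' unweighted mean of sensitivities is exactly 1. The ANOVA partitions the
#' corrected total SS into genotype, environment, sensitivity
#' heterogeneity, and residual (deviation) terms.
#'
#' @param t a complete [two_way_table()] (conventionally the
#'   [scale_table()]d one, so slopes and MS deviations are comparable
#'   across traits).
#' @return An `fw_fit`: `$genotypes` (genotype, mean, sensitivity, ms_dev),
#'   `$env_index`, `$anova`, `$slope_var`, `$slope_median`, `$msdev_var`,
#'   `$msdev_median`, `$mu`.
#' @export
fit_fw <- function(t) {
  pt <- tw_parts(t)
  n_e <- ncol(pt$X)
  if (n_e < 3L) stop_cfg("Finlay-Wilkinson slopes need >= 3 environments")
  ej <- pt$e # environmental index
  see <- sum(ej^2)
  # slope of row i on index: 1 + cov(D_i, ej)/see
  b <- 1 + as.numeric(pt$D %*% ej) / see
  resid <- pt$D - outer(b - 1, ej)
  rss <- rowSums(resid^2)
  ms_dev <- rss / (n_e - 2)
  ss_sens <- sum((b - 1)^2) * see
  ss_resid <- sum(rss)
  anova <- data.frame(
    term = c("genotype", "environment", "sensitivity", "residual"),
    df = c(nrow(pt$X) - 1L, n_e - 1L, nrow(pt$X) - 1L,
           (nrow(pt$X) - 1L) * (n_e - 2L)),
    ss = c(pt$ss_gen, pt$ss_env, ss_sens, ss_resid),
    stringsAsFactors = FALSE)
  anova$ms <- anova$ss / anova$df
  structure(list(
    genotypes = data.frame(genotype = rownames(pt$X),
                           mean = rowMeans(pt$X), sensitivity = b,
                           ms_dev = ms_dev, stringsAsFactors = FALSE,
                           row.names = NULL),
    env_index = stats::setNames(ej, colnames(pt$X)),
    mu = pt$mu, anova = anova, tss = pt$tss,
    slope_var = stats::var(b), slope_median = stats::median(b),
    msdev_var = stats::var(ms_dev), msdev_median = stats::median(ms_dev)),
    class = "fw_fit")
}

#' AMMI: additive main effects and multiplicative interaction
#'
#' Fits genotype and environment main effects, then decomposes the
#' double-centred interaction matrix by SVD into interaction principal
#' component axes (IPCAs). Scores use the symmetric convention
#' `a_ik = u_ik sqrt(lambda_k)`, `c_jk = v_jk sqrt(lambda_k)`, so the sum
#' of products over modes reconstructs the interaction exactly at full
#' rank and `SS_IPCAk = lambda_k^2`. IPCA F-tests use Gollob degrees of
#' freedom `(n_g - 1) + (n_e - 1) - (2k - 1)` and are approximate.
#'
#' @param t a complete [two_way_table()].
#' @param k_max number of IPCAs to retain (truncated with a warning if it
#'   exceeds `min(n_g, n_e) - 1`).
#' @return An `ammi_fit`: `$mu`, `$gen_effects`, `$env_effects`,
#'   `$svalues`, `$gen_scores`, `$env_scores`, `$anova`, `$tss`.
#' @export
fit_ammi <- function(t, k_max = 2L) {
  pt <- tw_parts(t)
  n_g <- nrow(pt$X); n_e <- ncol(pt$X)
  k_full <- min(n_g, n_e) - 1L
  if (k_max > k_full) {
    warning(sprintf("k_max truncated to %d", k_full), call. = FALSE)
    k_max <- k_full
  }
  sv <- svd(pt$D)
  lam <- sv$d[seq_len(k_full)]
  if (any(duplicated(signif(lam[lam > 1e-12], 12)))) {
    warning("equal singular values: IPCA axes are rotation-indeterminate within the tied subspace",
            call. = FALSE)
  }
  gen_scores <- sv$u[, seq_len(k_full), drop = FALSE] %*%
    diag(sqrt(lam), k_full)
  env_scores <- sv$v[, seq_len(k_full), drop = FALSE] %*%
    diag(sqrt(lam), k_full)
  dimnames(gen_scores) <- list(rownames(pt$X),
                               paste0("IPCA", seq_len(k_full)))
  dimnames(env_scores) <- list(colnames(pt$X),
                               paste0("IPCA", seq_len(k_full)))
  ss_k <- lam^2
  df_k <- (n_g - 1L) + (n_e - 1L) - (2L * seq_len(k_full) - 1L)
  keep <- seq_len(k_max)
  ss_resid <- sum(ss_k[-keep])
  df_resid <- (n_g - 1L) * (n_e - 1L) - sum(df_k[keep])
  anova <- data.frame(
    term = c("genotype", "environment", paste0("IPCA", keep), "residual"),
    df = c(n_g - 1L, n_e - 1L, df_k[keep], df_resid),
    ss = c(pt$ss_gen, pt$ss_env, ss_k[keep], ss_resid),
    stringsAsFactors = FALSE)
  anova$ms <- ifelse(anova$df > 0, anova$ss / anova$df, NA)
  structure(list(mu = pt$mu,
                 gen_effects = stats::setNames(pt$g, rownames(pt$X)),
                 env_effects = stats::setNames(pt$e, colnames(pt$X)),
                 svalues = lam, gen_scores = gen_scores,
                 env_scores = env_scores, k_max = k_max,
                 ss_interaction = pt$ss_int, anova = anova, tss = pt$tss),
            class = "ammi_fit")
}

#' GGE: genotype main effect plus genotype-by-environment interaction
#'
#' Subtracts environment (column) means and decomposes the centred matrix
#' by SVD; the genotype main effect stays inside the decomposition, which
#' is the basis of the GGE biplot. Biplot coordinates use symmetric
#' scaling (both modes scaled by the square root of the singular values).
#' Environment-vector cosine similarities summarise how strongly
#' environments rank genotypes alike.
#'
#' @param t a complete [two_way_table()].
#' @return A `gge_fit`: `$mu`, `$env_effects`, `$svalues`, `$gen_coords`,
#'   `$env_coords`, `$pc_pct` (% of G+GE per PC), `$pc12_pct`,
#'   `$env_cosines`, `$anova`, `$tss`.
#' @export
fit_gge <- function(t) {
  pt <- tw_parts(t)
  n_g <- nrow(pt$X); n_e <- ncol(pt$X)
  Xc <- pt$X - matrix(colMeans(pt$X), n_g, n_e, byrow = TRUE)
  k_full <- min(n_g, n_e)
  sv <- svd(Xc)
  lam <- sv$d[seq_len(k_full)]
  gen_coords <- sv$u[, seq_len(k_full), drop = FALSE] %*%
    diag(sqrt(lam), k_full)
  env_coords <- sv$v[, seq_len(k_full), drop = FALSE] %*%
    diag(sqrt(lam), k_full)
  dimnames(gen_coords) <- list(rownames(pt$X), paste0("PC", seq_len(k_full)))
  dimnames(env_coords) <- list(colnames(pt$X), paste0("PC", seq_len(k_full)))
  ss_gge <- sum(Xc^2)
  pc_pct <- if (ss_gge > 0) 100 * lam^2 / ss_gge else rep(0, k_full)
  # environment-vector angles in the full space = correlation-like cosines
  cosines <- matrix(NA_real_, n_e, n_e, dimnames = list(colnames(pt$X),
                                                        colnames(pt$X)))
  nrm <- sqrt(colSums(Xc^2))
  ok <- nrm > 0
  cosines[ok, ok] <- crossprod(Xc[, ok, drop = FALSE]) / tcrossprod(nrm[ok])
  anova <- data.frame(
    term = c("environment", "PC1", "PC2", "residual"),
    df = c(n_e - 1L, n_g + n_e - 3L, n_g + n_e - 5L, NA),
    ss = c(pt$ss_env, lam[1]^2, ifelse(k_full >= 2, lam[2]^2, 0),
           ss_gge - sum(lam[seq_len(min(2L, k_full))]^2)),
    stringsAsFactors = FALSE)
  structure(list(mu = pt$mu,
                 env_effects = stats::setNames(pt$e, colnames(pt$X)),
                 svalues = lam, gen_coords = gen_coords,
                 env_coords = env_coords, ss_gge = ss_gge,
                 pc_pct = pc_pct,
                 pc12_pct = sum(pc_pct[seq_len(min(2L, k_full))]),
                 env_cosines = cosines, anova = anova, tss = pt$tss),
            class = "gge_fit")
}

#' Partition the total sum of squares by model term
#'
#' Expresses each fitted term's SS as a percentage of the corrected total
#' sum of squares of the two-way table; the listed percentages sum to 100.
#'
#' @param fit an `fw_fit`, `ammi_fit` or `gge_fit`.
#' @return data.frame with columns `term`, `ss`, `pct_tss`.
#' @export
partition_tss <- function(fit) {
  stopifnot(inherits(fit, c("fw_fit", "ammi_fit", "gge_fit")))
  an <- fit$anova
  out <- data.frame(term = an$term, ss = an$ss,
                    pct_tss = 100 * an$ss / fit$tss,
                    stringsAsFactors = FALSE)
  out
}

#' Which-won-where: per-environment winners and the GGE hull
#'
#' Flags, for each environment, the genotype with the best (largest) cell
#' value, and whether that winner lies on the convex hull of the GGE
#' PC1-PC2 genotype coordinates.
#'
#' @param t the [two_way_table()] the GGE model was fitted to.
#' @param fit the corresponding `gge_fit`.
#' @return data.frame: environment, winner, winner_on_hull.
#' @export
gge_winners <- function(t, fit) {
  stopifnot(inherits(fit, "gge_fit"))
  X <- unclass(t)
  winners <- rownames(X)[apply(X, 2, which.max)]
  xy <- fit$gen_coords[, 1:2, drop = FALSE]
  hull <- rownames(xy)[grDevices::chull(xy[, 1], xy[, 2])]
  data.frame(environment = colnames(X), winner = winners,
             winner_on_hull = winners %in% hull,
             stringsAsFactors = FALSE)
}
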