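## Genotype x environment two-way table of adjusted means ---------------------

#' Construct a two-way (genotype x environment) table
#'
#' @param x numeric matrix, rows = genotypes, cols = environments.
#' @param imputed optional logical matrix flagging imputed cells.
#' @return A `two_way_table`.
#' @export
two_way_table <- function(x, imputed = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L,
            !is.null(rownames(x)), !is.null(colnames(x)))
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  structure(x, imputed = imputed, class = c("two_way_table", "matrix"))
}

#' @export
print.two_way_table <- function(x, ...) {
  cat(sprintf("two_way_table: %d genotypes x %d environments (%d missing, %d imputed)\n",
              nrow(x), ncol(x), sum(is.na(x)), sum(attr(x, "imputed"))))
  invisible(x)
}

#' Per-environment adjusted genotype means (BLUEs)
#'
#' Within each environment, fits genotype as a fixed effect with
#' replication random and row/column spatial trends fixed (when plot
#' coordinates are present); the genotype coefficients are the adjusted
#' means. Genotypes absent from an environment (or with no non-missing
#' value there) yield missing cells, which are counted in a message.
#'
#' @param table a [pheno_table()].
#' @param trait trait column.
#' @param control a [reml_control()].
#' @return A [two_way_table()] with possibly missing cells.
#' @export
two_way_means <- function(table, trait, control = reml_control(se = FALSE)) {
  df <- as.data.frame(table)
  if (!trait %in% names(df)) stop_cfg("trait '%s' not found", trait)
  envs <- sort(unique(df$environment))
  if (length(envs) < 2L) stop_cfg("trait observed in fewer than 2 environments")
  genos <- sort(unique(df$genotype))
  X <- matrix(NA_real_, length(genos), length(envs),
              dimnames = list(genos, envs))
  for (env in envs) {
    d <- df[df$environment == env & !is.na(df[[trait]]), , drop = FALSE]
    if (!nrow(d)) next
    fx <- c("genotype",
            if (all(c("row", "col") %in% names(d))) "row_col_trend")
    rnd <- if (length(unique(d$rep)) >= 2L) "rep" else character(0)
    if (length(rnd)) {
      fit <- fit_reml(d, spec = model_spec(trait, fixed = fx, random = rnd),
                      control = control)
      cf <- fit$fixef
    } else {
      Xd <- build_fixed_matrix(d, fx)
      cf <- stats::setNames(as.numeric(qr.coef(qr(Xd), d[[trait]])),
                            colnames(Xd))
    }
    gc <- cf[startsWith(names(cf), "genotype:")]
    names(gc) <- sub("^genotype:", "", names(gc))
    X[names(gc), env] <- gc
  }
  n_miss <- sum(is.na(X))
  if (n_miss > 0L) {
    message(sprintf("%d missing genotype-by-environment cell(s) flagged",
                    n_miss))
  }
  two_way_table(X)
}

#' Impute missing cells of a two-way table
#'
#' Iterates an additive (row + column) fit plus a rank-1 SVD of the
#' residual matrix, refilling the missing cells with the fitted values
#' until the largest change is below `tol`. Imputed cells are flagged in
#' the `imputed` attribute.
#'
#' @param t a [two_way_table()].
#' @param max_missing_frac maximum tolerated fraction of missing cells.
#' @param tol convergence tolerance on imputed values.
#' @param max_iter iteration cap.
#' @return A complete [two_way_table()].
#' @export
complete_table <- function(t, max_missing_frac = 0.2, tol = 1e-8,
                           max_iter = 500L) {
  stopifnot(inherits(t, "two_way_table"))
  miss <- is.na(unclass(t))
  if (!any(miss)) return(t)
  if (mean(miss) > max_missing_frac) {
    stop_cfg("%.1f%% of cells missing (> %.1f%%); filter genotypes or traits first",
             100 * mean(miss), 100 * max_missing_frac)
  }
  if (any(rowSums(!miss) == 0L) || any(colSums(!miss) == 0L)) {
    stop_cfg("a full row or column is missing; cannot impute")
  }
  X <- unclass(t)
  additive_fit <- function(M) {
    mu <- mean(M)
    r <- rowMeans(M) - mu
    cc <- colMeans(M) - mu
    outer(r, cc, `+`) + mu
  }
  # start from the additive expectation computed on observed margins
  mu0 <- mean(X[!miss])
  r0 <- rowMeans(X, na.rm = TRUE) - mu0
  c0 <- colMeans(X, na.rm = TRUE) - mu0
  fill <- outer(r0, c0, `+`) + mu0
  X[miss] <- fill[miss]
  # stage 1: additive EM to the least-squares additive completion
  for (it in seq_len(max_iter)) {
    pred <- additive_fit(X)
    delta <- max(abs(pred[miss] - X[miss]))
    X[miss] <- pred[miss]
    if (delta < tol) break
  }
  # stage 2: refine with a rank-1 interaction term
  for (it in seq_len(max_iter)) {
    A <- additive_fit(X)
    D <- X - A
    sv <- svd(D, nu = 1, nv = 1)
    pred <- A + sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
    delta <- max(abs(pred[miss] - X[miss]))
    X[miss] <- pred[miss]
    if (delta < tol) break
  }
  two_way_table(X, imputed = miss)
}

#' Standardise a two-way table to overall mean 0, SD 1
#'
#' `(x - mean) / sd` over all cells, the scaling applied before the
#' Finlay-Wilkinson fit so that sensitivity slopes and mean-square
#' deviations are comparable across traits measured in different units.
#' Stability indices (Wricke, GAI) must be computed on the unscaled table.
#'
#' @param t a complete [two_way_table()].
#' @return The scaled [two_way_table()].
#' @export
scale_table <- function(t) {
  stopifnot(inherits(t, "two_way_table"))
  X <- unclass(t)
  if (anyNA(X)) stop_cfg("scale_table needs a complete table")
  s <- stats::sd(X)
  if (s <= 0) stop_cfg("zero variance; cannot scale")
  two_way_table((X - mean(X)) / s, imputed = attr(t, "imputed"))
}
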