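## REML variance-component engine ---------------------------------------------
##
## Fits y = X beta + sum_k Z_k u_k + e with u_k ~ N(0, sigma_k^2 I) and
## e ~ N(0, sigma_e^2 I) by restricted maximum likelihood on the mixed-model
## equations. With lambda_k = sigma_k^2 / sigma_e^2, W = [X Z] and
## C = W'W + diag(0_p, 1/lambda_k I_qk),
##
##   -2 l_R = (n-p) log(2 pi sigma_e^2) + sum_k q_k log(lambda_k)
##            + log|C| + (y'y - s_hat' W'y) / sigma_e^2
##
## where C s_hat = W'y. The residual variance is profiled out; the
## remaining ratios are maximised by an optional EM warm-up (monotone in
## the log-likelihood, boundary-safe) followed by bounded quasi-Newton
## (L-BFGS-B). Components driven to the boundary are reported as pinned
## at zero. Standard errors come from a numerical Hessian of the
## unprofiled REML log-likelihood; BLUPs, prediction-error variances and
## the genotype block of the inverse coefficient matrix (for the Cullis
## heritability) come from the converged mixed-model equations.

#' Specify the mixed model
#'
#' @param response trait column to analyse.
#' @param fixed character vector of fixed terms: `"row_col_trend"` (centred
#'   linear row/column covariates nested in set x environment), `"set"`,
#'   `"genotype"` (genotype as fixed effect, suppressing the intercept, for
#'   adjusted-mean/BLUE models), or any numeric column name. The intercept
#'   is always included unless `"genotype"` is fixed.
#' @param random character vector of random terms: `"genotype"`,
#'   `"environment"`, `"rep_in_env"`, `"genotype_env"`, `"rep"`,
#'   `"row_in_set"`, `"col_in_set"`, any column name, or interactions
#'   `"a:b"`.
#' @return A `model_spec` list. The default is the overall random-genotype
#'   model: genotype, environment, replication-in-environment and
#'   genotype-by-environment random, row/column trends fixed.
#' @export
model_spec <- function(response,
                       fixed = c("row_col_trend"),
                       random = c("genotype", "environment", "rep_in_env",
                                  "genotype_env")) {
  stopifnot(is.character(response), length(response) == 1L)
  both <- intersect(fixed, random)
  if (length(both)) stop_cfg("term(s) in both fixed and random: %s",
                             paste(both, collapse = ", "))
  structure(list(response = response, fixed = fixed, random = random),
            class = "model_spec")
}

#' Control parameters for the REML fit
#'
#' @param em_iter EM warm-up iterations (0 disables; automatically skipped
#'   when the mixed-model equations exceed `em_dim_max` rows, since each EM
#'   step needs a full inverse).
#' @param max_iter maximum quasi-Newton iterations.
#' @param tol relative convergence tolerance on the variance components.
#' @param se compute standard errors and z-tests (numerical Hessian).
#' @param pin_tol variance ratio below which a component is pinned to 0.
#' @param em_dim_max largest coefficient-matrix dimension for EM warm-up.
#' @return A `reml_control` list.
#' @export
reml_control <- function(em_iter = 8L, max_iter = 500L, tol = 1e-8,
                         se = TRUE, pin_tol = 1e-6, em_dim_max = 1500L) {
  list(em_iter = em_iter, max_iter = max_iter, tol = tol, se = se,
       pin_tol = pin_tol, em_dim_max = em_dim_max)
}

resolve_random_factor <- function(df, term) {
  base_col <- function(nm) {
    switch(nm,
           genotype = df$genotype,
           environment = df$environment,
           rep = paste0("r", df$rep),
           set = df$set,
           rep_in_env = paste(df$environment, df$rep, sep = ":"),
           genotype_env = paste(df$genotype, df$environment, sep = ":"),
           row_in_set = paste(df$set, df$row, sep = ":"),
           col_in_set = paste(df$set, df$col, sep = ":"),
           {
             if (!nm %in% names(df)) stop_cfg("unknown random term: %s", nm)
             df[[nm]]
           })
  }
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  v <- base_col(parts[1])
  if (length(parts) > 1L) {
    for (pp in parts[-1]) v <- paste(v, base_col(pp), sep = ":")
  }
  factor(v)
}

build_fixed_matrix <- function(df, fixed) {
  n <- nrow(df)
  cols <- list()
  has_geno_fixed <- "genotype" %in% fixed
  if (!has_geno_fixed) cols[["(Intercept)"]] <- rep(1, n)
  for (term in fixed) {
    if (term == "genotype") {
      f <- factor(df$genotype)
      M <- stats::model.matrix(~ 0 + f)
      colnames(M) <- paste0("genotype:", levels(f))
      cols[[term]] <- M
    } else if (term == "row_col_trend") {
      if (!all(c("row", "col") %in% names(df))) {
        stop_cfg("fixed term row_col_trend needs row and col columns")
      }
      se <- factor(paste(df$set, df$environment, sep = ":"))
      rc <- df$row - stats::ave(df$row, se)
      cc <- df$col - stats::ave(df$col, se)
      M <- matrix(0, n, 2L * nlevels(se))
      colnames(M) <- c(paste0("row_trend:", levels(se)),
                       paste0("col_trend:", levels(se)))
      for (l in seq_len(nlevels(se))) {
        in_l <- as.integer(se) == l
        M[in_l, l] <- rc[in_l]
        M[in_l, nlevels(se) + l] <- cc[in_l]
      }
      cols[[term]] <- M
    } else if (term == "set") {
      f <- factor(df$set)
      if (nlevels(f) > 1L) {
        M <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(M) <- paste0("set:", levels(f)[-1])
        cols[[term]] <- M
      }
    } else if (term %in% names(df) && is.numeric(df[[term]])) {
      cols[[term]] <- matrix(df[[term]], ncol = 1,
                             dimnames = list(NULL, term))
    } else {
      stop_cfg("unknown fixed term: %s", term)
    }
  }
  X <- do.call(cbind, cols)
  # degenerate covariate columns (e.g. constant row within a trial) are 0
  keep <- colSums(abs(X)) > 1e-12
  X <- X[, keep, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_cfg("fixed-effects design is singular; aliased: %s",
             paste(aliased, collapse = ", "))
  }
  X
}

build_mm <- function(df, spec) {
  y <- df[[spec$response]]
  if (is.null(y)) stop_cfg("response '%s' not found", spec$response)
  keep <- !is.na(y)
  df <- df[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  n <- length(y)
  if (n < 3L) stop_cfg("fewer than 3 non-missing observations for '%s'",
                       spec$response)
  X <- build_fixed_matrix(df, spec$fixed)
  Zs <- list(); qk <- integer(0); levs <- list()
  for (term in spec$random) {
    f <- droplevels(resolve_random_factor(df, term))
    if (nlevels(f) < 2L) {
      stop_cfg("random term '%s' has fewer than 2 levels", term)
    }
    Zs[[term]] <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                       x = 1, dims = c(n, nlevels(f)))
    qk[term] <- nlevels(f)
    levs[[term]] <- levels(f)
  }
  W <- do.call(cbind, c(list(Matrix::Matrix(X, sparse = TRUE)), Zs))
  list(y = y, X = X, n = n, p = ncol(X), W = W, qk = qk, levels = levs,
       WtW = Matrix::forceSymmetric(Matrix::crossprod(W)),
       Wty = as.numeric(Matrix::crossprod(W, y)),
       yty = sum(y^2), df = df)
}

## core evaluator: given variance ratios, return -2 profiled REML loglik
## and (on request) solution/Cholesky
mm_core <- function(mm, state) {
  m <- mm$p + sum(mm$qk)
  function(lambda, want = "value") {
    dvec <- c(rep(0, mm$p), rep(1 / lambda, mm$qk))
    C <- Matrix::forceSymmetric(mm$WtW + Matrix::Diagonal(m, dvec))
    if (is.null(state$ch)) {
      state$ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      state$ch <- Matrix::update(state$ch, C)
    }
    ldC <- as.numeric(Matrix::determinant(state$ch, logarithm = TRUE,
                                          sqrt = FALSE)$modulus)
    shat <- as.numeric(Matrix::solve(state$ch, mm$Wty, system = "A"))
    quad <- mm$yty - sum(shat * mm$Wty)
    quad <- max(quad, 1e-12)
    np <- mm$n - mm$p
    sig2e <- quad / np
    neg2 <- np * log(2 * pi * sig2e) + sum(mm$qk * log(lambda)) + ldC + np
    if (want == "value") return(neg2)
    list(neg2 = neg2, shat = shat, sig2e = sig2e, C = C, ch = state$ch,
         ldC = ldC, quad = quad)
  }
}

## -2 REML loglik on the full variance scale (for the Hessian / SEs)
neg2_full <- function(mm, core) {
  function(sig2) {
    k <- length(mm$qk)
    se2 <- sig2[k + 1]
    lambda <- pmax(sig2[seq_len(k)], 1e-12) / se2
    res <- core(lambda, want = "all")
    np <- mm$n - mm$p
    np * log(2 * pi * se2) + sum(mm$qk * log(lambda)) + res$ldC +
      res$quad / se2
  }
}

num_grad <- function(f, x, lower) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- max(1e-4 * abs(x[i]), 1e-7)
    xl <- x; xl[i] <- max(x[i] - h, lower)
    xu <- x; xu[i] <- x[i] + h
    g[i] <- (f(xu) - f(xl)) / (xu[i] - xl[i])
  }
  g
}

num_hessian <- function(f, x, rel = 1e-3) {
  k <- length(x)
  H <- matrix(0, k, k)
  h <- pmax(rel * abs(x), 1e-8)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the random-genotype mixed model by REML
#'
#' Estimates the variance components of `spec` (by default genotype,
#' environment, replication-in-environment, genotype-by-environment and
#' residual) by REML, with one-sided z-tests, percent of phenotypic
#' variance explained, genotype BLUPs with prediction-error variances and
#' reliabilities, and the genotype block of the inverse mixed-model
#' coefficient matrix needed for the Cullis heritability. When
#' `"genotype"` is a fixed term the fit instead returns genotype BLUEs
#' (adjusted means) in `$fixef`.
#'
#' @param table a [pheno_table()] (or plain data.frame with the design
#'   columns).
#' @param spec a [model_spec()]; default `model_spec(trait)`.
#' @param trait shorthand for `spec = model_spec(trait)` with default terms.
#' @param control a [reml_control()].
#' @return An object of class `reml_fit`: `$varcomp` (term, estimate, SE,
#'   z, p_value, pct_explained, pinned), `$predictions` (genotype, blup,
#'   pev, reliability, drblup), `$loglik`, `$loglik_trace`, `$convergence`,
#'   `$iterations`, `$fixef`, `$vg_cov`, `$sigma2`.
#' @export
fit_reml <- function(table, spec = NULL, trait = NULL,
                     control = reml_control()) {
  if (is.null(spec)) {
    if (is.null(trait)) stop_cfg("supply spec or trait")
    spec <- model_spec(trait)
  }
  df <- as.data.frame(table)
  mm <- build_mm(df, spec)
  k <- length(mm$qk)
  m <- mm$p + sum(mm$qk)
  state <- new.env(parent = emptyenv())
  core <- mm_core(mm, state)

  vy <- stats::var(mm$y)
  sig2 <- rep(vy / (k + 1), k + 1) # equal split start
  names(sig2) <- c(names(mm$qk), "residual")
  trace <- numeric(0)
  iter_em <- 0L

  em_iter <- if (m > control$em_dim_max) 0L else control$em_iter
  if (em_iter > 0L) {
    blk_idx <- split(mm$p + seq_len(sum(mm$qk)),
                     rep(seq_len(k), mm$qk))
    for (it in seq_len(em_iter)) {
      lambda <- pmax(sig2[seq_len(k)], 1e-10 * sig2[k + 1]) / sig2[k + 1]
      res <- core(lambda, want = "all")
      trace <- c(trace, -0.5 * res$neg2)
      Cd <- as.matrix(res$C)
      Cinv <- chol2inv(chol(Cd))
      for (kk in seq_len(k)) {
        idx <- blk_idx[[kk]]
        u <- res$shat[idx]
        sig2[kk] <- (sum(u^2) +
                       res$sig2e * sum(diag(Cinv)[idx])) / mm$qk[kk]
      }
      sig2[k + 1] <- res$quad / (mm$n - mm$p)
      iter_em <- it
    }
  }

  lambda0 <- pmax(sig2[seq_len(k)], 1e-9 * sig2[k + 1]) / sig2[k + 1]
  lower <- rep(1e-10, k); upper <- rep(1e8, k)
  opt <- stats::optim(
    par = pmin(pmax(lambda0, lower), upper),
    fn = function(l) core(l),
    gr = function(l) num_grad(function(x) core(x), l, 1e-10),
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = control$max_iter,
                   factr = control$tol / .Machine$double.eps))
  lambda <- opt$par
  res <- core(lambda, want = "all")
  trace <- c(trace, -0.5 * res$neg2)
  sig2e <- res$sig2e
  sig2 <- c(lambda * sig2e, sig2e)
  names(sig2) <- c(names(mm$qk), "residual")
  pinned <- c(lambda <= control$pin_tol, FALSE)
  est <- sig2
  est[pinned] <- 0

  ## standard errors from the observed information (numerical Hessian)
  SE <- rep(NA_real_, k + 1)
  if (isTRUE(control$se)) {
    free <- which(!pinned)
    f_free <- function(sf) {
      s <- est; s[free] <- sf
      s[s <= 0] <- 1e-12
      neg2_full(mm, core)(s)
    }
    H <- try(num_hessian(f_free, est[free]), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(2 * solve(H), silent = TRUE) # Var = I^-1 = 2 H_{-2l}^-1
      if (!inherits(V, "try-error")) {
        dv <- diag(V)
        dv[dv < 0] <- NA
        SE[free] <- sqrt(dv)
      }
    }
    # restore Cholesky/solution at the optimum
    res <- core(lambda, want = "all")
  }
  z <- est / SE
  pval <- 1 - stats::pnorm(z) # one-sided: components are boundary-constrained

  varcomp <- data.frame(
    term = names(sig2), estimate = unname(est), SE = SE, z = unname(z),
    p_value = unname(pval),
    pct_explained = 100 * unname(est) / sum(est),
    pinned = unname(pinned), stringsAsFactors = FALSE)

  ## fixed effects and BLUPs
  fixef <- res$shat[seq_len(mm$p)]
  names(fixef) <- colnames(mm$X)
  blup_all <- list()
  off <- mm$p
  for (term in names(mm$qk)) {
    u <- res$shat[off + seq_len(mm$qk[term])]
    names(u) <- mm$levels[[term]]
    blup_all[[term]] <- u
    off <- off + mm$qk[term]
  }

  predictions <- NULL; vg_cov <- NULL
  if ("genotype" %in% names(mm$qk)) {
    gi <- mm$p + cumsum(c(0, mm$qk))[match("genotype", names(mm$qk))] +
      seq_len(mm$qk["genotype"])
    Eg <- Matrix::sparseMatrix(i = gi, j = seq_along(gi), x = 1,
                               dims = c(m, length(gi)))
    Cinv_g <- as.matrix(Matrix::solve(res$ch, Eg, system = "A"))[gi, ,
                                                                 drop = FALSE]
    vg_cov <- sig2e * (Cinv_g + t(Cinv_g)) / 2
    g_names <- mm$levels[["genotype"]]
    dimnames(vg_cov) <- list(g_names, g_names)
    pev <- diag(vg_cov)
    s2g <- est["genotype"]
    reliability <- if (s2g > 0) 1 - pev / s2g else rep(NA_real_, length(pev))
    predictions <- data.frame(
      genotype = g_names, blup = unname(blup_all[["genotype"]]),
      pev = unname(pev), reliability = unname(reliability),
      drblup = NA_real_, stringsAsFactors = FALSE)
  }

  structure(list(
    varcomp = varcomp, predictions = predictions, fixef = fixef,
    blup = blup_all, vg_cov = vg_cov, sigma2 = est,
    loglik = -0.5 * res$neg2, loglik_trace = trace,
    convergence = opt$convergence == 0L,
    iterations = iter_em + opt$counts[["function"]],
    n = mm$n, p = mm$p, qk = mm$qk, spec = spec,
    response = spec$response), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: %s, n = %d plots, logLik = %.3f (%s)\n",
              x$response, x$n, x$loglik,
              if (x$convergence) "converged" else "NOT converged"))
  vc <- x$varcomp
  vc$estimate <- signif(vc$estimate, 5)
  vc$pct_explained <- round(vc$pct_explained, 2)
  print(vc, row.names = FALSE)
  invisible(x)
}
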