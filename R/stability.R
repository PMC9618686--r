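## Genotype stability: Wricke's ecovalence and geometric adaptability ---------
##
## Both indices read the unscaled two-way table of adjusted means: Wi is a
## genotype's contribution to the interaction sum of squares (static
## stability, low = stable), GAI the geometric mean of its performance
## across environments (dynamic adaptability, high = good). GAI is only
## defined for genotypes whose cells are all positive.

#' Wricke's ecovalence
#'
#' `Wi = sum_j (x_ij - rowmean_i - colmean_j + grandmean)^2`, the row sum
#' of squared double-centred residuals, so that `sum_i Wi` equals the
#' interaction sum of squares exactly. An additional column reports each
#' genotype's percentage share of the interaction SS.
#'
#' @param t a complete, unscaled [two_way_table()].
#' @return A `stability_table` data.frame: genotype, mean, Wi, Wi_pct_gei.
#' @export
wricke <- function(t) {
  pt <- tw_parts(t)
  Wi <- rowSums(pt$D^2)
  out <- data.frame(genotype = rownames(pt$X), mean = rowMeans(pt$X),
                    Wi = unname(Wi),
                    Wi_pct_gei = if (pt$ss_int > 0) 100 * unname(Wi) / pt$ss_int
                                 else 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("stability_table", "data.frame"))
}

#' Geometric adaptability index
#'
#' `GAI_i = (prod_j x_ij)^(1/E)`, the geometric mean of genotype i across
#' the E environments, computed in log space. Genotypes with any
#' non-positive cell get a missing GAI with a warning. By the AM-GM
#' inequality, GAI never exceeds the arithmetic row mean.
#'
#' @param t a complete, unscaled [two_way_table()].
#' @return A `stability_table` data.frame: genotype, mean, GAI.
#' @export
gai <- function(t) {
  X <- unclass(t)
  if (anyNA(X)) stop_cfg("GAI needs a complete table")
  ok <- apply(X > 0, 1, all)
  g <- rep(NA_real_, nrow(X))
  g[ok] <- exp(rowMeans(log(X[ok, , drop = FALSE])))
  if (any(!ok)) {
    warning(sprintf("%d genotype(s) with non-positive cells: GAI missing",
                    sum(!ok)), call. = FALSE)
  }
  out <- data.frame(genotype = rownames(X), mean = rowMeans(X),
                    GAI = g, stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("stability_table", "data.frame"))
}

#' Combined stability table
#'
#' Wricke ecovalence and GAI side by side with their ranks: `Wi_rank`
#' ascending (1 = most stable), `GAI_rank` descending (1 = highest
#' adaptability). Ties are broken by genotype label.
#'
#' @param t a complete, unscaled [two_way_table()].
#' @return A `stability_table` data.frame: genotype, mean, Wi, Wi_pct_gei,
#'   Wi_rank, GAI, GAI_rank.
#' @export
stability_table <- function(t) {
  w <- wricke(t)
  g <- gai(t)
  out <- merge(as.data.frame(w), as.data.frame(g)[, c("genotype", "GAI")],
               by = "genotype", sort = TRUE)
  out$Wi_rank <- order(order(out$Wi, out$genotype))
  out$GAI_rank <- order(order(-out$GAI, out$genotype, na.last = TRUE))
  out <- out[, c("genotype", "mean", "Wi", "Wi_pct_gei", "Wi_rank",
                 "GAI", "GAI_rank")]
  structure(out, class = c("stability_table", "data.frame"))
}

#' Rank genotypes and apply the above-mean + stable selection rule
#'
#' Selects the top-k genotypes by the requested index (lowest Wi for
#' `"wi_top_k"`, highest GAI for `"gai_top_k"`), optionally intersected
#' with genotypes whose across-environment mean exceeds the population
#' mean — the selection rule for candidates that are both superior and
#' stable. When both indices are present, the overlap of their top-k sets
#' is reported as an attribute.
#'
#' @param s a `stability_table` (from [stability_table()], [wricke()] or
#'   [gai()]).
#' @param rule `"wi_top_k"` or `"gai_top_k"`.
#' @param k how many genotypes to select (clamped to the table size with a
#'   warning).
#' @param above_mean additionally require mean > population mean.
#' @return The table with `rank` and logical `selected` columns; attribute
#'   `top_k_overlap` lists genotypes in both indices' top-k when both are
#'   available.
#' @export
rank_and_select <- function(s, rule = c("wi_top_k", "gai_top_k"), k = 5L,
                            above_mean = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(s, "stability_table"))
  need <- if (rule == "wi_top_k") "Wi" else "GAI"
  if (!need %in% names(s)) stop_cfg("column %s not present in table", need)
  n <- nrow(s)
  if (k > n) {
    warning(sprintf("k clamped from %d to %d", k, n), call. = FALSE)
    k <- n
  }
  key <- if (rule == "wi_top_k") s$Wi else -s$GAI
  rk <- order(order(key, s$genotype, na.last = TRUE))
  sel <- rk <= k
  if (above_mean) sel <- sel & s$mean > mean(s$mean)
  s$rank <- rk
  s$selected <- sel
  if (all(c("Wi", "GAI") %in% names(s))) {
    top_wi <- s$genotype[order(s$Wi, s$genotype)][seq_len(k)]
    top_gai <- s$genotype[order(-s$GAI, s$genotype, na.last = TRUE)][seq_len(k)]
    attr(s, "top_k_overlap") <- intersect(top_wi, top_gai)
  }
  s
}
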