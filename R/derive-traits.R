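## Derived processed-product and yield traits ---------------------------------
##
## Conversion rates are ratios of recorded weights: the product weight as a
## percentage of the starting fresh-root weight loaded into processing.
## Yields convert plot root weight to tons/hectare through the per-plant
## ground area (plant spacing), using the count of plants actually
## harvested so that missing plants do not deflate yield.

# each derivation: output name, parent columns, function on the data.frame
.derivations <- list(
  gari_pct = list(
    parents = c("gari_weight", "starting_root_weight_gari"), units = "%",
    fn = function(d) 100 * d$gari_weight / d$starting_root_weight_gari,
    start = "starting_root_weight_gari", product = "gari_weight"),
  fufu_pct = list(
    parents = c("fufu_weight", "starting_root_weight_fufu"), units = "%",
    fn = function(d) 100 * d$fufu_weight / d$starting_root_weight_fufu,
    start = "starting_root_weight_fufu", product = "fufu_weight"),
  peel_loss_pct = list(
    parents = c("peel_weight", "starting_root_weight"), units = "%",
    fn = function(d) 100 * d$peel_weight / d$starting_root_weight,
    start = "starting_root_weight", product = "peel_weight"),
  fiber_content_pct = list(
    parents = c("dried_fiber_weight", "starting_root_weight_fufu"),
    units = "%",
    fn = function(d) 100 * d$dried_fiber_weight / d$starting_root_weight_fufu,
    start = "starting_root_weight_fufu", product = "dried_fiber_weight"),
  fyld = list(
    parents = c("RTWT", "n_plants_harvested"), units = "t/ha",
    fn = function(d, spacing_m2) {
      n <- d$n_plants_harvested
      n[!is.na(n) & n == 0L] <- NA # no plants harvested -> yield undefined
      d$RTWT / (n * spacing_m2) * 10
    }),
  dyld = list(
    parents = c("fyld", "dm"), units = "t/ha",
    fn = function(d) d$fyld * d$dm / 100),
  gari_yield = list(
    parents = c("fyld", "gari_pct"), units = "t/ha",
    fn = function(d) d$fyld * d$gari_pct / 100),
  fufu_yield = list(
    parents = c("fyld", "fufu_pct"), units = "t/ha",
    fn = function(d) d$fyld * d$fufu_pct / 100)
)

#' Derive processed-product and yield traits
#'
#' Adds, where the parent columns exist: gari and fufu conversion rates
#' (product weight as % of starting fresh-root weight), peel loss % and
#' fiber content %, fresh root yield `fyld` (t/ha) from plot root weight
#' `RTWT` (kg) adjusted by plant spacing, dry yield `dyld = fyld * dm/100`,
#' and product yields `gari_yield`, `fufu_yield`. Any record with a missing
#' parent gets a missing derived value, never an error; the operation is
#' idempotent (derived columns are recomputed from their parents).
#'
#' @param table a [pheno_table()].
#' @param spacing_m2 ground area per plant in m^2 (default 0.8).
#' @param net_plot_plants nominal net-plot plant count, used only to fill
#'   `n_plants_harvested` when that column is absent.
#' @return The table with derived trait columns added and registered.
#' @export
derive_traits <- function(table, spacing_m2 = 0.8, net_plot_plants = 20L) {
  stopifnot(inherits(table, "pheno_table"), spacing_m2 > 0)
  d <- as.data.frame(table)
  reg <- trait_registry(table)
  if (!"n_plants_harvested" %in% names(d) &&
      all(c("RTWT") %in% names(d))) {
    d$n_plants_harvested <- as.integer(net_plot_plants)
  }
  for (out in names(.derivations)) {
    dv <- .derivations[[out]]
    if (!all(dv$parents %in% names(d))) next
    if (!is.null(dv$start)) {
      bad <- !is.na(d[[dv$start]]) & d[[dv$start]] == 0 &
        !is.na(d[[dv$product]]) & d[[dv$product]] > 0
      if (any(bad)) {
        stop_cfg("%s recorded with zero %s in %d plot(s)",
                 dv$product, dv$start, sum(bad))
      }
    }
    val <- if (out == "fyld") dv$fn(d, spacing_m2) else dv$fn(d)
    d[[out]] <- as.numeric(val)
    reg <- register_trait(reg, out, dv$units, "derived")
  }
  pheno_table(d, registry = reg)
}
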