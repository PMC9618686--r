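## Long-format plot-level phenotype tables ------------------------------------
##
## A pheno_table is a data.frame with one row per field plot, keyed by
## (genotype, environment, rep, set), carrying design coordinates (row, col),
## the number of plants harvested, and one column per trait. A trait registry
## attribute records units and whether each trait is raw (measured) or
## derived (computed from raw parents).

.id_cols <- c("genotype", "environment", "rep", "set")

#' Default column-name dialect
#'
#' Maps the package's canonical column names to the names expected in an
#' input CSV. The default assumes cassavabase-style short labels as exported
#' from field books; override entries for files with different headers, e.g.
#' `default_dialect(genotype = "accession_name", environment = "studyName")`.
#'
#' @param ... named overrides, `canonical = "column-in-file"`.
#' @return Named character vector mapping canonical -> file column names.
#' @export
default_dialect <- function(...) {
  d <- c(genotype = "genotype", environment = "environment", rep = "rep",
         set = "set", row = "row", col = "col",
         n_plants_harvested = "n_plants_harvested")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop_cfg("unknown dialect entries: %s",
                              paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

new_trait_registry <- function(trait = character(), units = character(),
                               derivation = character()) {
  data.frame(trait = trait, units = units, derivation = derivation,
             stringsAsFactors = FALSE)
}

register_trait <- function(registry, trait, units, derivation) {
  registry <- registry[registry$trait != trait, , drop = FALSE]
  rbind(registry, new_trait_registry(trait, units, derivation))
}

#' Construct a phenotype table from a plot-level data frame
#'
#' @param df data.frame with at least `genotype`, `environment`, `rep`
#'   columns; `set`, `row`, `col`, `n_plants_harvested` are optional design
#'   columns, every other column is treated as a trait.
#' @param registry optional trait registry (data.frame with columns `trait`,
#'   `units`, `derivation`); traits not listed are registered as raw with
#'   unknown units.
#' @return A `pheno_table` (a data.frame subclass).
#' @export
pheno_table <- function(df, registry = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(c("genotype", "environment", "rep"), names(df))
  if (length(miss)) {
    stop_cfg("mandatory column(s) missing: %s", paste(miss, collapse = ", "))
  }
  if (!"set" %in% names(df)) df$set <- "S1"
  df$genotype <- as.character(df$genotype)
  df$environment <- as.character(df$environment)
  df$set <- as.character(df$set)
  df$rep <- as.integer(df$rep)
  for (cc in intersect(c("row", "col", "n_plants_harvested"), names(df))) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  key <- do.call(paste, c(df[.id_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    k <- strsplit(key[anyDuplicated(key)], "\r", fixed = TRUE)[[1]]
    stop_cfg(paste0("duplicate plot key (genotype=%s, environment=%s, ",
                    "rep=%s, set=%s)"), k[1], k[2], k[3], k[4])
  }
  traits <- setdiff(names(df),
                    c(.id_cols, "row", "col", "n_plants_harvested"))
  reg <- registry %||% new_trait_registry()
  for (tr in setdiff(traits, reg$trait)) {
    reg <- register_trait(reg, tr, "unknown", "raw")
  }
  reg <- reg[reg$trait %in% traits, , drop = FALSE]
  rownames(reg) <- NULL
  structure(df, trait_registry = reg,
            class = c("pheno_table", "data.frame"))
}

#' @export
print.pheno_table <- function(x, ...) {
  reg <- trait_registry(x)
  cat(sprintf("pheno_table: %d plots, %d genotypes, %d environments, %d traits\n",
              nrow(x), length(unique(x$genotype)),
              length(unique(x$environment)), nrow(reg)))
  cat("traits:", paste(reg$trait, collapse = ", "), "\n")
  invisible(x)
}

#' Trait registry of a phenotype table
#' @param x a `pheno_table`.
#' @return data.frame with columns `trait`, `units`, `derivation`.
#' @export
trait_registry <- function(x) attr(x, "trait_registry")

#' Read a long-format phenotype CSV
#'
#' One row per plot; column names resolved through a dialect map. All trait
#' columns are parsed as numeric; unparseable cells become `NA` and are
#' counted in a single warning rather than dropped, so downstream stages see
#' explicit missingness.
#'
#' @param path CSV file path.
#' @param dialect named character vector from [default_dialect()].
#' @return A [pheno_table()].
#' @export
read_pheno <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop_cfg("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  for (canon in names(dialect)) {
    fc <- dialect[[canon]]
    if (fc %in% names(raw) && canon != fc) {
      names(raw)[names(raw) == fc] <- canon
    }
  }
  mandatory <- c("genotype", "environment", "rep")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop_cfg("mandatory column(s) not resolvable via dialect: %s",
             paste(miss, collapse = ", "))
  }
  trait_cols <- setdiff(names(raw),
                        c(.id_cols, "row", "col", "n_plants_harvested"))
  n_bad <- 0L
  for (tc in trait_cols) {
    v <- suppressWarnings(as.numeric(raw[[tc]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[tc]]))
    raw[[tc]] <- v
  }
  if (n_bad > 0L) {
    warning(sprintf("%d unparseable trait cell(s) set to missing", n_bad),
            call. = FALSE)
  }
  pheno_table(raw)
}

#' Write any flat tabular result to CSV
#'
#' Writes with a header, deterministic column order and full double
#' precision (>= 10 significant digits) so that tables round-trip through
#' [read_pheno()] / `read.csv` without loss.
#'
#' @param obj a data.frame (including `pheno_table` and the package's result
#'   tables) or a matrix.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_table <- function(obj, path) {
  if (is.matrix(obj)) {
    obj <- data.frame(label = rownames(obj) %||% seq_len(nrow(obj)), obj,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(obj))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    write_csv_full(as.data.frame(obj), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_cfg("cannot write %s: %s", path,
                            conditionMessage(ok))
  invisible(path)
}
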