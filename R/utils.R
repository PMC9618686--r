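#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed and a key
#'
#' All randomness in the package flows from one master seed; independent
#' stages (design randomisation, genetic values, residuals per trait, ...)
#' draw from sub-streams keyed by name so that adding a stage never shifts
#' the draws of another.
#'
#' @param master integer master seed.
#' @param key character sub-stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

## round-trip safe CSV writing: full double precision, stable column order
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), NA, format(df[[j]], digits = 15L,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
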