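#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of the package draw their randomness from a single
#' master seed. Sub-seeds for individual samples, iterations or stages are
#' derived by combining the master seed with a stable string hash of the
#' labels identifying the draw, so that adding or reordering unrelated stages
#' never changes the stream used by an existing one.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer of the
#'   sub-seed, e.g. a sample id and an iteration index.
#' @return an integer seed in `[0, 2^31 - 20)`.
#' @export
#' @examples
#' derive_seed(42, "rarefy", "s001", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  parts <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1)), collapse = "/")
  h <- 0
  if (nzchar(parts)) {
    for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% 2147483629
  }
  as.integer((abs(seed) + h) %% 2147483629)
}

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV with fixed numeric formatting
#'
#' Doubles are written with 6 significant digits so that repeated pipeline
#' runs with the same seed produce byte-identical files.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
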