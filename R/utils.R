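# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  x
}

# Fixed-format TSV writer: 6 significant digits for doubles so that repeated
# runs with the same inputs produce byte-identical tables.
write_tsv6 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
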