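# Full-precision TSV writer: numbers survive a round trip bit-for-bit
# (17 significant digits), which the serialization contracts rely on.
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                scientific = TRUE,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Derive a stream of child seeds from one user-facing seed, all < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
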