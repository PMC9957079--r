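# Small fixtures built in code.

toy_counts <- function(nf = 30, ns = 4, seed = 1, libsize = 2e6) {
  set.seed(seed)
  p <- rlnorm(nf, 0, 1.5)
  p <- p / sum(p)
  m <- vapply(seq_len(ns), function(i) rnbinom(nf, mu = libsize * p, size = 20),
              numeric(nf))
  rownames(m) <- sprintf("hsa-miR-%d-5p", 100 + seq_len(nf))
  colnames(m) <- sprintf("S%d", seq_len(ns))
  count_table(m)
}

tiny_signature <- function(ct, k = 5) {
  signature_set(rownames(ct$counts)[seq_len(k)], label = "tiny")
}

write_counts_file <- function(ct, path, sep = "\t") {
  df <- data.frame(miRNA = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# expression matrix with controlled values for direct metric checks
fake_expr <- function(values_by_sample) {
  m <- do.call(cbind, values_by_sample)
  colnames(m) <- names(values_by_sample)
  m
}
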