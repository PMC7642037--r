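# Shared in-code fixtures; everything is generated, nothing is stored.

# tiny named expression matrix with a controllable seed
tiny_expression <- function(n_genes = 6L, n_samples = 5L, seed = 1L) {
  set.seed(seed)
  matrix(round(abs(rnorm(n_genes * n_samples, 5, 2)), 3),
         nrow = n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# correlation matrix with two planted blocks and near-zero background
planted_block_cm <- function(block_sizes = c(4L, 3L), within = 0.9,
                             between = 0.05) {
  n <- sum(block_sizes)
  genes <- sprintf("g%02d", seq_len(n))
  cm <- matrix(between, n, n, dimnames = list(genes, genes))
  at <- 1L
  for (size in block_sizes) {
    idx <- at:(at + size - 1L)
    cm[idx, idx] <- within
    at <- at + size
  }
  diag(cm) <- 1
  cm
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}

write_gff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

gff_row <- function(contig, start, end, strand, id, type = "gene") {
  paste(contig, "test", type, start, end, ".", strand, ".",
        paste0("ID=", id), sep = "\t")
}

# independent reverse complement (no Biostrings) for oracle checks
rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# adjusted Rand index between two label vectors (independent of any
# clustering package; pair-counting definition)
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
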