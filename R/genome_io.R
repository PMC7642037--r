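#' Read gene coordinates from a GFF3 file
#'
#' Parses records of the requested feature type (default `"gene"`) into a
#' coordinate table used for promoter extraction. The gene identifier is
#' taken from the `ID` attribute. Strand is mandatory because promoters are
#' strand-dependent.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to keep.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates, strand `+` or `-`).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  check_string(path, "path")
  if (!file.exists(path)) abort("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  rows <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) abort("malformed GFF3 record at line %d of %s", i, path)
    if (f[3L] != feature_type) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) abort("non-numeric coordinates at line %d of %s", i, path)
    if (start < 1L || start > end) {
      abort("invalid coordinates (need 1 <= start <= end) at line %d of %s", i, path)
    }
    if (!f[7L] %in% c("+", "-")) {
      abort("strand must be '+' or '-' (promoters are strand-dependent) at line %d of %s", i, path)
    }
    id <- sub("^.*(^|;)ID=([^;]+).*$", "\\2", f[9L])
    if (!grepl("(^|;)ID=", f[9L]) || !nzchar(id)) {
      abort("missing ID attribute at line %d of %s", i, path)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = id, contig_id = f[1L], start = start, end = end,
      strand = f[7L], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$gene_id)) {
    abort("duplicate gene id(s) in %s: %s", path,
          paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Extract promoter sequences upstream of annotated genes
#'
#' The promoter abuts the annotated transcription start: for a `+` strand
#' gene it is the `length` bases immediately 5' of `start`
#' (positions `start - length .. start - 1`, truncated at contig position 1);
#' for a `-` strand gene it is the reverse complement of positions
#' `end + 1 .. end + length`, truncated at the contig end. Sequences are
#' upper-cased; promoters are not clipped against neighbouring genes. Genes
#' with no upstream bases available are kept with an empty sequence (and a
#' warning) so the promoter universe stays consistent with the gene universe.
#'
#' @param genome_fasta Path to the genome FASTA file.
#' @param coords Coordinate table as returned by [read_gff_genes()].
#' @param length Promoter length: 1000, 2000 or 3000.
#' @return A `promoter_set`: list with `sequences` (named character vector),
#'   `requested_length`, and `actual_length` (named integer vector).
#' @export
extract_promoters <- function(genome_fasta, coords, length = 1000L) {
  if (!length %in% c(1000L, 2000L, 3000L)) {
    abort("promoter length must be 1000, 2000 or 3000, got %s", length)
  }
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- character(nrow(coords))
  names(seqs) <- coords$gene_id
  for (i in seq_len(nrow(coords))) {
    contig <- coords$contig_id[i]
    if (!contig %in% names(genome)) {
      abort("gene '%s' references unknown contig '%s'", coords$gene_id[i], contig)
    }
    clen <- length(genome[[contig]])
    if (coords$strand[i] == "+") {
      from <- max(1L, coords$start[i] - length)
      to <- coords$start[i] - 1L
    } else {
      from <- coords$end[i] + 1L
      to <- min(clen, coords$end[i] + length)
    }
    if (from > to) {
      warn("gene '%s' has no upstream sequence on contig '%s'; promoter is empty",
           coords$gene_id[i], contig)
      seqs[i] <- ""
      next
    }
    s <- Biostrings::subseq(genome[[contig]], from, to)
    if (coords$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- toupper(as.character(s))
  }
  structure(list(sequences = seqs,
                 requested_length = as.integer(length),
                 actual_length = setNames(nchar(seqs), names(seqs))),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, requested length %d (actual %d..%d)\n",
              length(x$sequences), x$requested_length,
              min(x$actual_length), max(x$actual_length)))
  invisible(x)
}
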