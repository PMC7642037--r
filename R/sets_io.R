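IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Read a gene-set collection from a GMT file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Members must be unique within a set and no set may be
#' empty.
#'
#' @param path Path to a GMT file.
#' @return A named list (by set id) of lists with `description` and
#'   `members`.
#' @export
read_gmt <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("GMT file is empty: %s", path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) abort("gene set '%s' is empty (line %d of %s)", f[1L], i, path)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) abort("gene set '%s' is empty (line %d of %s)", f[1L], i, path)
    if (anyDuplicated(members)) {
      abort("duplicate member(s) in gene set '%s': %s", f[1L],
            paste(unique(members[duplicated(members)]), collapse = ", "))
    }
    if (f[1L] %in% names(out)) abort("duplicate gene set id '%s' in %s", f[1L], path)
    out[[f[1L]]] <- list(description = f[2L], members = members)
  }
  out
}

#' Write a gene-set collection to a GMT file
#' @param collection Named list as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    paste(c(id, collection[[id]]$description, collection[[id]]$members),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif library from TSV
#'
#' Two tab-separated columns: motif id and IUPAC consensus string. Every
#' consensus letter must be one of `A C G T R Y S W K M B D H V N`.
#'
#' @param path Path to the motif TSV.
#' @return Named character vector: motif id -> consensus.
#' @export
read_motif_tsv <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort("motif file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("motif file is empty: %s", path)
  ids <- character(length(lines))
  cons <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || !nzchar(f[2L])) {
      abort("motif line %d of %s lacks a consensus", i, path)
    }
    ids[i] <- f[1L]
    cons[i] <- toupper(f[2L])
    letters_i <- strsplit(cons[i], "", fixed = TRUE)[[1L]]
    bad <- setdiff(letters_i, IUPAC_LETTERS)
    if (length(bad)) {
      abort("motif '%s' has invalid IUPAC letter(s): %s", ids[i],
            paste(bad, collapse = ", "))
    }
  }
  if (anyDuplicated(ids)) {
    abort("duplicate motif id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(cons, ids)
}

#' Write a motif library to TSV
#' @param motifs Named character vector of IUPAC consensus strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(motifs, path) {
  writeLines(paste(names(motifs), motifs, sep = "\t"), path)
  invisible(path)
}

#' Read a network edge list from TSV
#'
#' Columns: `gene_a`, `gene_b`, `pcc` and optionally `sign`
#' (`positive`/`negative`), with a header row. Edges are canonicalized so
#' that `gene_a < gene_b` lexicographically.
#'
#' @param path Path to the edge-list TSV.
#' @return A data.frame of edges in canonical order.
#' @export
read_edge_list <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort("edge list not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "pcc")
  if (!all(need %in% colnames(df))) {
    abort("edge list %s must have columns %s", path, paste(need, collapse = ", "))
  }
  if (!is.numeric(df$pcc)) abort("column 'pcc' in %s must be numeric", path)
  if (any(df$gene_a == df$gene_b)) abort("edge list %s contains self-loops", path)
  canonicalize_edges(df)
}

#' Write a network edge list to TSV
#' @param edges Data.frame with `gene_a`, `gene_b`, `pcc` (and optional
#'   further columns such as `sign`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  edges <- canonicalize_edges(edges)
  edges$pcc <- format_num(edges$pcc)
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
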