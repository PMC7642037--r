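#' Co-expression neighbours of a gene
#'
#' @param net A `coexpression_network`.
#' @param gene Gene id (must be a node of the network).
#' @param top_k Optional truncation: keep only the `top_k` strongest
#'   neighbours.
#' @return Data.frame `gene_id`, `pcc`, sorted by |pcc| descending (ties by
#'   gene id). Empty for an isolated gene that is in the network's gene
#'   universe.
#' @export
neighbors <- function(net, gene, top_k = NULL) {
  check_string(gene, "gene")
  edges <- net$edges
  universe <- if (!is.null(net$genes)) net$genes else net$nodes
  if (!gene %in% universe) abort("gene '%s' is not in the network", gene)
  hit <- edges$gene_a == gene | edges$gene_b == gene
  other <- ifelse(edges$gene_a[hit] == gene, edges$gene_b[hit], edges$gene_a[hit])
  out <- data.frame(gene_id = other, pcc = edges$pcc[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$pcc), out$gene_id), , drop = FALSE]
  if (!is.null(top_k)) {
    top_k <- check_count(top_k, "top_k", min = 1L)
    out <- head(out, top_k)
  }
  rownames(out) <- NULL
  out
}

#' Read an ortholog map from TSV
#'
#' Columns `source_gene`, `target_gene`, `bootstrap` (percent, 0-100) with
#' a header row.
#'
#' @param path Path to the TSV.
#' @return Data.frame of unique ortholog pairs.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("source_gene", "target_gene", "bootstrap")
  if (!all(need %in% colnames(df))) {
    abort("ortholog map %s must have columns %s", path, paste(need, collapse = ", "))
  }
  validate_ortholog_map(df)
}

validate_ortholog_map <- function(df) {
  if (!is.numeric(df$bootstrap) || any(df$bootstrap < 0) || any(df$bootstrap > 100)) {
    abort("bootstrap values must be percentages in [0, 100]")
  }
  if (anyDuplicated(df[, c("source_gene", "target_gene")])) {
    abort("ortholog pairs must be unique")
  }
  df
}

#' Count orthologous pairs between two gene neighbourhoods
#'
#' The number of (a, b) pairs with `a` in `list_a`, `b` in `list_b`, and
#' `a -> b` present in the (bootstrap-filtered) ortholog map — used to
#' compare a gene's co-expression neighbourhood across species.
#'
#' @param list_a Gene ids in the source species.
#' @param list_b Gene ids in the target species.
#' @param orthologs Ortholog map data.frame.
#' @param bootstrap_min Keep pairs with bootstrap strictly greater than
#'   this percentage (default 60).
#' @return Integer count of orthologous pairs.
#' @export
neighborhood_overlap <- function(list_a, list_b, orthologs, bootstrap_min = 60) {
  if (!length(list_a) || !length(list_b)) abort("both gene lists must be non-empty")
  om <- validate_ortholog_map(orthologs)
  om <- om[om$bootstrap > bootstrap_min, , drop = FALSE]
  sum(om$source_gene %in% list_a & om$target_gene %in% list_b)
}

#' Project a PPI network onto a target species through orthologs
#'
#' Interolog mapping: keep ortholog pairs with bootstrap strictly above
#' `bootstrap_min`; for every source interaction (s1, s2), emit every
#' target pair (t1, t2) with s1 -> t1 and s2 -> t2. Self-loops are dropped
#' and duplicate edges are collapsed (a union over multiple source networks
#' can be made by concatenating their edge lists first, keeping the
#' `provenance` column).
#'
#' @param source_edges Data.frame with columns `gene_a`, `gene_b` (source
#'   species interactions) and optionally `provenance`.
#' @param orthologs Ortholog map data.frame (`source_gene`, `target_gene`,
#'   `bootstrap`).
#' @param bootstrap_min Strict lower bound on bootstrap percent (default
#'   60).
#' @return Data.frame of target-species edges `gene_a`, `gene_b` (canonical
#'   order, deduplicated) plus `provenance` (comma-joined) when present in
#'   the input.
#' @export
project_ppi <- function(source_edges, orthologs, bootstrap_min = 60) {
  if (!all(c("gene_a", "gene_b") %in% colnames(source_edges))) {
    abort("source edges must have columns gene_a, gene_b")
  }
  om <- validate_ortholog_map(orthologs)
  om <- om[om$bootstrap > bootstrap_min, , drop = FALSE]
  targets <- split(om$target_gene, om$source_gene)
  has_prov <- "provenance" %in% colnames(source_edges)
  rows <- vector("list", nrow(source_edges))
  for (i in seq_len(nrow(source_edges))) {
    t1 <- targets[[source_edges$gene_a[i]]]
    t2 <- targets[[source_edges$gene_b[i]]]
    if (is.null(t1) || is.null(t2)) next
    g <- expand.grid(gene_a = t1, gene_b = t2, stringsAsFactors = FALSE)
    g <- g[g$gene_a != g$gene_b, , drop = FALSE]
    if (!nrow(g)) next
    if (has_prov) g$provenance <- source_edges$provenance[i]
    rows[[i]] <- g
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
    if (has_prov) out$provenance <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  if (has_prov) {
    key <- paste(out$gene_a, out$gene_b, sep = "\r")
    prov <- vapply(split(out$provenance, key), function(p) {
      paste(sort(unique(p)), collapse = ",")
    }, character(1L))
    out <- out[!duplicated(key), c("gene_a", "gene_b"), drop = FALSE]
    out$provenance <- unname(prov[paste(out$gene_a, out$gene_b, sep = "\r")])
  } else {
    out <- out[!duplicated(paste(out$gene_a, out$gene_b, sep = "\r")), , drop = FALSE]
  }
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Module membership lookup
#'
#' @param partition A `module_partition`.
#' @param gene Gene id.
#' @return List with `label` (module label, `"grey"` for unassigned) and
#'   `members` (all genes sharing that label).
#' @export
module_of <- function(partition, gene) {
  check_string(gene, "gene")
  if (!gene %in% names(partition$modules)) {
    abort("gene '%s' is not in the partition", gene)
  }
  label <- unname(partition$modules[[gene]])
  members <- names(partition$modules)[partition$modules == label]
  list(label = label, members = sort(members))
}
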