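#' Pearson correlation between two expression profiles
#'
#' Computes
#' \deqn{r_{xy} = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
#'   {\sqrt{\sum_i (x_i-\bar x)^2 \cdot \sum_i (y_i-\bar y)^2}}}
#' the linear correlation of two genes' expression values across samples.
#'
#' @param x,y Numeric vectors of equal length (>= 3 samples).
#' @return A number in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("'x' and 'y' must be numeric")
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  if (length(x) < 3L) abort("need at least 3 samples, got %d", length(x))
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    abort("correlation is undefined for a constant profile")
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  min(1, max(-1, r))
}

#' Pairwise correlation matrix over filtered genes
#'
#' Applies a minimal expression filter (a gene must reach `min_fpkm` in at
#' least `min_expressed_samples` samples), drops zero-variance genes, and
#' returns the gene x gene Pearson correlation matrix of the survivors.
#' Excluded gene ids are recorded in the `"excluded"` attribute.
#'
#' @param em Expression matrix (genes x samples).
#' @param min_expressed_samples Minimum number of samples at or above
#'   `min_fpkm` for a gene to be kept.
#' @param min_fpkm Expression threshold defining "expressed".
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `excluded` (named character vector of gene id -> reason).
#' @export
correlation_matrix <- function(em, min_expressed_samples = 2L, min_fpkm = 1) {
  em <- validate_expression_matrix(em)
  check_count(min_expressed_samples, "min_expressed_samples", min = 0L)
  check_number(min_fpkm, "min_fpkm", min = 0)
  expressed <- rowSums(em >= min_fpkm) >= min_expressed_samples
  constant <- rownames(em) %in% attr(em, "zero_variance")
  excluded <- c(
    setNames(rep("low_expression", sum(!expressed)), rownames(em)[!expressed]),
    setNames(rep("zero_variance", sum(expressed & constant)),
             rownames(em)[expressed & constant]))
  keep <- expressed & !constant
  if (sum(keep) < 2L) {
    abort("fewer than 2 genes survive the expression filter (%d of %d)",
          sum(keep), nrow(em))
  }
  cm <- cor(t(em[keep, , drop = FALSE]))
  cm[cm > 1] <- 1
  cm[cm < -1] <- -1
  diag(cm) <- 1
  attr(cm, "excluded") <- excluded
  cm
}

#' Density of an undirected simple graph
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_edges Number of edges.
#' @return `2 * n_edges / (n_nodes * (n_nodes - 1))`.
#' @export
network_density <- function(n_nodes, n_edges) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_edges <- check_count(n_edges, "n_edges", min = 0L)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    abort("%d edges exceed the maximum %d for %d nodes", n_edges, max_edges, n_nodes)
  }
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Scale-free topology fitting index
#'
#' Bins the positive degrees (or connectivities) into `n_bins` equal-width
#' bins, takes the mean degree and the frequency of each non-empty bin, and
#' returns the squared Pearson correlation between log10(frequency) and
#' log10(mean degree). Values near 1 indicate a power-law-like degree
#' distribution.
#'
#' @param degrees Non-negative numeric degree (or connectivity) values;
#'   zeros are ignored.
#' @param n_bins Number of equal-width bins (default 10).
#' @return The fit index in \[0, 1\], or `NA` when fewer than two non-empty
#'   bins (or fewer than two distinct positive degrees) are available.
#' @export
scale_free_fit <- function(degrees, n_bins = 10L) {
  if (!is.numeric(degrees) || any(degrees < 0)) {
    abort("'degrees' must be non-negative numbers")
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  d <- degrees[degrees > 0]
  if (length(unique(d)) < 2L) return(NA_real_)
  breaks <- seq(min(d), max(d), length.out = n_bins + 1L)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(d, bin, mean)
  freq <- tapply(d, bin, length) / length(d)
  ok <- !is.na(mean_k) & freq > 0
  if (sum(ok) < 2L) return(NA_real_)
  cor(log10(freq[ok]), log10(mean_k[ok]))^2
}

#' Scan correlation cutoffs for network size, density and scale-free fit
#'
#' For each candidate cutoff, thresholds the correlation matrix (edges with
#' `pcc >= cutoff` for the positive network; `pcc <= -|cutoff|` for the
#' negative network), and records the edge count, the number of non-isolated
#' nodes, the network density, and the scale-free fit of the degree
#' distribution. Two density denominators are reported: `density` over the
#' full scanned gene set (monotone non-increasing in the cutoff, used for
#' cutoff selection) and `density_connected` over the non-isolated nodes
#' only (comparable with the shrinking node counts, but not monotone when
#' nodes disappear faster than edges).
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param cutoffs Candidate cutoffs, sorted ascending in absolute value
#'   (e.g. `seq(0.6, 0.95, by = 0.05)`).
#' @param sign `"positive"` or `"negative"`.
#' @param n_bins Bins for [scale_free_fit()].
#' @return A data.frame (`threshold_scan`) with columns `cutoff`, `n_nodes`
#'   (non-isolated), `n_edges`, `density`, `density_connected`, `r_squared`.
#' @export
scan_thresholds <- function(cm, cutoffs, sign = c("positive", "negative"),
                            n_bins = 10L) {
  sign <- match.arg(sign)
  if (!is.numeric(cutoffs) || !length(cutoffs)) abort("'cutoffs' must be numeric")
  if (is.unsorted(abs(cutoffs))) abort("'cutoffs' must be sorted ascending in |value|")
  rows <- lapply(cutoffs, function(ct) {
    adj <- if (sign == "positive") cm >= abs(ct) else cm <= -abs(ct)
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    deg <- deg[deg > 0]
    n_edges <- sum(deg) / 2
    n_nodes <- length(deg)
    data.frame(
      cutoff = if (sign == "positive") abs(ct) else -abs(ct),
      n_nodes = n_nodes,
      n_edges = n_edges,
      density = network_density(nrow(cm), n_edges),
      density_connected = if (n_nodes >= 2L) network_density(n_nodes, n_edges)
                          else NA_real_,
      r_squared = if (n_nodes >= 2L) scale_free_fit(deg, n_bins) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_scan", "data.frame")
  attr(out, "sign") <- sign
  out
}

#' Select a correlation cutoff from a threshold scan
#'
#' Among scanned cutoffs whose network density does not exceed
#' `max_density`, returns the one maximizing the scale-free fit index; ties
#' are broken toward the smaller absolute cutoff (the denser, more
#' informative network).
#'
#' @param scan Result of [scan_thresholds()].
#' @param max_density Upper bound on acceptable network density.
#' @return The selected cutoff (signed as scanned).
#' @export
select_cutoff <- function(scan, max_density = 0.05) {
  check_number(max_density, "max_density", min = 0, max = 1)
  ok <- !is.na(scan$r_squared) & !is.na(scan$density) & scan$density <= max_density
  if (!any(ok)) {
    abort("no scanned cutoff satisfies density <= %s; raise the density bound",
          max_density)
  }
  cand <- scan[ok, , drop = FALSE]
  best <- cand[cand$r_squared == max(cand$r_squared), , drop = FALSE]
  best$cutoff[which.min(abs(best$cutoff))]
}

#' Build signed co-expression networks from a correlation matrix
#'
#' Edges are kept by strict inequality: `pcc > pos_cutoff` for the positive
#' network and `pcc < neg_cutoff` for the negative network. Self-loops are
#' excluded; isolated genes do not appear in the edge list but the total
#' filtered gene count is retained.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param pos_cutoff Positive cutoff in (0, 1\].
#' @param neg_cutoff Negative cutoff in \[-1, 0).
#' @return A list with elements `positive` and `negative`, each a
#'   `coexpression_network`: list of `sign`, `cutoff`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `pcc`), `nodes` (non-isolated gene ids) and
#'   `n_genes_total`.
#' @export
build_network <- function(cm, pos_cutoff = 0.8, neg_cutoff = -0.75) {
  check_number(pos_cutoff, "pos_cutoff")
  check_number(neg_cutoff, "neg_cutoff")
  if (pos_cutoff <= 0 || pos_cutoff > 1) abort("'pos_cutoff' must be in (0, 1]")
  if (neg_cutoff >= 0 || neg_cutoff < -1) abort("'neg_cutoff' must be in [-1, 0)")
  list(positive = one_network(cm, pos_cutoff, "positive"),
       negative = one_network(cm, neg_cutoff, "negative"))
}

one_network <- function(cm, cutoff, sign) {
  keep <- if (sign == "positive") cm > cutoff else cm < cutoff
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(cm)[idx[, 1L]],
                      gene_b = rownames(cm)[idx[, 2L]],
                      pcc = cm[idx],
                      stringsAsFactors = FALSE)
  edges <- canonicalize_edges(edges)
  rownames(edges) <- NULL
  structure(list(sign = sign,
                 cutoff = cutoff,
                 edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 genes = rownames(cm),
                 n_genes_total = nrow(cm)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("%s co-expression network: cutoff %s, %d nodes (%d genes total), %d edges\n",
              x$sign, format(x$cutoff), length(x$nodes), x$n_genes_total,
              nrow(x$edges)))
  invisible(x)
}

#' Write a co-expression network to an edge-list TSV
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  edges <- net$edges
  edges$sign <- rep(net$sign, nrow(edges))
  write_edge_list(edges, path)
}

#' Read a co-expression network from an edge-list TSV
#' @param path Path written by [write_network()].
#' @param cutoff,sign Optional metadata; inferred from the file when absent
#'   (`sign` from the `sign` column, `cutoff` as the least extreme pcc).
#' @return A `coexpression_network`.
#' @export
read_network <- function(path, cutoff = NULL, sign = NULL) {
  edges <- read_edge_list(path)
  if (is.null(sign)) {
    sign <- if ("sign" %in% colnames(edges) && nrow(edges)) {
      edges$sign[1L]
    } else if (nrow(edges) && edges$pcc[1L] < 0) "negative" else "positive"
  }
  if (is.null(cutoff)) {
    cutoff <- if (!nrow(edges)) NA_real_
              else if (sign == "positive") min(edges$pcc) else max(edges$pcc)
  }
  structure(list(sign = sign, cutoff = cutoff,
                 edges = edges[, c("gene_a", "gene_b", "pcc")],
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 n_genes_total = NA_integer_),
            class = "coexpression_network")
}
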