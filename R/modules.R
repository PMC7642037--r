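#' Module-detection configuration
#'
#' @param soft_power Soft-threshold exponent beta applied to |PCC|
#'   (default 7).
#' @param min_module_size Smallest cluster kept as a module; smaller
#'   clusters become `"grey"` (default 30).
#' @param cut_height Static dendrogram cut, as a fraction of the maximal
#'   merge height (default 0.9). Unclustered background genes sit at
#'   topological-overlap dissimilarity near 1 and, at typical sample sizes,
#'   reach chance overlap of a few percent with real modules; cutting well
#'   below the background plateau (module-internal merges happen far lower)
#'   keeps them out.
#' @param merge_cut_height Eigengene dissimilarity (1 - PCC) below which
#'   modules are merged (default 0.25).
#' @return A `detection_config` list.
#' @export
detection_config <- function(soft_power = 7L, min_module_size = 30L,
                             cut_height = 0.9, merge_cut_height = 0.25) {
  structure(list(
    soft_power = check_count(soft_power, "soft_power", min = 1L),
    min_module_size = check_count(min_module_size, "min_module_size", min = 2L),
    cut_height = check_number(cut_height, "cut_height", min = 1e-12, max = 1),
    merge_cut_height = check_number(merge_cut_height, "merge_cut_height",
                                    min = 0, max = 1)),
    class = "detection_config")
}

#' Soft-threshold scan: scale-free fit and mean connectivity per power
#'
#' For each candidate power, forms the unsigned weighted adjacency
#' `|PCC|^beta`, computes each gene's connectivity `k_i = sum_j a_ij`
#' (excluding the diagonal), and reports the scale-free fit of the
#' connectivity distribution together with its mean. Used to choose the
#' power at which the weighted network approximates scale-free topology.
#'
#' @param cm Correlation matrix.
#' @param powers Candidate integer powers (>= 1).
#' @param n_bins Bins for [scale_free_fit()].
#' @return Data.frame with columns `power`, `r_squared`,
#'   `mean_connectivity`.
#' @export
soft_threshold_scan <- function(cm, powers = 1:12, n_bins = 10L) {
  rows <- lapply(powers, function(p) {
    a <- adjacency(cm, p)
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(power = as.integer(p),
               r_squared = scale_free_fit(k, n_bins),
               mean_connectivity = mean(k))
  })
  do.call(rbind, rows)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |PCC_ij|^beta`, with unit diagonal.
#'
#' @param cm Correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
adjacency <- function(cm, beta = 7L) {
  beta <- check_count(beta, "beta", min = 1L)
  a <- abs(cm)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' where \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} counts shared
#' (weighted) neighbours and \eqn{k_i = \sum_{u \ne i} a_{iu}}.
#' `TOM_ii = 1`. Two genes are topologically similar when they are directly
#' connected and share neighbourhoods.
#'
#' @param a Symmetric adjacency with entries in \[0, 1\] and unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  if (!is.matrix(a) || !isSymmetric(unname(a), tol = 1e-8)) {
    abort("'a' must be a symmetric matrix")
  }
  if (any(a < 0) || any(a > 1)) abort("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  # (a0 %*% a0)[i, j] = sum_u a_iu a_uj with the u = i and u = j terms zero
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (l + a0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cluster genes into modules from a TOM matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at `cut_height` (a fraction of the maximal merge height). Clusters
#' smaller than `min_module_size` are labelled `"grey"`; the rest are
#' labelled `M1`, `M2`, ... in decreasing size order.
#'
#' @param tom TOM similarity matrix with gene ids as dimnames.
#' @param config A [detection_config()].
#' @return A `module_partition`: list with `modules` (named character
#'   vector gene -> label), `eigengenes` (`NULL` until computed) and
#'   `config`.
#' @export
cluster_modules <- function(tom, config = detection_config()) {
  if (is.null(rownames(tom))) abort("'tom' must have gene ids as dimnames")
  genes <- rownames(tom)
  if (length(genes) < config$min_module_size) {
    warn("fewer genes (%d) than min_module_size (%d); all genes are grey",
         length(genes), config$min_module_size)
    labels <- setNames(rep("grey", length(genes)), genes)
  } else {
    hc <- hclust(as.dist(1 - tom), method = "average")
    h <- config$cut_height * max(hc$height)
    cl <- cutree(hc, h = h)
    labels <- relabel_by_size(cl, config$min_module_size)
  }
  structure(list(modules = labels, eigengenes = NULL, config = config),
            class = "module_partition")
}

# Relabel raw cluster ids: clusters below the size floor -> grey, others
# M1, M2, ... in decreasing size order (ties broken by smallest member id
# for determinism).
relabel_by_size <- function(cl, min_size) {
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  first_gene <- vapply(keep, function(k) min(names(cl)[cl == k]), character(1L))
  ord <- keep[order(-as.integer(sizes[keep]), first_gene)]
  map <- setNames(paste0("M", seq_along(ord)), ord)
  out <- rep("grey", length(cl))
  hit <- as.character(cl) %in% names(map)
  out[hit] <- map[as.character(cl)[hit]]
  setNames(out, names(cl))
}

#' Module eigengene
#'
#' The first principal component of the module's gene x sample expression
#' submatrix after per-gene standardization (mean 0, sd 1 across samples),
#' returned as a unit-length vector over samples. The sign is fixed so the
#' eigengene correlates non-negatively with the module's mean standardized
#' profile, making results deterministic.
#'
#' @param em Expression matrix.
#' @param members Gene ids of the module (all must be rows of `em`).
#' @return Numeric vector, one value per sample, unit Euclidean norm.
#' @export
module_eigengene <- function(em, members) {
  missing <- setdiff(members, rownames(em))
  if (length(missing)) {
    abort("module member(s) absent from the expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  x <- em[members, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (all(sds == 0)) abort("all module members have constant expression")
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  v <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
  mean_profile <- colMeans(z)
  if (sum(v * mean_profile) < 0) v <- -v
  setNames(v, colnames(em))
}

#' Compute eigengenes for every non-grey module of a partition
#'
#' @param em Expression matrix.
#' @param partition A `module_partition`.
#' @return The partition with its `eigengenes` slot filled (matrix,
#'   modules x samples).
#' @export
compute_eigengenes <- function(em, partition) {
  labs <- setdiff(unique(partition$modules), "grey")
  labs <- labs[order(as.integer(sub("^M", "", labs)))]
  eg <- t(vapply(labs, function(l) {
    module_eigengene(em, names(partition$modules)[partition$modules == l])
  }, numeric(ncol(em))))
  rownames(eg) <- labs
  partition$eigengenes <- eg
  partition
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - PCC(E_i, E_j)` is below `merge_cut_height`,
#' recomputing the merged module's eigengene after each merge, until no
#' pair qualifies. Grey genes are never merged into a module. Labels are
#' reassigned by size after merging.
#'
#' @param em Expression matrix.
#' @param partition A `module_partition`.
#' @param merge_cut_height Dissimilarity threshold; defaults to the value
#'   in the partition's config.
#' @return The merged `module_partition` with updated eigengenes.
#' @export
merge_modules <- function(em, partition, merge_cut_height = NULL) {
  if (is.null(merge_cut_height)) merge_cut_height <- partition$config$merge_cut_height
  check_number(merge_cut_height, "merge_cut_height", min = 0, max = 1)
  labels <- partition$modules
  repeat {
    labs <- setdiff(unique(labels), "grey")
    if (length(labs) < 2L) break
    eg <- t(vapply(labs, function(l) {
      module_eigengene(em, names(labels)[labels == l])
    }, numeric(ncol(em))))
    diss <- 1 - cor(t(eg))
    diag(diss) <- Inf
    if (min(diss) >= merge_cut_height) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    from <- labs[max(idx)]
    to <- labs[min(idx)]
    labels[labels == from] <- to
  }
  # relabel by size, M1 largest
  cl <- labels
  cl[cl == "grey"] <- NA
  sizes <- sort(table(cl), decreasing = TRUE)
  map <- setNames(paste0("M", seq_along(sizes)), names(sizes))
  merged <- ifelse(is.na(cl), "grey", map[cl])
  partition$modules <- setNames(merged, names(labels))
  compute_eigengenes(em, partition)
}

#' Detect functional modules in one call
#'
#' Runs the full weighted-network pipeline: correlation matrix, unsigned
#' soft-thresholded adjacency, topological overlap, average-linkage
#' clustering with a static cut, eigengene computation, and eigengene-based
#' module merging.
#'
#' @param em Expression matrix.
#' @param config A [detection_config()].
#' @param min_expressed_samples,min_fpkm Expression filter passed to
#'   [correlation_matrix()].
#' @return A merged `module_partition` (genes dropped by the expression
#'   filter are labelled `"grey"`).
#' @export
detect_modules <- function(em, config = detection_config(),
                           min_expressed_samples = 2L, min_fpkm = 1) {
  cm <- correlation_matrix(em, min_expressed_samples, min_fpkm)
  a <- adjacency(cm, config$soft_power)
  tom <- tom_similarity(a)
  part <- cluster_modules(tom, config)
  part <- merge_modules(em, part)
  dropped <- setdiff(rownames(em), names(part$modules))
  if (length(dropped)) {
    part$modules <- c(part$modules, setNames(rep("grey", length(dropped)), dropped))
  }
  part
}

#' @export
print.module_partition <- function(x, ...) {
  labs <- setdiff(unique(x$modules), "grey")
  cat(sprintf("module_partition: %d modules over %d genes (%d grey)\n",
              length(labs), length(x$modules), sum(x$modules == "grey")))
  if (length(labs)) {
    sizes <- sort(table(x$modules[x$modules != "grey"]), decreasing = TRUE)
    print(sizes)
  }
  invisible(x)
}

#' Write a module partition (and its eigengenes) to TSV
#' @param partition A `module_partition`.
#' @param path Output path for the gene -> module table.
#' @param eigengene_path Optional output path for the module x sample
#'   eigengene table.
#' @return `path`, invisibly.
#' @export
write_modules <- function(partition, path, eigengene_path = NULL) {
  df <- data.frame(gene_id = names(partition$modules),
                   module = unname(partition$modules),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eigengene_path) && !is.null(partition$eigengenes)) {
    eg <- data.frame(module = rownames(partition$eigengenes),
                     apply(partition$eigengenes, 2L, format_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(eg, eigengene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
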