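#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' belong to the set:
#' \deqn{P(X = k) = \frac{\binom{n}{k}\binom{N-n}{K-k}}{\binom{N}{K}}}
#' Computed in log space for numerical stability. Impossible configurations
#' (`K - k > N - n`) return 0.
#'
#' @param N Universe size.
#' @param K Genes in the annotated set.
#' @param n Query size.
#' @param k Overlap (may be a vector).
#' @return Probability (vectorized over `k`).
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  N <- check_count(N, "N", min = 0L)
  K <- check_count(K, "K", min = 0L)
  n <- check_count(n, "n", min = 0L)
  if (K > N) abort("K (%d) exceeds N (%d)", K, N)
  if (n > N) abort("n (%d) exceeds N (%d)", n, N)
  if (any(k != round(k)) || any(k < 0)) abort("'k' must be non-negative integers")
  if (any(k > pmin(n, K))) abort("'k' exceeds min(n, K)")
  out <- numeric(length(k))
  feasible <- (K - k) <= (N - n)
  kk <- k[feasible]
  out[feasible] <- exp(lchoose(n, kk) + lchoose(N - n, K - kk) - lchoose(N, K))
  out
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' `P(X >= k)`: the probability of an overlap at least as large as
#' observed, the p-value used for over-representation.
#'
#' @inheritParams hypergeom_pmf
#' @return The upper-tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  k <- check_count(k, "k", min = 0L)
  if (k == 0L) return(1)
  i <- k:min(n, K)
  min(1, sum(hypergeom_pmf(N, K, n, i)))
}

#' One-sided Fisher's exact test for enrichment on a 2x2 table
#'
#' Table layout: `(k, n-k; K-k, N-n-K+k)` — query/non-query by in-set/out-of-set.
#' The one-sided (greater) p-value coincides with the hypergeometric upper
#' tail on the same margins.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return One-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  fisher.test(tab, alternative = "greater")$p.value
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Statistic `sum((O - E)^2 / E)` on 1 degree of freedom, upper-tail
#' p-value. No continuity correction by default.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- check_2x2(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e == 0)) {
    abort("a zero expected count makes the chi-squared test invalid; use the exact test")
  }
  d <- abs(tab - e)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("table cells must be non-negative integers")
  }
  tab
}

ADJUST_METHODS <- c(bonferroni = "bonferroni", holm = "holm",
                    hochberg = "hochberg", hommel = "hommel",
                    BH = "BH", BY = "BY")

#' Adjust p-values for multiple testing
#'
#' Supports Bonferroni, Holm, Hochberg, Hommel, Benjamini-Hochberg (`BH`)
#' and Benjamini-Yekutieli (`BY`). Input order is preserved and adjusted
#' values are capped at 1.
#'
#' @param p P-values in (0, 1\].
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`, `"hommel"`,
#'   `"BH"`, `"BY"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  method <- match.arg(method, names(ADJUST_METHODS))
  p.adjust(p, method = ADJUST_METHODS[[method]])
}

#' Gene-set over-representation analysis
#'
#' Tests a query gene list against every set in a collection. For each set
#' with at least one overlapping gene (all sets when `include_empty`), the
#' p-value is the hypergeometric upper tail, the one-sided Fisher exact
#' test, or the chi-squared test on the induced 2x2 table; p-values are
#' then adjusted across all tested sets.
#'
#' @param query Character vector of query gene ids.
#' @param collection Gene-set collection from [read_gmt()].
#' @param universe Character vector of background gene ids. Defaults to the
#'   union of all collection members (the annotated universe).
#' @param test `"hypergeometric"`, `"fisher"` or `"chisq"`.
#' @param correction Correction method for [adjust_pvalues()].
#' @param include_empty Also test (and count toward the correction) sets
#'   with zero overlap.
#' @return Data.frame sorted by raw p-value (ties by set id) with columns
#'   `set_id`, `description`, `N`, `K`, `n`, `k`, `p_raw`, `p_adjusted`,
#'   `overlap_genes` (comma-separated).
#' @export
gsea <- function(query, collection,
                 universe = NULL,
                 test = c("hypergeometric", "fisher", "chisq"),
                 correction = "BH",
                 include_empty = FALSE) {
  test <- match.arg(test)
  if (!length(collection)) abort("the gene-set collection is empty")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(collection, `[[`, "members"))))
  }
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    if (length(outside) == length(query)) {
      abort("no query gene is present in the background universe")
    }
    warn("%d query gene(s) absent from the universe were excluded: %s",
         length(outside), paste(head(outside, 5L), collapse = ", "))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]]$members, universe)
    K <- length(members)
    overlap <- intersect(query, members)
    k <- length(overlap)
    data.frame(set_id = id, description = collection[[id]]$description,
               N = N, K = K, n = n, k = k,
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$K > 0L, , drop = FALSE]
  if (!include_empty) res <- res[res$k > 0L, , drop = FALSE]
  if (!nrow(res)) {
    warn("no gene set overlaps the query; nothing to test")
    res$p_raw <- numeric(0)
    res$p_adjusted <- numeric(0)
    return(res[, c("set_id", "description", "N", "K", "n", "k",
                   "p_raw", "p_adjusted", "overlap_genes")])
  }
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    with(res[i, ], switch(test,
      hypergeometric = hypergeom_tail(N, K, n, k),
      fisher = fisher_exact_2x2(matrix(c(k, K - k, n - k, N - n - K + k), 2L)),
      chisq = chisq_2x2(matrix(c(k, K - k, n - k, N - n - K + k), 2L))$p_value))
  }, numeric(1L))
  res$p_adjusted <- adjust_pvalues(res$p_raw, correction)
  res <- res[order(res$p_raw, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_id", "description", "N", "K", "n", "k",
          "p_raw", "p_adjusted", "overlap_genes")]
}
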