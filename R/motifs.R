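#' Count motif matches in a promoter sequence
#'
#' Counts every position (overlaps allowed) where the IUPAC consensus
#' matches the forward strand, plus every match of the consensus against
#' the reverse complement of the sequence. Degenerate motif letters match
#' their IUPAC base sets; an `N` in the sequence matches only the motif
#' letter `N`. Palindromic matches therefore count once per strand.
#'
#' @param sequence DNA string over `A C G T N` (lowercase accepted).
#' @param consensus IUPAC consensus string.
#' @return Integer match count (0 when the motif is longer than the
#'   sequence).
#' @export
scan_motif <- function(sequence, consensus) {
  check_string(sequence, "sequence")
  check_string(consensus, "consensus")
  validate_consensus(consensus)
  sequence <- toupper(sequence)
  if (nchar(consensus) > nchar(sequence) || nchar(sequence) == 0L) return(0L)
  subj <- Biostrings::DNAString(sequence)
  fixed <- c(pattern = FALSE, subject = TRUE)
  fwd <- Biostrings::countPattern(consensus, subj, fixed = fixed)
  rev <- Biostrings::countPattern(consensus, Biostrings::reverseComplement(subj),
                                  fixed = fixed)
  as.integer(fwd + rev)
}

validate_consensus <- function(consensus) {
  letters_c <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  if (!length(letters_c)) abort("motif consensus must be non-empty")
  bad <- setdiff(letters_c, IUPAC_LETTERS)
  if (length(bad)) {
    abort("invalid IUPAC letter(s) in consensus '%s': %s", consensus,
          paste(bad, collapse = ", "))
  }
  invisible(consensus)
}

#' Per-promoter match counts for a motif library
#'
#' Builds the motif x gene matrix of [scan_motif()] counts over a promoter
#' set — the workhorse shared by the observed statistic and the empirical
#' null, computed once per universe.
#'
#' @param promoters A `promoter_set`.
#' @param motifs Named character vector of IUPAC consensus strings.
#' @return Integer matrix, motifs in rows, genes in columns.
#' @export
motif_count_matrix <- function(promoters, motifs) {
  stopifnot(inherits(promoters, "promoter_set"))
  for (m in motifs) validate_consensus(m)
  subj <- Biostrings::DNAStringSet(toupper(promoters$sequences))
  rc <- Biostrings::reverseComplement(subj)
  fixed <- c(pattern = FALSE, subject = TRUE)
  counts <- t(vapply(motifs, function(cons) {
    Biostrings::vcountPattern(cons, subj, fixed = fixed) +
      Biostrings::vcountPattern(cons, rc, fixed = fixed)
  }, integer(length(subj))))
  dimnames(counts) <- list(names(motifs), names(promoters$sequences))
  counts
}

#' Mean motif match count over a gene list
#'
#' @param promoters A `promoter_set`.
#' @param genes Gene ids to average over.
#' @param consensus IUPAC consensus of one motif.
#' @return Arithmetic mean match count per promoter.
#' @export
mean_matches <- function(promoters, genes, consensus) {
  stopifnot(inherits(promoters, "promoter_set"))
  missing <- setdiff(genes, names(promoters$sequences))
  if (length(missing)) {
    if (length(missing) == length(genes)) {
      abort("none of the listed genes has a promoter entry")
    }
    warn("%d gene(s) without a promoter entry were excluded: %s",
         length(missing), paste(head(missing, 5L), collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  mean(vapply(promoters$sequences[genes], scan_motif, integer(1L),
              consensus = consensus))
}

#' Empirical null model for motif match counts
#'
#' Draws `B` random gene lists of size `n` (uniformly, without replacement
#' within a list) from the promoter universe and, for each motif, pools the
#' per-gene match counts of all `B * n` sampled promoters into a null mean
#' `mu` and standard deviation `sigma`. With `pooling = "per_list_mean"`
#' the null is instead built from the `B` list means (the alternative
#' reading of the sampling scheme).
#'
#' @param promoters A `promoter_set` (the gene universe).
#' @param motifs Named character vector of consensus strings.
#' @param n Query size the null must match.
#' @param B Number of random gene lists (default 1000).
#' @param seed Random seed; the null is deterministic given the seed.
#' @param pooling `"per_gene"` (default) or `"per_list_mean"`.
#' @param counts Optional precomputed [motif_count_matrix()] for these
#'   promoters and motifs.
#' @return A `motif_null`: list with `mu` and `sigma` (named by motif),
#'   `B`, `n`, `promoter_length`, `pooling`, `seed`.
#' @export
build_null <- function(promoters, motifs, n, B = 1000L, seed = NULL,
                       pooling = c("per_gene", "per_list_mean"),
                       counts = NULL) {
  pooling <- match.arg(pooling)
  n <- check_count(n, "n", min = 1L)
  B <- check_count(B, "B", min = 1L)
  universe <- names(promoters$sequences)
  if (n > length(universe)) {
    abort("query size %d exceeds the promoter universe (%d genes)", n,
          length(universe))
  }
  if (is.null(counts)) counts <- motif_count_matrix(promoters, motifs)
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) sample.int(length(universe), n),
           integer(n))
  })
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
  idx <- as.vector(draws)
  if (pooling == "per_gene") {
    pooled <- counts[, idx, drop = FALSE]
    mu <- rowMeans(pooled)
    sigma <- apply(pooled, 1L, sd)
  } else {
    list_means <- vapply(seq_len(B), function(b) {
      rowMeans(counts[, draws[, b], drop = FALSE])
    }, numeric(nrow(counts)))
    if (is.null(dim(list_means))) list_means <- matrix(list_means, nrow = 1L)
    mu <- rowMeans(list_means)
    sigma <- apply(list_means, 1L, sd)
  }
  structure(list(mu = setNames(mu, names(motifs)),
                 sigma = setNames(sigma, names(motifs)),
                 B = B, n = n,
                 promoter_length = promoters$requested_length,
                 pooling = pooling, seed = seed),
            class = "motif_null")
}

#' Standardized motif enrichment score
#'
#' `Z = (x_bar - mu) / (sigma / sqrt(n))`: the observed mean match count of
#' the query, standardized against the empirical null of random gene lists
#' of the same size.
#'
#' @param x_bar Observed mean match count over the query promoters.
#' @param mu,sigma Null mean and standard deviation per promoter.
#' @param n Query size.
#' @return The Z score (`NA` when `sigma` is 0).
#' @export
motif_z <- function(x_bar, mu, sigma, n) {
  check_number(x_bar, "x_bar")
  check_number(mu, "mu")
  check_number(sigma, "sigma", min = 0)
  n <- check_count(n, "n", min = 1L)
  if (sigma == 0) return(NA_real_)
  (x_bar - mu) / (sigma / sqrt(n))
}

#' Upper-tail probability of a motif Z score
#'
#' `P = 1 - Phi(Z)`, the probability under the null of a query mean at
#' least as large as observed (equivalently
#' `1 - Pnorm(x_bar; mu, sigma / sqrt(n))`).
#'
#' @param z Z score from [motif_z()].
#' @return Upper-tail probability in \[0, 1\].
#' @export
motif_p <- function(z) {
  check_number(z, "z")
  pnorm(z, lower.tail = FALSE)
}

#' Promoter motif (cis-element) enrichment for a gene list
#'
#' For every motif: the mean match count over the query genes' promoters is
#' compared with an empirical null built from `B` random gene lists of the
#' same size drawn from the promoter universe, giving a Z score and an
#' upper-tail normal P value. Motifs with `P < 0.05` are flagged
#' significant. A motif whose null is degenerate (`sigma = 0`, e.g. absent
#' from every promoter) gets `z = NA`, `P` of 1 (or 0 if the observed mean
#' still exceeds the null mean) and `degenerate = TRUE`.
#'
#' @param query Gene ids to test.
#' @param promoters A `promoter_set` covering the gene universe.
#' @param motifs Named character vector of consensus strings.
#' @param B Number of null gene lists (default 1000).
#' @param seed Random seed for the null draws.
#' @param pooling Null pooling mode, see [build_null()].
#' @param alpha Significance level on P (default 0.05).
#' @param counts Optional precomputed [motif_count_matrix()] for these
#'   promoters and motifs (a pure cache; results are identical).
#' @return Data.frame sorted by P: `motif_id`, `consensus`, `x_bar`, `mu`,
#'   `sigma`, `n`, `z`, `p`, `significant`, `degenerate`.
#' @export
motif_enrich <- function(query, promoters, motifs, B = 1000L, seed = NULL,
                         pooling = c("per_gene", "per_list_mean"),
                         alpha = 0.05, counts = NULL) {
  pooling <- match.arg(pooling)
  query <- unique(query)
  missing <- setdiff(query, names(promoters$sequences))
  if (length(missing)) {
    if (length(missing) == length(query)) {
      abort("no query gene has a promoter entry")
    }
    warn("%d query gene(s) without promoters were excluded", length(missing))
    query <- setdiff(query, missing)
  }
  if (is.null(counts)) counts <- motif_count_matrix(promoters, motifs)
  null <- build_null(promoters, motifs, n = length(query), B = B, seed = seed,
                     pooling = pooling, counts = counts)
  x_bar <- rowMeans(counts[, query, drop = FALSE])
  res <- data.frame(motif_id = names(motifs),
                    consensus = unname(motifs),
                    x_bar = unname(x_bar),
                    mu = unname(null$mu),
                    sigma = unname(null$sigma),
                    n = length(query),
                    stringsAsFactors = FALSE)
  res$z <- ifelse(res$sigma > 0,
                  (res$x_bar - res$mu) / (res$sigma / sqrt(res$n)),
                  NA_real_)
  res$p <- ifelse(res$sigma > 0, pnorm(res$z, lower.tail = FALSE),
                  ifelse(res$x_bar > res$mu, 0, 1))
  res$degenerate <- res$sigma == 0
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
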