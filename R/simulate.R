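#' Simulation specification
#'
#' Defines the synthetic study: blocks of co-regulated genes sharing a
#' latent sample profile, background noise genes, and a promoter universe
#' with an optional planted motif. Defaults emulate a mid-sized plant
#' expression compendium (~40 RNA-seq samples) with five co-expression
#' modules whose within-module expected correlation is
#' `signal_sd^2 / (signal_sd^2 + noise_sd^2) = 0.8`, and a 500-gene
#' promoter universe of 1-kb promoters with a 20-motif library.
#'
#' @param n_genes Total genes in the expression matrix.
#' @param n_samples Number of samples.
#' @param module_sizes Sizes of the planted co-expression blocks.
#' @param signal_sd Standard deviation of each block's shared latent
#'   profile.
#' @param noise_sd Standard deviation of per-gene independent noise.
#' @param n_promoters Genes in the promoter universe.
#' @param promoter_length Promoter length (1000, 2000 or 3000).
#' @param gene_body_length Length of the simulated gene body on each
#'   contig.
#' @param n_motifs Motifs in the simulated library.
#' @param motif_length Length of each simulated motif.
#' @param planted_motif Index of the motif planted into enriched
#'   promoters.
#' @param planted_copies Copies planted per enriched promoter.
#' @param enriched_set_size Number of promoters carrying the planted
#'   motif.
#' @param seed Random seed driving every generator.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 2000L, n_samples = 40L,
                     module_sizes = c(200L, 160L, 120L, 90L, 60L),
                     signal_sd = 2, noise_sd = 1,
                     n_promoters = 500L, promoter_length = 1000L,
                     gene_body_length = 300L,
                     n_motifs = 20L, motif_length = 6L,
                     planted_motif = 1L, planted_copies = 3L,
                     enriched_set_size = 30L,
                     seed = 1L) {
  spec <- list(n_genes = check_count(n_genes, "n_genes", min = 2L),
               n_samples = check_count(n_samples, "n_samples", min = 3L),
               module_sizes = vapply(module_sizes, check_count,
                                     integer(1L), name = "module_sizes", min = 1L),
               signal_sd = check_number(signal_sd, "signal_sd", min = 0),
               noise_sd = check_number(noise_sd, "noise_sd", min = 0),
               n_promoters = check_count(n_promoters, "n_promoters", min = 1L),
               promoter_length = check_count(promoter_length, "promoter_length", min = 10L),
               gene_body_length = check_count(gene_body_length, "gene_body_length", min = 1L),
               n_motifs = check_count(n_motifs, "n_motifs", min = 1L),
               motif_length = check_count(motif_length, "motif_length", min = 2L),
               planted_motif = check_count(planted_motif, "planted_motif", min = 1L),
               planted_copies = check_count(planted_copies, "planted_copies", min = 0L),
               enriched_set_size = check_count(enriched_set_size, "enriched_set_size", min = 1L),
               seed = check_count(seed, "seed"))
  if (sum(spec$module_sizes) > spec$n_genes) {
    abort("module sizes sum to %d, more than n_genes = %d",
          sum(spec$module_sizes), spec$n_genes)
  }
  if (spec$planted_motif > spec$n_motifs) abort("planted_motif exceeds n_motifs")
  if (spec$enriched_set_size > spec$n_promoters) {
    abort("enriched_set_size exceeds n_promoters")
  }
  if (spec$planted_copies * spec$motif_length > spec$promoter_length) {
    abort("planted copies do not fit in the promoter")
  }
  structure(spec, class = "sim_spec")
}

#' Simulate a block-structured expression matrix
#'
#' Each block's genes share a latent per-sample profile
#' (`N(0, signal_sd^2)`) plus independent gene-level noise
#' (`N(0, noise_sd^2)`); remaining genes are pure noise. Values are shifted
#' by the global minimum to a non-negative FPKM-like scale (correlations
#' are shift-invariant, so the planted structure is preserved).
#'
#' @param spec A [sim_spec()].
#' @return List with `expression` (gene x sample matrix) and `truth`
#'   (named character vector gene -> block label, `"grey"` for noise
#'   genes).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    truth <- setNames(rep("grey", spec$n_genes), genes)
    x <- matrix(rnorm(spec$n_genes * spec$n_samples, sd = spec$noise_sd),
                nrow = spec$n_genes,
                dimnames = list(genes, sprintf("s%02d", seq_len(spec$n_samples))))
    at <- 1L
    for (b in seq_along(spec$module_sizes)) {
      size <- spec$module_sizes[b]
      latent <- rnorm(spec$n_samples, sd = spec$signal_sd)
      rows <- at:(at + size - 1L)
      x[rows, ] <- x[rows, ] + rep(latent, each = size)
      truth[rows] <- paste0("M", b)
      at <- at + size
    }
    x <- x - min(x)
    list(expression = x, truth = truth)
  })
}

#' Simulate a promoter universe with a planted motif
#'
#' Generates uniform-random promoter sequences, a concrete motif library,
#' and a genome FASTA + GFF3 pair laid out one gene per contig (alternating
#' strands) so that promoter extraction through the standard io path
#' reproduces the generated sequences exactly. Copies of the planted motif
#' are written at random non-overlapping positions into the promoters of
#' the enriched gene set.
#'
#' @param spec A [sim_spec()].
#' @param dir Directory for `genome.fa`, `genes.gff3` and `motifs.tsv`
#'   (created if needed).
#' @return List with `promoters` (a `promoter_set`), `motifs` (named
#'   character vector), `enriched_genes`, `planted_motif` (motif id),
#'   and the file paths `genome_fasta`, `gff3`, `motif_tsv`.
#' @export
simulate_promoters <- function(spec, dir = tempfile("simfix")) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed(spec$seed + 1L, {
    genes <- sprintf("p%04d", seq_len(spec$n_promoters))
    motifs <- setNames(vapply(seq_len(spec$n_motifs), function(i) {
      paste(sample(bases, spec$motif_length, replace = TRUE), collapse = "")
    }, character(1L)), sprintf("MOT%03d", seq_len(spec$n_motifs)))
    planted_id <- names(motifs)[spec$planted_motif]
    planted <- motifs[[planted_id]]
    enriched <- sample(genes, spec$enriched_set_size)
    seqs <- vapply(genes, function(g) {
      paste(sample(bases, spec$promoter_length, replace = TRUE), collapse = "")
    }, character(1L))
    if (spec$planted_copies > 0L) {
      m <- spec$motif_length
      n_slots <- spec$promoter_length %/% m
      for (g in enriched) {
        slots <- sample.int(n_slots, spec$planted_copies)
        s <- seqs[[g]]
        for (sl in slots) {
          substr(s, (sl - 1L) * m + 1L, sl * m) <- planted
        }
        seqs[[g]] <- s
      }
    }
    # one contig per gene; even-numbered genes on the minus strand
    contigs <- character(spec$n_promoters)
    gff <- character(spec$n_promoters)
    body_pool <- function() paste(sample(bases, spec$gene_body_length,
                                         replace = TRUE), collapse = "")
    for (i in seq_along(genes)) {
      body <- body_pool()
      contig_id <- sprintf("ctg%04d", i)
      if (i %% 2L == 1L) {
        contigs[i] <- paste0(seqs[[i]], body)
        start <- spec$promoter_length + 1L
        end <- spec$promoter_length + spec$gene_body_length
        strand <- "+"
      } else {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seqs[[i]])))
        contigs[i] <- paste0(body, rc)
        start <- 1L
        end <- spec$gene_body_length
        strand <- "-"
      }
      gff[i] <- paste(contig_id, "coexfun_sim", "gene", start, end, ".",
                      strand, ".", paste0("ID=", genes[i]), sep = "\t")
    }
    genome_fasta <- file.path(dir, "genome.fa")
    writeLines(as.vector(rbind(sprintf(">ctg%04d", seq_along(genes)), contigs)),
               genome_fasta)
    gff3 <- file.path(dir, "genes.gff3")
    writeLines(c("##gff-version 3", gff), gff3)
    motif_tsv <- file.path(dir, "motifs.tsv")
    write_motif_tsv(motifs, motif_tsv)
    promoters <- structure(list(
      sequences = seqs,
      requested_length = as.integer(spec$promoter_length),
      actual_length = setNames(nchar(seqs), genes)),
      class = "promoter_set")
    list(promoters = promoters, motifs = motifs,
         enriched_genes = enriched, planted_motif = planted_id,
         genome_fasta = genome_fasta, gff3 = gff3, motif_tsv = motif_tsv)
  })
}

#' Simulate a correlation matrix with a planted scale-free graph
#'
#' Generates a Barabasi-Albert preferential-attachment graph and fills a
#' symmetric correlation-like matrix: planted edges get correlations drawn
#' uniformly from `edge_range`, non-edges from `background_range`. Scanning
#' cutoffs inside `edge_range` then prunes the planted graph progressively
#' while keeping its heavy-tailed degree structure, which is what cutoff
#' selection by scale-free fit assumes.
#'
#' @param n_genes Number of genes (nodes).
#' @param m Edges added per step of preferential attachment.
#' @param edge_range Correlation range for planted edges.
#' @param background_range Correlation range for non-edges.
#' @param seed Random seed.
#' @return Symmetric matrix with unit diagonal and gene ids as dimnames.
#' @export
simulate_scale_free_cm <- function(n_genes = 1500L, m = 3L,
                                   edge_range = c(0.6, 1),
                                   background_range = c(0, 0.5),
                                   seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 3L)
  with_seed(seed, {
    g <- igraph::sample_pa(n_genes, m = m, directed = FALSE)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    genes <- sprintf("g%04d", seq_len(n_genes))
    cm <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    up <- upper.tri(cm)
    n_up <- sum(up)
    vals <- runif(n_up, background_range[1L], background_range[2L])
    edge_up <- adj[up]
    vals[edge_up] <- runif(sum(edge_up), edge_range[1L], edge_range[2L])
    cm[up] <- vals
    cm <- cm + t(cm)
    diag(cm) <- 1
    cm
  })
}

#' Simulate an annotation collection from a truth partition
#'
#' Emits one gene set per non-grey block. With `contamination > 0`, that
#' fraction of each set's members is swapped for random genes outside the
#' block, weakening (but usually not destroying) the enrichment signal.
#'
#' @param truth Named character vector gene -> block label (from
#'   [simulate_expression()]).
#' @param contamination Fraction of each set's members replaced by random
#'   outside genes, in \[0, 1).
#' @param seed Random seed for the contamination swaps.
#' @return A gene-set collection (same shape as [read_gmt()]).
#' @export
simulate_annotation <- function(truth, contamination = 0, seed = 1L) {
  check_number(contamination, "contamination", min = 0, max = 1 - 1e-9)
  labs <- setdiff(unique(truth), "grey")
  labs <- labs[order(labs)]
  universe <- names(truth)
  with_seed(seed, {
    out <- list()
    for (l in labs) {
      members <- names(truth)[truth == l]
      if (!length(members)) next
      if (contamination > 0) {
        n_swap <- floor(contamination * length(members))
        if (n_swap > 0L) {
          drop <- sample(members, n_swap)
          pool <- setdiff(universe, members)
          add <- sample(pool, n_swap)
          members <- c(setdiff(members, drop), add)
        }
      }
      out[[paste0("SET_", l)]] <- list(
        description = sprintf("genes of simulated block %s", l),
        members = sort(members))
    }
    out
  })
}
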