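test_that("pearson implements the product-moment formula", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
})

test_that("correlation_matrix matches a per-pair loop and reports exclusions", {
  set.seed(5)
  em <- matrix(abs(rnorm(50 * 20, 10, 4)), 50,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  cm <- correlation_matrix(em, min_expressed_samples = 0L, min_fpkm = 0)
  expect_identical(rownames(cm), rownames(em))
  for (i in seq(1, 41, by = 10)) {
    for (j in seq(2, 50, by = 9)) {
      if (i == j) next
      expect_equal(cm[i, j], pearson(em[i, ], em[j, ]), tolerance = 1e-10)
    }
  }
  expect_true(isSymmetric(unname(cm)))
  expect_true(all(diag(cm) == 1))
  expect_true(all(abs(cm) <= 1))
})

test_that("the expression filter excludes constant and unexpressed genes", {
  em <- tiny_expression(4L, 6L, seed = 2L)
  em["g02", ] <- 7          # constant
  em["g03", ] <- 0.01       # never reaches min_fpkm
  em <- validate_expression_matrix(em)
  cm <- correlation_matrix(em, min_expressed_samples = 2L, min_fpkm = 1)
  expect_identical(sort(rownames(cm)), c("g01", "g04"))
  excl <- attr(cm, "excluded")
  expect_identical(unname(excl["g02"]), "zero_variance")
  expect_identical(unname(excl["g03"]), "low_expression")

  em2 <- em[c("g02", "g03", "g01"), ]
  expect_error(correlation_matrix(validate_expression_matrix(em2)),
               "fewer than 2 genes")
})

test_that("a duplicated profile correlates perfectly with itself", {
  em <- tiny_expression(3L, 6L, seed = 3L)
  em["g02", ] <- em["g01", ]
  cm <- correlation_matrix(validate_expression_matrix(em),
                           min_expressed_samples = 0L, min_fpkm = 0)
  expect_equal(cm["g01", "g02"], 1)
})

test_that("network_density is 2E / (N(N-1))", {
  expect_equal(network_density(4, 3), 0.5)
  expect_equal(network_density(10, 0), 0)
  expect_equal(network_density(5, 10), 1)
  expect_error(network_density(4, 7), "exceed")
})

test_that("scale_free_fit is high for a power law and low for constant-p graphs", {
  degs <- rep(1:100, times = round(1e5 / (1:100)^2))
  expect_gte(scale_free_fit(degs), 0.95)

  expect_true(is.na(scale_free_fit(rep(4, 50))))

  set.seed(9)
  er <- rbinom(2000, 1999, 0.01)
  expect_lt(scale_free_fit(er[er > 0]), scale_free_fit(degs))
})

test_that("scale_free_fit equals an independent binned log-log regression", {
  d <- c(1, 1, 1, 1, 2, 2, 3)
  got <- scale_free_fit(d, n_bins = 3L)
  bins <- cut(d, breaks = seq(1, 3, length.out = 4), include.lowest = TRUE)
  mk <- tapply(d, bins, mean)
  fr <- tapply(d, bins, length) / length(d)
  oracle <- summary(lm(log10(fr) ~ log10(mk)))$r.squared
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("threshold scans are monotone and match per-cutoff recomputation", {
  cm <- planted_block_cm(c(10L, 8L), within = 0.85, between = 0.2)
  set.seed(1)
  jitter <- matrix(runif(nrow(cm)^2, -0.05, 0.05), nrow(cm))
  jitter <- (jitter + t(jitter)) / 2
  cm <- cm + jitter
  cm[cm > 1] <- 1
  cm[cm < -1] <- -1
  diag(cm) <- 1
  cutoffs <- c(0.3, 0.5, 0.7, 0.9)
  scan <- scan_thresholds(cm, cutoffs, "positive")

  expect_true(all(diff(scan$n_edges) <= 0))
  for (i in seq_along(cutoffs)) {
    adj <- cm >= cutoffs[i]
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    deg <- deg[deg > 0]
    expect_equal(scan$n_edges[i], sum(deg) / 2)
    expect_equal(scan$n_nodes[i], length(deg))
    expect_equal(scan$density[i], network_density(nrow(cm), sum(deg) / 2))
    if (length(deg) >= 2) {
      expect_equal(scan$density_connected[i],
                   network_density(length(deg), sum(deg) / 2))
    }
  }
  expect_true(all(diff(scan$density) <= 0))
})

test_that("an empty graph at a cutoff yields a row with undefined fit", {
  cm <- diag(4)
  dimnames(cm) <- list(paste0("g", 1:4), paste0("g", 1:4))
  scan <- scan_thresholds(cm, c(0.5, 0.9), "positive")
  expect_equal(scan$n_edges, c(0, 0))
  expect_true(all(is.na(scan$r_squared)))
})

test_that("select_cutoff maximizes fit under the density bound with ties to smaller cutoffs", {
  scan <- data.frame(cutoff = c(0.6, 0.8, 0.9),
                     n_nodes = c(100, 80, 50),
                     n_edges = c(500, 40, 12),
                     density = c(0.10, 0.01, 0.005),
                     r_squared = c(0.50, 0.90, 0.85))
  expect_equal(select_cutoff(scan, max_density = 0.05), 0.8)
  expect_error(select_cutoff(scan, max_density = 0.001), "density")

  ties <- transform(scan, r_squared = 0.9, density = 0.01)
  expect_equal(select_cutoff(ties, max_density = 0.05), 0.6)
})

test_that("a 0.6..0.95 grid with the fit peaking at 0.8 selects 0.8", {
  grid <- seq(0.6, 0.95, by = 0.05)
  scan <- data.frame(cutoff = grid,
                     n_nodes = 200 - 20 * seq_along(grid),
                     n_edges = 2000 %/% seq_along(grid),
                     density = seq(0.04, 0.005, length.out = length(grid)),
                     r_squared = c(0.55, 0.65, 0.75, 0.82, 0.91, 0.88, 0.86, 0.80))
  expect_equal(select_cutoff(scan, max_density = 0.05), 0.8)
})

test_that("build_network applies strict cutoffs and keeps blocks separate", {
  cm <- planted_block_cm(c(4L, 3L), within = 0.9, between = 0.1)
  cm["g01", "g02"] <- cm["g02", "g01"] <- 0.8     # exactly at the cutoff
  cm["g05", "g06"] <- cm["g06", "g05"] <- -0.8
  nets <- build_network(cm, pos_cutoff = 0.8, neg_cutoff = -0.75)

  pos <- nets$positive$edges
  expect_false(any(pos$gene_a == "g01" & pos$gene_b == "g02"))
  expect_true(all(pos$pcc > 0.8))

  neg <- nets$negative$edges
  expect_equal(nrow(neg), 1L)
  expect_equal(neg$pcc, -0.8)

  # positive edges only within the planted blocks
  block <- function(g) ifelse(g <= "g04", 1L, 2L)
  expect_true(all(block(pos$gene_a) == block(pos$gene_b)))
  expect_true(all(pos$gene_a < pos$gene_b))
  expect_equal(nets$positive$n_genes_total, 7L)
})

test_that("networks round-trip through edge-list TSV", {
  cm <- planted_block_cm(c(4L, 3L))
  nets <- build_network(cm, 0.8, -0.75)
  tf <- tempfile(fileext = ".tsv")
  write_network(nets$positive, tf)
  back <- read_network(tf)
  expect_equal(back$edges$gene_a, nets$positive$edges$gene_a)
  expect_equal(back$edges$pcc, nets$positive$edges$pcc, tolerance = 1e-6)
  expect_identical(back$sign, "positive")
})
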