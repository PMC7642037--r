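test_that("adjacency raises |PCC| to the soft power", {
  cm <- matrix(c(1, -0.5, -0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacency(cm, 7)["a", "b"], 0.0078125)
  expect_equal(adjacency(cm, 1), abs(cm))
  cm[1, 2] <- cm[2, 1] <- 1
  expect_true(all(adjacency(cm, 12) == 1))
})

test_that("soft-threshold scan reports shrinking mean connectivity", {
  cm <- planted_block_cm(c(20L, 15L), within = 0.8, between = 0.3)
  scan <- soft_threshold_scan(cm, powers = c(1L, 4L, 7L))
  expect_true(all(diff(scan$mean_connectivity) <= 0))

  eye <- diag(5)
  dimnames(eye) <- list(paste0("g", 1:5), paste0("g", 1:5))
  scan0 <- soft_threshold_scan(eye, powers = c(1L, 7L))
  expect_equal(scan0$mean_connectivity, c(0, 0))
})

test_that("TOM matches a brute-force triple loop", {
  set.seed(21)
  n <- 30L
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  tom <- tom_similarity(a)

  oracle <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(unname(tom), oracle, tolerance = 1e-10)
  expect_true(isSymmetric(unname(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_true(all(diag(tom) == 1))
})

test_that("TOM limiting cases: full overlap and no overlap", {
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(tom_similarity(ones) == 1))

  a <- diag(4)
  dimnames(a) <- list(letters[1:4], letters[1:4])
  tom <- tom_similarity(a)
  expect_true(all(tom[upper.tri(tom)] == 0))

  chain <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  chain[1, 2] <- chain[2, 1] <- 0.5
  chain[2, 3] <- chain[3, 2] <- 0.5
  diag(chain) <- 1
  tom <- tom_similarity(chain)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(tom[1, 3], 0.25 / 1.5)
})

test_that("planted blocks are recovered as modules, invariant to gene order", {
  spec <- sim_spec(n_genes = 130L, n_samples = 60L,
                   module_sizes = c(50L, 50L), signal_sd = 2, noise_sd = 1,
                   seed = 31L)
  sim <- simulate_expression(spec)
  config <- detection_config(min_module_size = 30L)
  cm <- correlation_matrix(sim$expression, min_expressed_samples = 0L,
                           min_fpkm = 0)
  tom <- tom_similarity(adjacency(cm, config$soft_power))
  part <- cluster_modules(tom, config)

  labs <- setdiff(unique(part$modules), "grey")
  expect_equal(length(labs), 2L)
  for (b in c("M1", "M2")) {
    truth_b <- names(sim$truth)[sim$truth == b]
    rec <- unique(part$modules[truth_b])
    expect_length(rec, 1L)
    expect_true(rec != "grey")
  }

  perm <- sample(rownames(tom))
  part2 <- cluster_modules(tom[perm, perm], config)
  agree <- table(part$modules[perm], part2$modules)
  expect_equal(sum(agree > 0 & outer(rownames(agree) != "grey",
                                     colnames(agree) != "grey")),
               length(labs))
})

test_that("raising the static cut toward 1 absorbs background genes into modules", {
  spec <- sim_spec(n_genes = 400L, n_samples = 40L,
                   module_sizes = c(80L, 60L), seed = 32L)
  sim <- simulate_expression(spec)
  cm <- correlation_matrix(sim$expression, 0L, 0)
  tom <- tom_similarity(adjacency(cm, 7L))
  n_assigned <- vapply(c(0.9, 0.99), function(ch) {
    part <- cluster_modules(tom, detection_config(cut_height = ch))
    sum(part$modules != "grey")
  }, numeric(1L))
  expect_gt(n_assigned[2L], n_assigned[1L])

  part90 <- cluster_modules(tom, detection_config(cut_height = 0.9))
  rec <- part90$modules[names(sim$truth)]
  ng <- rec != "grey"
  expect_gte(adjusted_rand(rec[ng], sim$truth[ng]), 0.9)
})

test_that("too-few or uncorrelated genes all end up grey", {
  set.seed(11)
  em <- matrix(abs(rnorm(10 * 20, 10)), 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  cm <- correlation_matrix(em, 0L, 0)
  tom <- tom_similarity(adjacency(cm, 7))
  expect_warning(part <- cluster_modules(tom, detection_config(min_module_size = 30L)),
                 "grey")
  expect_true(all(part$modules == "grey"))
})

test_that("module eigengene is the leading singular vector with fixed sign", {
  spec <- sim_spec(n_genes = 20L, n_samples = 15L, module_sizes = 20L,
                   seed = 41L)
  em <- simulate_expression(spec)$expression
  eg <- module_eigengene(em, rownames(em))
  expect_equal(sum(eg^2), 1, tolerance = 1e-12)

  z <- t(scale(t(em)))
  sv <- svd(z)$v[, 1L]
  expect_equal(abs(unname(eg)), abs(sv), tolerance = 1e-8)
  expect_gte(cor(eg, colMeans(z)), 0)
})

test_that("eigengene degenerate cases: identical profiles and single genes", {
  em <- tiny_expression(4L, 8L, seed = 6L)
  em["g02", ] <- em["g01", ] * 2   # same standardized profile
  em["g03", ] <- em["g01", ] + 1
  eg <- module_eigengene(em, c("g01", "g02", "g03"))
  prof <- unname(scale(em["g01", ])[, 1L])
  expect_equal(unname(eg), prof / sqrt(sum(prof^2)), tolerance = 1e-8)

  single <- module_eigengene(em, "g04")
  prof4 <- unname(scale(em["g04", ])[, 1L])
  expect_equal(unname(single), prof4 / sqrt(sum(prof4^2)), tolerance = 1e-10)

  expect_error(module_eigengene(em, c("g01", "nope")), "nope")
})

test_that("modules with similar eigengenes merge; dissimilar ones do not", {
  set.seed(51)
  n_s <- 30L
  latent1 <- rnorm(n_s, sd = 2)
  latent2 <- rnorm(n_s, sd = 2)
  mk_block <- function(latent, n, prefix) {
    m <- t(replicate(n, latent + rnorm(n_s, sd = 0.5)))
    rownames(m) <- paste0(prefix, seq_len(n))
    m
  }
  em <- rbind(mk_block(latent1, 10L, "a"), mk_block(latent1, 10L, "b"),
              mk_block(latent2, 10L, "c"))
  em <- em - min(em)
  colnames(em) <- paste0("s", seq_len(n_s))
  labels <- setNames(rep(c("M1", "M2", "M3"), each = 10L), rownames(em))
  part <- structure(list(modules = labels, eigengenes = NULL,
                         config = detection_config(min_module_size = 5L)),
                    class = "module_partition")

  merged <- merge_modules(em, part, merge_cut_height = 0.25)
  labs <- setdiff(unique(merged$modules), "grey")
  expect_equal(length(labs), 2L)
  # the two same-latent blocks share a label, the third stays apart
  expect_equal(unique(merged$modules[paste0("a", 1:10)]),
               unique(merged$modules[paste0("b", 1:10)]))
  expect_false(unique(merged$modules[paste0("c", 1:10)]) %in%
               unique(merged$modules[paste0("a", 1:10)]))
})

test_that("three mutually similar modules collapse into one; grey is preserved", {
  set.seed(52)
  n_s <- 25L
  latent <- rnorm(n_s, sd = 2)
  em <- t(replicate(31L, latent + rnorm(n_s, sd = 0.4)))
  em[31L, ] <- rnorm(n_s)   # a grey gene
  em <- em - min(em)
  dimnames(em) <- list(sprintf("g%02d", 1:31), paste0("s", seq_len(n_s)))
  labels <- setNames(c(rep(c("M1", "M2", "M3"), each = 10L), "grey"),
                     rownames(em))
  part <- structure(list(modules = labels, eigengenes = NULL,
                         config = detection_config(min_module_size = 5L)),
                    class = "module_partition")
  merged <- merge_modules(em, part, merge_cut_height = 0.25)
  expect_equal(setdiff(unique(merged$modules), "grey"), "M1")
  expect_identical(unname(merged$modules[["g31"]]), "grey")
  expect_lte(length(unique(merged$modules)), length(unique(labels)))
})
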