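test_that("signed adjacency matches its closed form and the naive oracle", {
  # perfectly correlated, anti-correlated and orthogonal profiles
  v <- c(1, 2, 3, 4, 5, 6)
  w <- c(1, -1, 1, -1, 1, -1)  # orthogonal to the linear trend? check via cor
  expr <- rbind(up = v, up2 = 2 * v + 3, down = -v, osc = w)
  a <- signed_adjacency(expr, beta = 6)
  expect_equal(a["up", "up2"], 1)                # cor = +1
  expect_equal(a["up", "down"], 0, tolerance = 1e-12)  # cor = -1
  r <- cor(v, w)
  expect_equal(a["up", "osc"], ((1 + r) / 2)^6, tolerance = 1e-12)
  expect_equal(diag(a), rep(1, 4), ignore_attr = TRUE)
  expect_equal(a, t(a))
  # cor = 0 -> (1/2)^6
  expect_equal(((1 + 0) / 2)^6, 0.015625)

  set.seed(11)
  rnd <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(signed_adjacency(rnd, 6), adjacency_oracle(rnd, 6),
               tolerance = 1e-10, ignore_attr = TRUE)
  # signed-hybrid variant kills negative correlation without inflating it
  h <- signed_adjacency(rnd, 6, type = "signed_hybrid")
  rr <- cor(t(rnd))
  expect_equal(h[2, 3], max(rr[2, 3], 0)^6, tolerance = 1e-12)
  # zero-variance gene is a named error
  bad <- rbind(rnd, flat = rep(1, 8))
  expect_error(signed_adjacency(bad, 6), "flat")
})

test_that("topological overlap matches hand computation and the triple loop", {
  # 3-gene toy: hand-computed from the definition
  a <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.5,
                0.3, 0.5, 1), 3, 3)
  tom <- tom_similarity(a)
  # connectivities: k1 = 1.1, k2 = 1.3, k3 = 0.8
  expect_equal(tom[1, 2], (0.3 * 0.5 + 0.8) / (min(1.1, 1.3) + 1 - 0.8),
               tolerance = 1e-12)
  expect_equal(tom[1, 3], (0.8 * 0.5 + 0.3) / (min(1.1, 0.8) + 1 - 0.3),
               tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))

  # identical binary rows with a_ij = 1 -> perfect overlap, TOM = 1
  a2 <- matrix(c(1, 1, 1,
                 1, 1, 1,
                 1, 1, 1), 3, 3)
  expect_equal(tom_similarity(a2)[1, 2], 1, tolerance = 1e-12)

  # no direct edge, no shared neighbours -> TOM = 0
  a3 <- diag(3); a3[1, 2] <- a3[2, 1] <- 0  # fully disconnected off-diagonal
  expect_equal(tom_similarity(a3)[1, 2], 0)

  set.seed(21)
  rnd <- matrix(runif(100), 10, 10)
  rnd <- (rnd + t(rnd)) / 2; diag(rnd) <- 1
  expect_equal(tom_similarity(rnd), tom_oracle(rnd), tolerance = 1e-10)
  expect_true(all(tom_similarity(rnd) >= 0 & tom_similarity(rnd) <= 1 + 1e-12))
})

test_that("planted correlation blocks are recovered as modules", {
  sim <- simulate_blocks(n_blocks = 2, block_size = 50, n_noise = 0,
                         n_samples = 60, within_cor = 0.8, seed = 31)
  tom <- tom_similarity(signed_adjacency(sim$expr, 6))
  labels <- detect_modules(tom, min_module_size = 10, cut_height = 0.95)
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_gte(rand_index(labels, sim$labels), 0.95)
  # permutation invariance up to label renaming
  perm <- sample(nrow(sim$expr))
  labels_p <- detect_modules(tom[perm, perm], 10, 0.95)
  expect_gte(rand_index(labels_p, labels[perm]), 0.999)
})

test_that("unstructured and degenerate inputs get the boundary labels", {
  set.seed(41)
  noise <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(paste0("g", 1:60), NULL))
  tom <- tom_similarity(signed_adjacency(noise, 6))
  labels <- detect_modules(tom, min_module_size = 10, cut_height = 0.7)
  expect_true(all(labels == 0))  # no structure -> all unassigned
  # one tight block -> one module holding everything
  v <- rnorm(30)
  block <- t(sapply(1:20, function(i) v + rnorm(30, 0, 0.05)))
  rownames(block) <- paste0("b", 1:20)
  tom2 <- tom_similarity(signed_adjacency(block, 6))
  lab2 <- detect_modules(tom2, min_module_size = 10, cut_height = 0.95)
  expect_true(all(lab2 == 1))
})

test_that("module eigengenes satisfy the variance and sign contracts", {
  set.seed(51)
  v <- rnorm(25)
  # rank-1 module: all members equal to v (plus tiny jitter for variance)
  mod <- t(sapply(1:6, function(i) v))
  rownames(mod) <- paste0("g", 1:6)
  e <- module_eigengene(mod, rownames(mod))
  expect_equal(sd(e), 1, tolerance = 1e-9)
  expect_equal(abs(cor(e, v)), 1, tolerance = 1e-9)
  expect_gt(mean(cor(e, t(mod))), 0)       # sign convention
  # v and -v in equal numbers: orientation still coherent, |cor| = 1
  mod2 <- rbind(mod[1:3, ], -mod[1:3, ])
  rownames(mod2) <- paste0("g", 1:6)
  e2 <- module_eigengene(mod2, rownames(mod2))
  expect_equal(abs(as.numeric(cor(e2, v))), 1, tolerance = 1e-9)
  # random module: unit variance
  rnd <- matrix(rnorm(8 * 25), 8, 25, dimnames = list(paste0("r", 1:8), NULL))
  expect_equal(sd(module_eigengene(rnd, rownames(rnd))), 1, tolerance = 1e-9)
  # zero-variance member dropped with a warning
  rnd2 <- rbind(rnd, flat = rep(2, 25))
  expect_warning(module_eigengene(rnd2, rownames(rnd2)), "flat")
})

test_that("module-trait correlation matches the textbook t formula", {
  set.seed(61)
  n <- 40
  trait <- rep(c(1, 0), each = n / 2)
  e <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("m", 1:3), NULL))
  res <- module_trait_correlation(e, trait)
  for (i in 1:3) {
    r <- cor(e[i, ], trait)
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(res$r[i], r, tolerance = 1e-12)
    expect_equal(res$p_value[i], 2 * pt(-abs(t), n - 2), tolerance = 1e-12)
    # agrees with cor.test as an independent check
    ct <- cor.test(e[i, ], trait)
    expect_equal(res$p_value[i], ct$p.value, tolerance = 1e-9)
  }
  # eigengene equal to the trait coding -> r = 1
  res1 <- module_trait_correlation(matrix(trait, 1), trait)
  expect_equal(res1$r, 1)
  expect_lt(res1$p_value, 1e-20)
  # orthogonal by construction -> r = 0
  orth <- trait - mean(trait)
  orth <- rnorm(n)
  orth <- orth - sum(orth * (trait - mean(trait))) /
    sum((trait - mean(trait))^2) * (trait - mean(trait))
  expect_lt(abs(module_trait_correlation(matrix(orth, 1), trait)$r), 1e-10)
  expect_error(module_trait_correlation(e, rep(1, n)), "constant")
  expect_error(module_trait_correlation(matrix(rep(1, n), 1), trait),
               "constant eigengene")
})

test_that("hypergeometric ORA matches exact enumeration", {
  background <- paste0("g", 1:20)
  sets <- list(hit5 = paste0("g", 1:5))
  res <- ora_hypergeometric(paste0("g", 1:5), background, sets)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 6.45e-5, tolerance = 1e-2)
  expect_equal(res$overlap, 5)
  expect_equal(res$expected, 5 * 5 / 20)

  # zero overlap -> p = 1
  res0 <- ora_hypergeometric(paste0("g", 6:10), background,
                             list(s = paste0("g", 1:5)))
  expect_equal(res0$p_value, 1)

  # random cases vs pmf enumeration, populations <= 30
  set.seed(71)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    bg <- paste0("x", 1:N)
    K <- sample(2:(N - 2), 1)
    nq <- sample(2:(N - 2), 1)
    set <- sample(bg, K)
    query <- sample(bg, nq)
    ov <- length(intersect(set, query))
    res <- ora_hypergeometric(query, bg, list(s = set))
    expect_equal(res$p_value, hyper_tail_oracle(ov, K, N, nq),
                 tolerance = 1e-12)
  }

  # disjoint set skipped with a warning
  expect_warning(
    resd <- ora_hypergeometric(paste0("g", 1:3), background,
                               list(out = paste0("z", 1:4),
                                    s = paste0("g", 1:5))), "disjoint")
  expect_equal(resd$term_id, "s")
  expect_error(ora_hypergeometric("g1", character(0), list()), "empty")
})

test_that("GMT files round-trip", {
  dir <- withr::local_tempdir()
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g2", "g9"))
  path <- file.path(dir, "sets.gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
  writeLines("broken_line_no_tabs", path)
  expect_error(read_gmt(path), "malformed")
})
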