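# Independent brute-force oracles used to verify the implementation paths.

# Normal-equations OLS oracle: group coefficient, t, two-sided p.
ols_oracle <- function(X, y) {
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  g <- match("group", colnames(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[g, g])
  t <- b[g] / se
  list(coef = b[g], t = t, p = 2 * pt(-abs(t), df))
}

# Exhaustive DMR segmentation oracle: test every contiguous CpG window of a
# single-chromosome panel against the three rules (all members significant,
# every adjacent gap <= max_gap, window maximal), keep maximal windows with
# >= min_cpgs members. `panel` has pos, fdr sorted by pos.
dmr_windows_oracle <- function(panel, threshold, max_gap = 1000, min_cpgs = 2) {
  n <- nrow(panel)
  sig <- !is.na(panel$fdr) & panel$fdr < threshold
  ok_window <- function(i, j) {
    if (!all(sig[i:j])) return(FALSE)
    if (j > i && any(diff(panel$pos[i:j]) > max_gap)) return(FALSE)
    TRUE
  }
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!ok_window(i, j)) next
    # maximal: no valid extension either way
    if (i > 1 && ok_window(i - 1, j)) next
    if (j < n && ok_window(i, j + 1)) next
    if (j - i + 1 >= min_cpgs)
      out[[length(out) + 1]] <- c(start = panel$pos[i], end = panel$pos[j],
                                  n = j - i + 1)
  }
  if (length(out) == 0) return(data.frame(start = integer(0),
                                          end = integer(0), n = integer(0)))
  unique(as.data.frame(do.call(rbind, out)))
}

# Exhaustive hypergeometric upper tail from the pmf (choose() arithmetic).
hyper_tail_oracle <- function(overlap, K, N, n) {
  ks <- overlap:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Triple-loop TOM oracle.
tom_oracle <- function(a) {
  p <- nrow(a)
  a0 <- a; diag(a0) <- 0
  k <- rowSums(a0)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    shared <- sum(a0[i, ] * a0[, j])
    tom[i, j] <- (shared + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
  }
  tom
}

# Naive double-loop signed adjacency oracle.
adjacency_oracle <- function(expr, beta) {
  p <- nrow(expr)
  a <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) a[i, j] <- ((1 + cor(expr[i, ], expr[j, ])) / 2)^beta
  }
  a
}

# All permutations of 1..n (for the exhaustive permutation-p oracle).
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exact two-sided permutation p over the full permutation group.
perm_p_oracle <- function(x, y) {
  r_obs <- cor(x, y)
  perms <- all_perms(length(x))
  rs <- apply(perms, 1, function(pm) cor(x, y[pm]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Correlated-block expression generator for network-recovery tests: each
# block shares a latent factor; factors are mutually orthogonalized so the
# planted between-block correlation is exactly 0. Optionally the factor of
# block 1 is shifted in cases to plant a trait-associated module.
simulate_blocks <- function(n_blocks = 2, block_size = 50, n_noise = 0,
                            n_samples = 63, within_cor = 0.8,
                            groups = NULL, shift = 0, seed = 1) {
  set.seed(seed)
  lam <- sqrt(within_cor)
  genes <- list(); labels <- integer(0); factors <- list()
  for (b in seq_len(n_blocks)) {
    f <- rnorm(n_samples)
    if (b == 1 && shift != 0 && !is.null(groups))
      f <- f + shift * (groups == "case")
    f <- f - mean(f)
    for (prev in factors) f <- f - sum(f * prev) / sum(prev^2) * prev
    f <- as.numeric(scale(f))
    factors[[b]] <- f
    g <- matrix(lam * rep(f, each = block_size) +
                  sqrt(1 - lam^2) * rnorm(block_size * n_samples),
                block_size)
    genes[[b]] <- g
    labels <- c(labels, rep(b, block_size))
  }
  if (n_noise > 0) {
    genes[[n_blocks + 1]] <- matrix(rnorm(n_noise * n_samples), n_noise)
    labels <- c(labels, rep(0, n_noise))
  }
  expr <- do.call(rbind, genes)
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  list(expr = expr, labels = labels)
}

# Small synthetic blood cell-type reference panel (markers x 6 types):
# each type gets a block of near-exclusive hypermethylated markers.
make_reference <- function(n_markers_per_type = 8, seed = 5) {
  set.seed(seed)
  types <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")
  m <- n_markers_per_type * length(types)
  ref <- matrix(runif(m * 6, 0.05, 0.15), m, 6,
                dimnames = list(sprintf("mk%03d", seq_len(m)), types))
  for (t in seq_along(types)) {
    rows <- ((t - 1) * n_markers_per_type + 1):(t * n_markers_per_type)
    ref[rows, t] <- runif(n_markers_per_type, 0.8, 0.95)
  }
  ref
}
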