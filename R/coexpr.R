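#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(i, j)) / 2) ^ beta` with unit diagonal. The signed
#' form maps perfect anti-correlation to 0 rather than 1, so modules are
#' direction-coherent. A signed-hybrid variant (`max(cor, 0) ^ beta`) is
#' available for comparison.
#'
#' @param expr gene x sample matrix (residualized log expression).
#' @param beta soft-thresholding power (default 6).
#' @param type `"signed"` (default) or `"signed_hybrid"`.
#' @return symmetric gene x gene adjacency in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, beta = 6, type = c("signed", "signed_hybrid")) {
  type <- match.arg(type)
  assert_that(beta >= 1, "soft power must be >= 1")
  assert_that(ncol(expr) >= 3, "need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v <= 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v <= 0], 5), collapse = ", "),
         call. = FALSE)
  r <- stats::cor(t(expr))
  a <- if (type == "signed") ((1 + r) / 2)^beta else pmax(r, 0)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `k` the connectivity (row sum minus the diagonal);
#' diagonal 1. Values lie in `[0, 1]` for adjacency in `[0, 1]`.
#'
#' @param a adjacency matrix from [signed_adjacency()].
#' @return TOM matrix.
#' @export
tom_similarity <- function(a) {
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules on the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height; clusters below `min_module_size` are relabelled 0 (unassigned,
#' the "grey" convention). Labels are ordered by module size, largest
#' first. This fixed-height cut is a deterministic simplification of
#' dynamic tree cutting.
#'
#' @param tom TOM matrix.
#' @param min_module_size smallest assignable module.
#' @param cut_height dissimilarity cut in `[0, 1]`.
#' @return integer vector of module labels named by gene (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.95) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  kept_sizes <- sort(sizes[keep], decreasing = TRUE)
  for (i in seq_along(kept_sizes)) {
    labels[raw == as.integer(names(kept_sizes)[i])] <- i
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengene
#'
#' First principal component of the per-gene z-scored member submatrix,
#' scaled to unit variance, with the sign fixed so the mean correlation
#' with member profiles is positive. Zero-variance members are dropped
#' with a warning.
#'
#' @param expr gene x sample matrix.
#' @param members gene ids of the module (>= 2).
#' @return numeric vector, one value per sample, variance 1.
#' @export
module_eigengene <- function(expr, members) {
  sub <- expr[members, , drop = FALSE]
  assert_that(ncol(sub) >= 3, "need at least 3 samples")
  v <- apply(sub, 1, stats::var)
  if (any(v <= 0)) {
    warning("dropping zero-variance member(s): ",
            paste(members[v <= 0], collapse = ", "))
    sub <- sub[v > 0, , drop = FALSE]
  }
  assert_that(nrow(sub) >= 2, "need at least 2 usable members")
  z <- t(scale(t(sub)))             # per-gene z-score
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, t(sub))) < 0) e <- -e
  unname(e)
}

#' Correlate module eigengenes with a binary trait
#'
#' Pearson correlation of each eigengene with the trait coding
#' (case = 1, control = 0) and a two-sided t-distribution p-value on
#' `n - 2` degrees of freedom.
#'
#' @param eigengenes module x sample matrix (or a single vector).
#' @param trait numeric/logical trait vector, non-constant.
#' @return data.frame with `module`, `r`, `p_value`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (is.vector(eigengenes)) eigengenes <- matrix(eigengenes, nrow = 1)
  trait <- as.numeric(trait)
  assert_that(stats::sd(trait) > 0, "trait is constant")
  n <- length(trait)
  out <- apply(eigengenes, 1, function(e) {
    if (stats::sd(e) == 0) stop("constant eigengene", call. = FALSE)
    r <- stats::cor(e, trait)
    t <- r * sqrt((n - 2) / (1 - r^2))
    c(r = r, p = 2 * stats::pt(-abs(t), n - 2))
  })
  data.frame(module = rownames(eigengenes) %||% seq_len(ncol(out)),
             r = out["r", ], p_value = out["p", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set overrepresentation
#'
#' For each set, the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing the observed overlap when `|query|` genes
#' are sampled without replacement from the background; BH FDR across the
#' tested sets. Sets are intersected with the background first; sets with
#' no background member are skipped with a warning.
#'
#' @param query character vector of genes (subset of `background`).
#' @param background character vector, the tested universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame sorted by p with `term_id`, `term_size`, `overlap`,
#'   `expected`, `p_value`, `fdr`.
#' @export
ora_hypergeometric <- function(query, background, gene_sets) {
  assert_that(length(background) > 0, "empty background")
  background <- unique(background)
  query <- unique(query)
  assert_that(all(query %in% background), "query must be within the background")
  N <- length(background); n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), background)
    K <- length(set)
    if (K == 0) {
      warning("gene set disjoint from background, skipped: ", id)
      return(NULL)
    }
    ov <- length(intersect(set, query))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_size = K, overlap = ov,
               expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(term_id = character(0), term_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p_value = numeric(0), fdr = numeric(0)))
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p_value)
  res[order(res$p_value), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", l, call. = FALSE)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
}
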