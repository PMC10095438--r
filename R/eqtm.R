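#' Match DMRs to cis genes
#'
#' One candidate pair per (region, annotated gene) where the gene survived
#' expression filtering; the gene annotation of a region is the union of
#' its member CpGs' gene labels (multi-gene regions fan out to one pair
#' per gene). Regions whose genes were all filtered out land in the drop
#' log. Regions with no gene annotation (intergenic) are optionally
#' matched to the nearest TSS within `cis_window` and flagged.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param annotation CpG annotation (provides member-CpG gene labels).
#' @param gene_models gene model table (for intergenic nearest-TSS lookup).
#' @param expressed character vector of gene ids that survived filtering.
#' @param cis_window max TSS distance for intergenic matching, bp
#'   (default 1e5); `0` disables intergenic matching.
#' @return list with `pairs` (data.frame `region_id`, `gene_id`,
#'   `intergenic_match`) and `dropped` (data.frame `region_id`, `gene_id`,
#'   `reason`).
#' @export
match_cis <- function(dmrs, annotation, gene_models, expressed,
                      cis_window = 1e5) {
  pairs <- list(); dropped <- list()
  for (i in seq_len(nrow(dmrs))) {
    members <- strsplit(dmrs$member_cpgs[i], ",", fixed = TRUE)[[1]]
    genes <- annotation$gene[match(members, annotation$cpg_id)]
    genes <- unique(genes[!is.na(genes) & nzchar(genes)])
    if (length(genes) == 0 && cis_window > 0) {
      gm <- gene_models[gene_models$chrom == dmrs$chrom[i], , drop = FALSE]
      if (nrow(gm) > 0) {
        d <- pmin(abs(gm$tss - dmrs$start[i]), abs(gm$tss - dmrs$end[i]))
        if (min(d) <= cis_window) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            region_id = dmrs$region_id[i],
            gene_id = gm$gene_id[which.min(d)],
            intergenic_match = TRUE, stringsAsFactors = FALSE)
          next
        }
      }
      dropped[[length(dropped) + 1L]] <- data.frame(
        region_id = dmrs$region_id[i], gene_id = NA_character_,
        reason = "no gene within cis window", stringsAsFactors = FALSE)
      next
    }
    for (g in genes) {
      if (g %in% expressed) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          region_id = dmrs$region_id[i], gene_id = g,
          intergenic_match = FALSE, stringsAsFactors = FALSE)
      } else {
        dropped[[length(dropped) + 1L]] <- data.frame(
          region_id = dmrs$region_id[i], gene_id = g,
          reason = "gene not expressed", stringsAsFactors = FALSE)
      }
    }
    if (length(genes) == 0 && cis_window <= 0) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        region_id = dmrs$region_id[i], gene_id = NA_character_,
        reason = "intergenic, matching disabled", stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(region_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  list(pairs = if (length(pairs)) do.call(rbind, pairs)
       else cbind(empty, intergenic_match = logical(0)),
       dropped = if (length(dropped)) do.call(rbind, dropped)
       else cbind(empty, reason = character(0)))
}

#' Per-sample median methylation of a region
#'
#' @param beta CpG x sample beta matrix.
#' @param member_cpgs CpG ids of the region (all must be present).
#' @return numeric vector, one median per sample.
#' @export
dmr_median_methylation <- function(beta, member_cpgs) {
  missing <- setdiff(member_cpgs, rownames(beta))
  if (length(missing) > 0)
    stop("member CpG(s) missing from beta matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  col_medians(beta[member_cpgs, , drop = FALSE])
}

#' Pearson correlation between region medians and log expression
#'
#' @param medians,log_expr aligned per-sample vectors, both non-constant,
#'   n >= 3.
#' @return Pearson r.
#' @export
eqtm_correlation <- function(medians, log_expr) {
  assert_that(length(medians) == length(log_expr), "length mismatch")
  assert_that(length(medians) >= 3, "need at least 3 samples")
  if (stats::sd(medians) == 0 || stats::sd(log_expr) == 0)
    stop("constant input vector", call. = FALSE)
  stats::cor(medians, log_expr)
}

# Vectorised Pearson r for index-resampled columns.
r_columns <- function(x, y, idx) {
  n <- nrow(idx)
  X <- matrix(x[idx], n); Y <- matrix(y[idx], n)
  sx <- colSums(X); sy <- colSums(Y)
  num <- n * colSums(X * Y) - sx * sy
  den2 <- (n * colSums(X^2) - sx^2) * (n * colSums(Y^2) - sy^2)
  r <- ifelse(den2 <= 0, NA_real_, num / sqrt(pmax(den2, 0)))
  r
}

#' Percentile-bootstrap confidence interval for the eQTM correlation
#'
#' Samples are resampled with replacement as pairs; the correlation is
#' recomputed per replicate and the interval taken at the
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles. Replicates where
#' either resampled vector is constant are redrawn (bounded retries, then
#' dropped with a warning); if more than half of the replicates are
#' degenerate the data are unusable and an error is raised. Seeded and
#' reproducible.
#'
#' @param medians,log_expr aligned per-sample vectors.
#' @param n_boot bootstrap replicates (default 100000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(medians, log_expr, n_boot = 100000, level = 0.95,
                         seed = 1L) {
  assert_that(length(medians) >= 3, "need at least 3 samples")
  n <- length(medians)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
    r <- r_columns(medians, log_expr, idx)
    for (retry in 1:5) {
      bad <- which(is.na(r))
      if (length(bad) == 0) break
      idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), n)
      r[bad] <- r_columns(medians, log_expr, idx2)
    }
    n_bad <- sum(is.na(r))
    if (n_bad > n_boot / 2)
      stop("over half of bootstrap replicates are degenerate", call. = FALSE)
    if (n_bad > 0) {
      warning(n_bad, " degenerate bootstrap replicate(s) dropped")
      r <- r[!is.na(r)]
    }
    alpha <- (1 - level) / 2
    unname(stats::quantile(r, c(alpha, 1 - alpha), type = 7))
  })
}

#' Permutation p-value for the eQTM correlation
#'
#' The null distribution is built by permuting the expression vector
#' against the methylation vector; the two-sided p-value uses the add-one
#' estimator `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`, so p is
#' never zero. Seeded and reproducible.
#'
#' @param medians,log_expr aligned per-sample vectors.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return p-value in `(0, 1]`.
#' @export
resampling_pvalue <- function(medians, log_expr, n_perm = 10000, seed = 1L) {
  r_obs <- eqtm_correlation(medians, log_expr)
  n <- length(medians)
  with_seed(seed, {
    idx <- matrix(0L, n, n_perm)
    for (j in seq_len(n_perm)) idx[, j] <- sample.int(n)
    Y <- matrix(log_expr[idx], n)
    zx <- (medians - mean(medians))
    r_perm <- as.numeric(crossprod(zx, sweep(Y, 2, colMeans(Y)))) /
      sqrt(sum(zx^2) * colSums(sweep(Y, 2, colMeans(Y))^2))
    (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  })
}

#' Group-specific correlations
#'
#' Pearson r within cases and controls separately; groups with fewer than
#' 3 samples or a constant vector yield `NA` with a flag.
#'
#' @param medians,log_expr aligned per-sample vectors.
#' @param groups character vector, `"case"` / `"control"`.
#' @return list with `r_case`, `r_control`, `flagged`.
#' @export
group_correlations <- function(medians, log_expr, groups) {
  one <- function(g) {
    i <- groups == g
    if (sum(i) < 3 || stats::sd(medians[i]) == 0 ||
        stats::sd(log_expr[i]) == 0) return(NA_real_)
    stats::cor(medians[i], log_expr[i])
  }
  r_case <- one("case"); r_control <- one("control")
  list(r_case = r_case, r_control = r_control,
       flagged = is.na(r_case) || is.na(r_control))
}

# Feature label of a region w.r.t. its matched gene (Table-style vocabulary,
# most specific first: upstream window / 5'UTR -> Promoter, first exon ->
# 1st exon, body/3'UTR -> Gene body, otherwise Intergenic).
region_feature <- function(member_features, member_pos, gene_model) {
  in_window <- FALSE
  if (!is.null(gene_model) && nrow(gene_model) == 1) {
    if (gene_model$strand == "+")
      in_window <- any(member_pos >= gene_model$tss - 1500 &
                         member_pos <= gene_model$tss - 1)
    else
      in_window <- any(member_pos >= gene_model$tss + 1 &
                         member_pos <= gene_model$tss + 1500)
  }
  if (in_window || any(member_features %in% c("TSS1500", "5UTR"))) "Promoter"
  else if (any(member_features == "1stExon")) "1st exon"
  else if (any(member_features %in% c("Body", "3UTR"))) "Gene body"
  else "Intergenic"
}

# Direction labels for one pair.
classify_pair <- function(mean_delta_beta, group_effect, raw_diff) {
  dmr_direction <- if (mean_delta_beta > 0) "Hyper-methylated" else "Hypo-methylated"
  eff <- if (!is.na(group_effect) && group_effect != 0) group_effect else raw_diff
  expression_direction <- if (is.na(eff) || eff == 0) "none"
  else if (eff > 0) "Overexpression" else "Underexpression"
  list(dmr_direction = dmr_direction,
       expression_direction = expression_direction)
}

#' Run the full cis-eQTM analysis
#'
#' For every matched DMR-gene pair: per-sample region median methylation,
#' Pearson correlation with the gene's log2 normalized expression,
#' percentile-bootstrap 95% CI, permutation p-value, group-specific
#' correlations, and feature/direction labels. Pairs with `p < sig_level`
#' are flagged significant without multiplicity correction (the
#' region-level scan already applied FDR control); BH-adjusted q-values
#' are available via `include_q`.
#'
#' @param beta CpG x sample beta matrix.
#' @param counts gene x sample count matrix (unfiltered; filtering and
#'   normalization happen here).
#' @param samples sample table.
#' @param dmrs DMR table (typically called at the relaxed FDR < 0.1).
#' @param annotation CpG annotation.
#' @param gene_models gene model table.
#' @param de_table optional precomputed [de_test()] result (for the
#'   expression-direction label); computed on the fly when `NULL`.
#' @param n_boot,n_perm,level resampling settings.
#' @param sig_level per-pair significance threshold (default 0.05).
#' @param min_nonzero_frac expression filter (default 0.90).
#' @param cis_window intergenic matching window, bp.
#' @param include_q add a BH-adjusted `q_value` column.
#' @param seed global seed; per-pair resampling streams are derived from it.
#' @return list with `eqtms` (one row per pair, sorted by p) and `dropped`
#'   (the match drop log).
#' @export
run_eqtm_analysis <- function(beta, counts, samples, dmrs, annotation,
                              gene_models, de_table = NULL,
                              n_boot = 100000, n_perm = 10000, level = 0.95,
                              sig_level = 0.05, min_nonzero_frac = 0.90,
                              cis_window = 1e5, include_q = FALSE,
                              seed = 1L) {
  empty <- data.frame(region_id = character(0), position = character(0),
                      gene_id = character(0), n_cpgs = integer(0),
                      r = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_value = numeric(0),
                      r_case = numeric(0), r_control = numeric(0),
                      dmr_feature = character(0), dmr_direction = character(0),
                      expression_direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0)
    return(list(eqtms = empty,
                dropped = data.frame(region_id = character(0),
                                     gene_id = character(0),
                                     reason = character(0))))
  filtered <- filter_expressed(counts, min_nonzero_frac)
  log_expr <- log_transform(normalize_counts(filtered)$normalized)
  matched <- match_cis(dmrs, annotation, gene_models,
                       expressed = rownames(filtered),
                       cis_window = cis_window)
  if (nrow(matched$pairs) == 0)
    return(list(eqtms = empty, dropped = matched$dropped))
  if (is.null(de_table)) de_table <- de_test(filtered, samples)

  rows <- vector("list", nrow(matched$pairs))
  for (i in seq_len(nrow(matched$pairs))) {
    rid <- matched$pairs$region_id[i]
    gid <- matched$pairs$gene_id[i]
    dmr <- dmrs[dmrs$region_id == rid, , drop = FALSE]
    members <- strsplit(dmr$member_cpgs, ",", fixed = TRUE)[[1]]
    med <- dmr_median_methylation(beta, members)
    y <- log_expr[gid, ]
    if (stats::sd(med) == 0 || stats::sd(y) == 0) {
      matched$dropped <- rbind(matched$dropped,
                               data.frame(region_id = rid, gene_id = gid,
                                          reason = "constant vector"))
      next
    }
    r <- eqtm_correlation(med, y)
    ci <- bootstrap_ci(med, y, n_boot = n_boot, level = level,
                       seed = stream_seed(seed, "boot") + 13 * i)
    p <- resampling_pvalue(med, y, n_perm = n_perm,
                           seed = stream_seed(seed, "perm") + 13 * i)
    gc <- group_correlations(med, y, samples$group)
    ann_i <- annotation[match(members, annotation$cpg_id), ]
    gm <- gene_models[gene_models$gene_id == gid, , drop = FALSE]
    feat <- region_feature(ann_i$feature, ann_i$pos, gm)
    de_i <- de_table[de_table$gene_id == gid, , drop = FALSE]
    raw_diff <- mean(y[samples$group == "case"]) -
      mean(y[samples$group == "control"])
    cls <- classify_pair(dmr$mean_delta_beta,
                         if (nrow(de_i)) de_i$log2_fold_change else NA_real_,
                         raw_diff)
    rows[[i]] <- data.frame(
      region_id = rid,
      position = sprintf("%s:%d-%d", dmr$chrom, dmr$start, dmr$end),
      gene_id = gid, n_cpgs = dmr$n_cpgs, r = r,
      ci_low = ci[1], ci_high = ci[2], p_value = p,
      r_case = gc$r_case, r_control = gc$r_control,
      dmr_feature = feat, dmr_direction = cls$dmr_direction,
      expression_direction = cls$expression_direction,
      significant = p < sig_level, stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  res <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(res) > 0) {
    res <- res[order(res$p_value), , drop = FALSE]
    rownames(res) <- NULL
    if (include_q) res$q_value <- bh_fdr(res$p_value)
  }
  list(eqtms = res, dropped = matched$dropped)
}

#' Export per-pair scatter data for plotting
#'
#' One row per sample and pair: region median beta, log2 expression and
#' group, the data behind a methylation-vs-expression scatter.
#'
#' @param beta CpG x sample beta matrix.
#' @param log_expr gene x sample log2 expression matrix.
#' @param samples sample table.
#' @param dmrs DMR table.
#' @param eqtms result table from [run_eqtm_analysis()].
#' @return long data.frame (`region_id`, `gene_id`, `sample_id`, `group`,
#'   `median_beta`, `log2_expr`).
#' @export
eqtm_scatter_data <- function(beta, log_expr, samples, dmrs, eqtms) {
  out <- lapply(seq_len(nrow(eqtms)), function(i) {
    dmr <- dmrs[dmrs$region_id == eqtms$region_id[i], , drop = FALSE]
    members <- strsplit(dmr$member_cpgs, ",", fixed = TRUE)[[1]]
    data.frame(region_id = eqtms$region_id[i], gene_id = eqtms$gene_id[i],
               sample_id = samples$sample_id, group = samples$group,
               median_beta = dmr_median_methylation(beta, members),
               log2_expr = log_expr[eqtms$gene_id[i], ],
               stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(region_id = character(0), gene_id = character(0),
               sample_id = character(0), group = character(0),
               median_beta = numeric(0), log2_expr = numeric(0))
}
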