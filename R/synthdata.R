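#' Configure a synthetic case/control methylation + expression cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults emulate a whole-blood 450K-style EWAS with matched RNA-seq at
#' desk scale: 12 cases vs 51 controls, 20,000 CpGs over 22 autosomes and a
#' 2,000-gene count panel, with six blood cell-type fractions drawn per
#' sample from a Dirichlet distribution.
#'
#' Methylation is simulated on the M-value (logit2) scale — baseline +
#' group shift + cell-fraction confound + Gaussian noise — then mapped back
#' through the inverse logit so beta values stay in `[0, 1]`. Counts are
#' negative binomial with per-gene dispersion `phi` (variance
#' `mu + phi * mu^2`). Planted differentially methylated regions (DMRs) and
#' methylation-coupled genes (eQTMs) are recorded in a ground-truth registry
#' for recovery testing.
#'
#' @param n_cases,n_controls group sizes (both must be >= 2).
#' @param n_cpgs,n_genes,n_chromosomes panel dimensions.
#' @param planted_dmr_specs list of specs, each a list with `n_cpgs`
#'   (CpGs in the region), `delta_beta` (signed mean beta shift in cases),
#'   and optionally `max_gap` (max intra-region spacing, nt; default 250).
#' @param planted_eqtm_specs list of specs, each a list with `rho` (target
#'   Pearson correlation between region-median beta and log2 expression),
#'   `region` (index into `planted_dmr_specs`; default the i-th region) and
#'   optionally `gene` (gene id; default an auto-assigned panel gene).
#' @param nb_dispersion per-gene NB dispersion `phi`.
#' @param beta_noise_sd residual SD on the M-value scale.
#' @param cell_fraction_alpha Dirichlet concentration for the six blood cell
#'   types (CD8T, CD4T, NK, Bcell, Mono, Gran).
#' @param cell_confound_sd SD of per-CpG loadings on standardized cell
#'   fractions (0 disables the confound).
#' @param confound_frac fraction of CpGs carrying a cell-fraction loading.
#' @param group_cell_shift multiplicative tilt of the granulocyte Dirichlet
#'   weight in cases (0 = identical composition distributions).
#' @param seed global seed; expanded internally into independent per-stream
#'   seeds (map, beta, counts, fractions) so adding one stream never
#'   perturbs another.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_cases = 12, n_controls = 51,
                       n_cpgs = 20000, n_genes = 2000, n_chromosomes = 22,
                       planted_dmr_specs = list(),
                       planted_eqtm_specs = list(),
                       nb_dispersion = 0.15,
                       beta_noise_sd = 0.5,
                       cell_fraction_alpha = c(CD8T = 6, CD4T = 12, NK = 3,
                                               Bcell = 3, Mono = 6, Gran = 30),
                       cell_confound_sd = 0.4,
                       confound_frac = 0.1,
                       group_cell_shift = 0.15,
                       seed = 1L) {
  assert_that(n_cases >= 2 && n_controls >= 2, "need >= 2 samples per group")
  assert_that(n_cpgs >= 1 && n_genes >= 1 && n_chromosomes >= 1,
              "panel dimensions must be positive")
  assert_that(length(cell_fraction_alpha) == 6 && all(cell_fraction_alpha > 0),
              "cell_fraction_alpha must be 6 positive concentrations")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  planted_dmr_specs <- lapply(planted_dmr_specs, function(s) {
    s$max_gap <- s$max_gap %||% 250
    assert_that(s$n_cpgs >= 2, "planted DMR needs >= 2 CpGs")
    assert_that(abs(s$delta_beta) < 1, "planted |delta_beta| must be < 1")
    s
  })
  n_reg <- length(planted_dmr_specs)
  planted_eqtm_specs <- lapply(seq_along(planted_eqtm_specs), function(i) {
    s <- planted_eqtm_specs[[i]]
    s$region <- s$region %||% i
    assert_that(abs(s$rho) <= 1, "target rho must lie in [-1, 1]")
    assert_that(s$region >= 1 && s$region <= n_reg,
                "eQTM spec ", i, " references region ", s$region,
                " but only ", n_reg, " planted DMRs are configured")
    s
  })
  total_planted <- sum(vapply(planted_dmr_specs, `[[`, 0, "n_cpgs"))
  assert_that(total_planted <= n_cpgs,
              "planted regions need more CpGs than the panel holds")
  assert_that(length(planted_eqtm_specs) <= n_genes,
              "more planted eQTM genes than panel genes")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_cpgs = as.integer(n_cpgs), n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    planted_dmr_specs = planted_dmr_specs,
    planted_eqtm_specs = planted_eqtm_specs,
    nb_dispersion = nb_dispersion, beta_noise_sd = beta_noise_sd,
    cell_fraction_alpha = cell_fraction_alpha,
    cell_confound_sd = cell_confound_sd, confound_frac = confound_frac,
    group_cell_shift = group_cell_shift,
    seed = as.integer(seed)), class = "sim_config")
}

CELL_TYPES <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")
CHROM_LENGTH <- 3e7  # synthetic chromosome span, bp

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a full dataset with the statistical structure the downstream
#' analysis assumes: group-shifted beta values at planted regions,
#' cell-composition confounding, NB counts, and cis methylation-expression
#' coupling where the gene's log2 mean absorbs the planted region's
#' standardized median beta with a coefficient solved (delta method on the
#' NB log-variance) so the realized Pearson correlation with log2 counts
#' targets the spec's `rho`. Identical config + seed gives byte-identical
#' output.
#'
#' @param config a [sim_config()] object.
#' @return list with `beta` (CpG x sample matrix), `counts` (gene x sample
#'   integer matrix), `samples` (sample table), `cpg_annotation`,
#'   `gene_models`, `truth` (planted-effect registry).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- c(rep("case", config$n_cases), rep("control", config$n_controls))

  ## --- cell fractions & demographics ----------------------------------
  fractions <- with_seed(stream_seed(config$seed, "fractions"), {
    a_ctrl <- config$cell_fraction_alpha
    a_case <- a_ctrl
    a_case["Gran"] <- a_case["Gran"] * (1 + config$group_cell_shift)
    rbind(rdirichlet(config$n_cases, a_case),
          rdirichlet(config$n_controls, a_ctrl))
  })
  colnames(fractions) <- CELL_TYPES
  demo <- with_seed(stream_seed(config$seed, "ages"), {
    age <- c(clip(stats::rnorm(config$n_cases, 6.95, 3.68), 1, 18),
             clip(stats::rnorm(config$n_controls, 13.20, 2.94), 1, 18))
    sex <- c(ifelse(stats::runif(config$n_cases) < 7 / 12, "M", "F"),
             ifelse(stats::runif(config$n_controls) < 33 / 51, "M", "F"))
    list(age = round(age, 2), sex = sex)
  })
  samples <- data.frame(sample_id = sample_id, group = group,
                        age = demo$age, sex = demo$sex,
                        fractions, stringsAsFactors = FALSE)

  ## --- genomic map: planted regions first, background after -----------
  map <- with_seed(stream_seed(config$seed, "map"), {
    build_map(config)
  })

  ## --- methylation -----------------------------------------------------
  beta <- with_seed(stream_seed(config$seed, "beta"), {
    simulate_beta(config, map, samples, fractions)
  })

  ## --- expression ------------------------------------------------------
  counts <- with_seed(stream_seed(config$seed, "counts"), {
    simulate_counts(config, map, beta, samples)
  })

  truth <- list(
    dmr_regions = map$regions,
    eqtm_pairs = map$eqtm_pairs,
    null_cpg_ids = setdiff(rownames(beta),
                           unlist(lapply(map$regions, `[[`, "cpg_ids"))),
    null_gene_ids = setdiff(rownames(counts),
                            vapply(map$eqtm_pairs, `[[`, "", "gene_id")))

  list(beta = beta, counts = counts, samples = samples,
       cpg_annotation = map$annotation, gene_models = map$gene_models,
       truth = truth)
}

# Lay out CpGs, genes and planted regions on synthetic chromosomes.
build_map <- function(config) {
  n_reg <- length(config$planted_dmr_specs)
  regions <- vector("list", n_reg)
  # genes: panel-wide ids, TSS scattered over chromosomes
  gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
  g_chrom <- sprintf("chr%d", sample.int(config$n_chromosomes,
                                         config$n_genes, replace = TRUE))
  g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  g_tss <- sample.int(CHROM_LENGTH - 1e5, config$n_genes) + 5e4

  # eQTM-linked genes are re-anchored next to their regions below
  eqtm_pairs <- list()
  used_genes <- character(0)

  cpg_chrom <- character(config$n_cpgs)
  cpg_pos <- integer(config$n_cpgs)
  cpg_gene <- character(config$n_cpgs)
  cpg_feature <- character(config$n_cpgs)
  idx <- 1L

  reserved <- list()  # per-chromosome occupied windows for planted regions
  for (r in seq_len(n_reg)) {
    spec <- config$planted_dmr_specs[[r]]
    chrom <- sprintf("chr%d", ((r - 1L) %% config$n_chromosomes) + 1L)
    base <- 10000L + 50000L * ((r - 1L) %/% config$n_chromosomes)
    gaps <- sample.int(spec$max_gap, spec$n_cpgs - 1L, replace = TRUE)
    pos <- as.integer(base + c(0L, cumsum(gaps)))
    assert_that(max(pos) <= CHROM_LENGTH,
                "planted region ", r, " exceeds the chromosome length")
    ids <- idx:(idx + spec$n_cpgs - 1L)
    cpg_chrom[ids] <- chrom
    cpg_pos[ids] <- pos
    # link a gene: either the spec'd eQTM gene or a fresh panel gene
    linked <- NULL
    for (e in seq_along(config$planted_eqtm_specs)) {
      if (config$planted_eqtm_specs[[e]]$region == r) linked <- e
    }
    gi <- if (!is.null(linked) && !is.null(config$planted_eqtm_specs[[linked]]$gene)) {
      match(config$planted_eqtm_specs[[linked]]$gene, gene_id)
    } else {
      setdiff(seq_len(config$n_genes), match(used_genes, gene_id))[1]
    }
    assert_that(!is.na(gi), "planted eQTM gene not in the gene panel")
    used_genes <- c(used_genes, gene_id[gi])
    g_chrom[gi] <- chrom
    g_strand[gi] <- "+"
    g_tss[gi] <- max(pos) + 500L   # region sits in the TSS1500 window
    cpg_gene[ids] <- gene_id[gi]
    cpg_feature[ids] <- "TSS1500"
    regions[[r]] <- list(region_id = sprintf("region_%02d", r),
                         chrom = chrom, start = min(pos), end = max(pos),
                         cpg_ids = sprintf("cg%07d", ids),
                         delta_beta = spec$delta_beta,
                         gene_id = gene_id[gi])
    if (!is.null(linked)) {
      eqtm_pairs[[length(eqtm_pairs) + 1L]] <-
        list(region_id = regions[[r]]$region_id, gene_id = gene_id[gi],
             rho = config$planted_eqtm_specs[[linked]]$rho)
    }
    reserved[[chrom]] <- c(reserved[[chrom]] %||% integer(0),
                           min(pos) - 1500L, max(pos) + 1500L)
    idx <- idx + spec$n_cpgs
  }

  # background CpGs: uniform over chromosomes, kept >= 1500 nt clear of
  # planted regions so a planted region can never silently extend
  n_bg <- config$n_cpgs - (idx - 1L)
  if (n_bg > 0) {
    bg_chrom <- sprintf("chr%d", sample.int(config$n_chromosomes, n_bg,
                                            replace = TRUE))
    bg_pos <- integer(n_bg)
    for (ch in unique(bg_chrom)) {
      sel <- which(bg_chrom == ch)
      p <- sample.int(CHROM_LENGTH - 2e5, length(sel)) + 1e5
      win <- reserved[[ch]]
      if (!is.null(win)) {
        for (w in seq(1, length(win), by = 2)) {
          inside <- p >= win[w] & p <= win[w + 1]
          p[inside] <- p[inside] + (win[w + 1] - win[w]) + 2000L
        }
      }
      bg_pos[sel] <- as.integer(p)
    }
    ids <- idx:config$n_cpgs
    cpg_chrom[ids] <- bg_chrom
    cpg_pos[ids] <- bg_pos
    feats <- sample(c("TSS1500", "5UTR", "1stExon", "Body", "3UTR", "IGR"),
                    n_bg, replace = TRUE,
                    prob = c(.12, .08, .05, .35, .05, .35))
    # gene labels respect the CpG's chromosome; chromosomes without genes
    # fall back to intergenic
    genes_by_chrom <- split(gene_id, g_chrom)
    bg_gene <- character(n_bg)
    for (ch in unique(bg_chrom)) {
      sel <- which(bg_chrom == ch)
      pool <- genes_by_chrom[[ch]]
      if (is.null(pool)) feats[sel] <- "IGR"
      else bg_gene[sel] <- pool[sample.int(length(pool), length(sel),
                                           replace = TRUE)]
    }
    cpg_feature[ids] <- feats
    cpg_gene[ids] <- ifelse(feats == "IGR", "", bg_gene)
  }

  annotation <- data.frame(cpg_id = sprintf("cg%07d", seq_len(config$n_cpgs)),
                           chrom = cpg_chrom, pos = cpg_pos,
                           gene = cpg_gene, feature = cpg_feature,
                           stringsAsFactors = FALSE)
  # enforce unique (chrom, pos)
  dup <- duplicated(paste(annotation$chrom, annotation$pos))
  while (any(dup)) {
    annotation$pos[dup] <- annotation$pos[dup] + 1L
    dup <- duplicated(paste(annotation$chrom, annotation$pos))
  }
  gene_models <- data.frame(
    chrom = g_chrom,
    start = pmax(1L, ifelse(g_strand == "+", g_tss, g_tss - 20000L)),
    end = ifelse(g_strand == "+", g_tss + 20000L, g_tss),
    gene_id = gene_id, strand = g_strand, tss = g_tss,
    first_exon_start = ifelse(g_strand == "+", g_tss, g_tss - 300L),
    first_exon_end = ifelse(g_strand == "+", g_tss + 300L, g_tss),
    stringsAsFactors = FALSE)
  list(annotation = annotation, gene_models = gene_models,
       regions = regions, eqtm_pairs = eqtm_pairs)
}

# M-scale linear model per CpG: baseline + group shift + cell confound + noise.
simulate_beta <- function(config, map, samples, fractions) {
  p <- config$n_cpgs
  n <- nrow(samples)
  comp <- sample(1:3, p, replace = TRUE, prob = c(.55, .35, .10))
  base_m <- c(-2.8, 2.8, 0)[comp] + stats::rnorm(p, 0, 0.8)
  base_beta <- inv_m(base_m)

  shift_m <- numeric(p)
  for (reg in map$regions) {
    i <- match(reg$cpg_ids, map$annotation$cpg_id)
    target <- clip(base_beta[i] + reg$delta_beta, 1e-4, 1 - 1e-4)
    shift_m[i] <- beta_to_m(target) - base_m[i]
  }
  load <- matrix(0, p, 6)
  if (config$cell_confound_sd > 0 && config$confound_frac > 0) {
    carriers <- which(stats::runif(p) < config$confound_frac)
    load[carriers, ] <- stats::rnorm(length(carriers) * 6, 0,
                                     config$cell_confound_sd)
  }
  z_frac <- scale(fractions)
  z_frac[is.nan(z_frac)] <- 0
  is_case <- as.numeric(samples$group == "case")
  m <- matrix(base_m, p, n) +
    outer(shift_m, is_case) +
    load %*% t(z_frac) +
    matrix(stats::rnorm(p * n, 0, config$beta_noise_sd), p, n)
  beta <- clip(inv_m(m), 0, 1)
  dimnames(beta) <- list(map$annotation$cpg_id, samples$sample_id)
  beta
}

inv_m <- function(m) 2^m / (1 + 2^m)

# NB counts; planted eQTM genes absorb the region's standardized median
# beta into their log2 mean with the delta-method coefficient for target rho.
simulate_counts <- function(config, map, beta, samples) {
  g <- config$n_genes
  n <- nrow(samples)
  gene_id <- map$gene_models$gene_id
  # wide baseline with a low-expression tail, so the expressed-gene filter
  # removes a realistic minority of the panel
  log2_mu <- clip(stats::rnorm(g, 6, 2.5), -2, 13)
  lib <- stats::rnorm(n, 0, 0.15)
  phi <- config$nb_dispersion
  log2_mat <- matrix(log2_mu, g, n) + matrix(lib, g, n, byrow = TRUE)

  for (pair in map$eqtm_pairs) {
    gi <- match(pair$gene_id, gene_id)
    reg <- Find(function(r) r$region_id == pair$region_id, map$regions)
    med <- col_medians(beta[reg$cpg_ids, , drop = FALSE])
    x <- as.numeric(scale(med))
    log2_mu[gi] <- 9  # keep shot noise small relative to the coupling
    mu_g <- 2^log2_mu[gi]
    v <- (1 / mu_g + phi) / log(2)^2
    rho <- pair$rho
    assert_that(abs(rho) < 0.999,
                "target rho ", rho, " unattainable under NB noise settings")
    b <- sqrt(v) * rho / sqrt(1 - rho^2)
    log2_mat[gi, ] <- log2_mu[gi] + lib + b * x
  }
  mu <- 2^log2_mat
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / phi), g, n)
  dimnames(counts) <- list(gene_id, samples$sample_id)
  storage.mode(counts) <- "integer"
  counts
}

#' Write / read a cohort dataset as plain-text files
#'
#' `write_dataset()` persists all matrices and tables (TSV/CSV, full
#' precision; ground truth as JSON) and returns the file manifest.
#' `read_dataset()` reads them back with validation; the round trip is
#' lossless to 1e-12.
#'
#' @param dataset a list as returned by [generate_cohort()].
#' @param dir directory to write to / read from.
#' @return `write_dataset`: named character vector of file paths
#'   (invisibly); `read_dataset`: the dataset list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_matrix_tsv(dataset$beta, f("beta.tsv"), "cpg_id")
  write_matrix_tsv(dataset$counts, f("counts.tsv"), "gene_id")
  utils::write.csv(dataset$samples, f("samples.csv"), row.names = FALSE)
  utils::write.table(dataset$cpg_annotation, f("cpg_annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$gene_models, f("gene_models.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dataset$truth, f("truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(beta = "beta.tsv", counts = "counts.tsv",
                samples = "samples.csv", cpg_annotation = "cpg_annotation.tsv",
                gene_models = "gene_models.tsv", truth = "truth.json")
  jsonlite::write_json(as.list(manifest), f("manifest.json"),
                       auto_unbox = TRUE)
  invisible(vapply(manifest, f, ""))
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_matrix_tsv <- function(path, what = c("beta", "counts")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header in ", path, call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- if (what == "beta") which(m < 0 | m > 1, arr.ind = TRUE)
         else which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid %s value %g at row '%s', column '%s' in %s",
                 what, m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path), call. = FALSE)
  }
  if (what == "counts") storage.mode(m) <- "integer"
  m
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  f <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    p
  }
  samples <- utils::read.csv(f("samples.csv"), stringsAsFactors = FALSE)
  bad <- which(abs(rowSums(samples[, CELL_TYPES]) - 1) > 1e-9)
  if (length(bad) > 0)
    stop("cell fractions do not sum to 1 for sample ",
         samples$sample_id[bad[1]], call. = FALSE)
  truth <- jsonlite::read_json(f("truth.json"), simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  truth$dmr_regions <- lapply(truth$dmr_regions, as.list)
  truth$eqtm_pairs <- lapply(truth$eqtm_pairs, as.list)
  list(beta = read_matrix_tsv(f("beta.tsv"), "beta"),
       counts = read_matrix_tsv(f("counts.tsv"), "counts"),
       samples = samples,
       cpg_annotation = utils::read.delim(f("cpg_annotation.tsv"),
                                          stringsAsFactors = FALSE),
       gene_models = utils::read.delim(f("gene_models.tsv"),
                                       stringsAsFactors = FALSE),
       truth = truth)
}
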