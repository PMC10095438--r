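#' Default pipeline configuration
#'
#' All analysis thresholds in one place: DMP/DMR significance (FDR 0.05,
#' relaxed 0.1 for the region set feeding the eQTM stage), the 1000 nt /
#' 2-CpG region rule, the 90% expression filter, soft power 6, 100,000
#' bootstraps, 10,000 permutations, 95% CI level, and the 0.05 eQTM
#' significance level.
#'
#' @param ... overrides for individual keys.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(dmp_fdr = 0.05, dmr_fdr_relaxed = 0.1, max_gap = 1000,
              min_cpgs = 2, min_nonzero_frac = 0.90, soft_power = 6,
              min_module_size = 10, cut_height = 0.95,
              n_boot = 100000, n_perm = 10000, ci_level = 0.95,
              eqtm_sig_level = 0.05, cis_window = 1e5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Run the full analysis pipeline on a dataset
#'
#' Stages: per-CpG differential methylation -> region calling (strict and
#' relaxed FDR) -> differential expression -> signed co-expression network
#' with module-trait correlation -> cis-eQTM analysis. All stage tables
#' are written as TSV under `outdir` together with a JSON run manifest
#' (config, seed, input checksums, output list). Deterministic given the
#' seed.
#'
#' @param dataset list as from [generate_cohort()] / [read_dataset()].
#' @param outdir output directory.
#' @param config list from [pipeline_config()].
#' @param seed seed for the resampling stages.
#' @param coexpr run the co-expression stage (the slowest; default TRUE).
#' @return list with all stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(dataset, outdir, config = pipeline_config(),
                         seed = 1L, coexpr = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] seed=%d elapsed=%.1fs %s", stage, seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    msg))
  }
  ds <- dataset
  design <- design_spec()

  dmps <- fit_dmps(ds$beta, ds$samples, design)
  log_stage("dmp", sprintf("%d CpGs tested, %d at FDR<%.2g",
                           nrow(dmps), sum(dmps$fdr < config$dmp_fdr,
                                           na.rm = TRUE), config$dmp_fdr))
  dmrs_strict <- call_dmrs(dmps, ds$cpg_annotation, config$dmp_fdr,
                           config$max_gap, config$min_cpgs)
  dmrs_relaxed <- call_dmrs(dmps, ds$cpg_annotation, config$dmr_fdr_relaxed,
                            config$max_gap, config$min_cpgs)
  log_stage("dmr", sprintf("%d regions (FDR<%.2g), %d (FDR<%.2g)",
                           nrow(dmrs_strict), config$dmp_fdr,
                           nrow(dmrs_relaxed), config$dmr_fdr_relaxed))

  filtered <- filter_expressed(ds$counts, config$min_nonzero_frac)
  de <- de_test(filtered, ds$samples, design)
  log_stage("de", sprintf("%d genes tested, %d at FDR<0.05",
                          nrow(de), sum(de$fdr < 0.05, na.rm = TRUE)))

  modules <- NULL; module_trait <- NULL
  if (coexpr) {
    log_expr <- log_transform(normalize_counts(filtered)$normalized)
    covar <- build_design_matrix(ds$samples, design)
    covar <- covar[, !(colnames(covar) %in% c("intercept", "group")),
                   drop = FALSE]
    resid <- residualize(log_expr, covar)
    v <- apply(resid, 1, stats::var)
    resid <- resid[v > 1e-12, , drop = FALSE]
    adj <- signed_adjacency(resid, config$soft_power)
    tom <- tom_similarity(adj)
    modules <- detect_modules(tom, config$min_module_size, config$cut_height)
    assigned <- sort(unique(modules[modules > 0]))
    if (length(assigned) > 0) {
      eg <- t(vapply(assigned, function(m)
        module_eigengene(resid, names(modules)[modules == m]),
        numeric(ncol(resid))))
      rownames(eg) <- paste0("module_", assigned)
      module_trait <- module_trait_correlation(
        eg, as.numeric(ds$samples$group == "case"))
    }
    log_stage("coexpr", sprintf("%d modules over %d genes",
                                length(assigned), nrow(resid)))
  }

  eqtm <- run_eqtm_analysis(ds$beta, ds$counts, ds$samples, dmrs_relaxed,
                            ds$cpg_annotation, ds$gene_models, de_table = de,
                            n_boot = config$n_boot, n_perm = config$n_perm,
                            level = config$ci_level,
                            sig_level = config$eqtm_sig_level,
                            min_nonzero_frac = config$min_nonzero_frac,
                            cis_window = config$cis_window, seed = seed)
  log_stage("eqtm", sprintf("%d pairs tested, %d significant",
                            nrow(eqtm$eqtms), sum(eqtm$eqtms$significant)))

  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  outputs <- c(wt(dmps, "dmp_table.tsv"),
               wt(dmrs_strict, "dmr_table.tsv"),
               wt(dmrs_relaxed, "dmr_table_relaxed.tsv"),
               wt(de, "de_table.tsv"),
               wt(eqtm$eqtms, "eqtm_table.tsv"),
               wt(eqtm$dropped, "eqtm_drop_log.tsv"))
  if (!is.null(modules)) {
    outputs <- c(outputs,
                 wt(data.frame(gene_id = names(modules), module = modules),
                    "module_assignments.tsv"))
    if (!is.null(module_trait))
      outputs <- c(outputs, wt(module_trait, "module_trait.tsv"))
  }
  wt(ds$samples, "samples.tsv")

  manifest <- list(
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(
      wt(data.frame(key = names(config),
                    value = vapply(config, format, "")), "config.tsv"))),
    outputs = basename(outputs),
    output_checksums = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dmps = dmps, dmrs_strict = dmrs_strict,
                 dmrs_relaxed = dmrs_relaxed, de = de,
                 modules = modules, module_trait = module_trait,
                 eqtm = eqtm, manifest = manifest))
}

#' Summarise a completed pipeline run
#'
#' Builds a plain-text report from the persisted stage tables: cohort
#' composition (group sizes, male percentages rounded half-up to one
#' decimal, mean ages), DMP counts split hypo/hyper, region counts at both
#' FDR cuts, DE counts at FDR and nominal thresholds, flagged modules, and
#' the eQTM table. Missing stages are marked as gaps rather than failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also printable).
#' @export
report_run <- function(run_dir) {
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  lines <- c("== Analysis run summary ==", "")
  samples <- rd("samples.tsv")
  if (!is.null(samples)) {
    lines <- c(lines, "-- Cohort --", cohort_summary_lines(samples), "")
  } else lines <- c(lines, "-- Cohort: MISSING --", "")

  dmps <- rd("dmp_table.tsv")
  if (!is.null(dmps)) {
    sig <- dmps[!is.na(dmps$fdr) & dmps$fdr < 0.05, ]
    lines <- c(lines, "-- Differential methylation --",
               sprintf("CpGs tested: %d", nrow(dmps)),
               sprintf("DMPs at FDR<0.05: %d (%d hypomethylated, %d hypermethylated)",
                       nrow(sig), sum(sig$direction == "hypo"),
                       sum(sig$direction == "hyper")), "")
  } else lines <- c(lines, "-- Differential methylation: MISSING --", "")

  for (nm in c(strict = "dmr_table.tsv", relaxed = "dmr_table_relaxed.tsv")) {
    dmrs <- rd(nm)
    lab <- if (nm == "dmr_table.tsv") "FDR<0.05" else "FDR<0.1 (relaxed)"
    if (!is.null(dmrs))
      lines <- c(lines, sprintf("DMRs at %s: %d (%d hypo, %d hyper)",
                                lab, nrow(dmrs),
                                sum(dmrs$direction == "hypo"),
                                sum(dmrs$direction == "hyper")))
  }
  lines <- c(lines, "")
  de <- rd("de_table.tsv")
  if (!is.null(de)) {
    lines <- c(lines, "-- Differential expression --",
               sprintf("Genes tested: %d", nrow(de)),
               sprintf("Genes at FDR<0.05: %d", sum(de$fdr < 0.05, na.rm = TRUE)),
               sprintf("Genes at nominal p<0.05: %d",
                       sum(de$p_value < 0.05, na.rm = TRUE)), "")
  } else lines <- c(lines, "-- Differential expression: MISSING --", "")

  mt <- rd("module_trait.tsv")
  if (!is.null(mt)) {
    sig <- mt[mt$p_value < 0.05, , drop = FALSE]
    lines <- c(lines, "-- Co-expression modules --",
               sprintf("Modules: %d; trait-associated at p<0.05: %d",
                       nrow(mt), nrow(sig)))
    if (nrow(sig) > 0)
      lines <- c(lines, sprintf("  %s: r = %.2f, p = %.3g",
                                sig$module, sig$r, sig$p_value))
    lines <- c(lines, "")
  }

  eqtms <- rd("eqtm_table.tsv")
  lines <- c(lines, "-- cis-eQTM --")
  if (is.null(eqtms) || nrow(eqtms) == 0) {
    lines <- c(lines, "no pairs tested")
  } else {
    lines <- c(lines,
               sprintf("Pairs tested: %d; significant at p<0.05: %d",
                       nrow(eqtms), sum(eqtms$significant)),
               utils::capture.output(print(
                 eqtms[, c("position", "gene_id", "r", "p_value",
                           "dmr_feature", "dmr_direction",
                           "expression_direction")], row.names = FALSE)))
  }
  lines
}

#' Cohort composition summary
#'
#' Group sizes, male counts and percentages (half-up rounding to one
#' decimal, e.g. 7 male of 12 cases prints 58.3), and mean age (SD).
#'
#' @param samples sample table with `group`, `sex`, `age`.
#' @return character vector of lines; the percentages are also returned in
#'   attribute `percentages` (named `case_male_pct`, `control_male_pct`).
#' @export
cohort_summary_lines <- function(samples) {
  one <- function(g) {
    s <- samples[samples$group == g, ]
    m <- sum(s$sex == "M")
    pct <- round_half_up(100 * m / nrow(s), 1)
    list(line = sprintf("%s: n=%d, male %d/%d (%.1f%%), age %.2f (+-%.2f)",
                        g, nrow(s), m, nrow(s), pct,
                        mean(s$age), stats::sd(s$age)),
         pct = pct)
  }
  ca <- one("case"); co <- one("control")
  structure(c(ca$line, co$line),
            percentages = c(case_male_pct = ca$pct,
                            control_male_pct = co$pct))
}
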