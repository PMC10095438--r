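#' Combine member p-values with Stouffer's method
#'
#' `z_i = qnorm(1 - p_i)`, `Z = sum(z_i) / sqrt(n)`, combined
#' `p = 1 - pnorm(Z)`. Inputs at exactly 0 or 1 are clipped to `eps` /
#' `1 - eps` and flagged by attribute `clipped`.
#'
#' @param p member p-values (interpreted one-sided by the caller).
#' @param eps clipping bound for degenerate 0/1 inputs.
#' @return list with `z` and `p`.
#' @export
stouffer_combine <- function(p, eps = 1e-15) {
  assert_that(length(p) >= 1, "need at least one p-value")
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  clipped <- p <= 0 | p >= 1
  p <- clip(p, eps, 1 - eps)
  z <- sum(stats::qnorm(1 - p)) / sqrt(length(p))
  structure(list(z = z, p = 1 - stats::pnorm(z)),
            clipped = any(clipped))
}

#' Call differentially methylated regions from a DMP table
#'
#' Per chromosome, CpGs are scanned in position order; a region is a
#' maximal run of consecutively FDR-significant CpGs in which every
#' adjacent pair is at most `max_gap` nucleotides apart. An intervening
#' non-significant panel CpG breaks a run (the strict reading of
#' "consecutively significant"), as does a gap over `max_gap`. Runs of at
#' least `min_cpgs` members are emitted.
#'
#' Region evidence is summarised with Stouffer's method on one-sided member
#' p-values oriented by the region's dominant methylation direction, so
#' members shifting the opposite way cancel rather than reinforce; regions
#' of mixed sign are kept but flagged. Region coordinates are the positions
#' of the first and last member CpG, 1-based inclusive.
#'
#' @param dmps data.frame from [fit_dmps()].
#' @param annotation CpG annotation covering every CpG in `dmps`.
#' @param fdr_threshold significance cut on the member FDR (0.05 for the
#'   primary scan; 0.1 for the relaxed region selection feeding the eQTM
#'   analysis).
#' @param max_gap maximum spacing between successive significant CpGs, nt.
#' @param min_cpgs minimum members per region.
#' @return data.frame with one row per region: `region_id`, `chrom`,
#'   `start`, `end`, `n_cpgs`, `member_cpgs` (comma-joined), `stouffer_z`,
#'   `stouffer_p`, `mean_delta_beta`, `direction`, `mixed_sign`, sorted by
#'   `stouffer_p`.
#' @export
call_dmrs <- function(dmps, annotation, fdr_threshold = 0.05,
                      max_gap = 1000, min_cpgs = 2) {
  missing <- setdiff(dmps$cpg_id, annotation$cpg_id)
  if (length(missing) > 0)
    stop("CpG(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ann <- annotation[match(dmps$cpg_id, annotation$cpg_id), ]
  tab <- data.frame(cpg_id = dmps$cpg_id, chrom = ann$chrom, pos = ann$pos,
                    p_value = dmps$p_value, fdr = dmps$fdr,
                    delta_beta = dmps$delta_beta,
                    stringsAsFactors = FALSE)
  # stable position order within chromosome (ties keep input order)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  if (anyDuplicated(paste(tab$chrom, tab$pos)))
    message("duplicate CpG positions present; resolved by input order")

  out <- list()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    sig <- !is.na(sub$fdr) & sub$fdr < fdr_threshold
    run_start <- NULL
    flush <- function(i_end) {
      if (is.null(run_start)) return()
      members <- sub[run_start:i_end, , drop = FALSE]
      if (nrow(members) >= min_cpgs)
        out[[length(out) + 1L]] <<- summarise_region(members)
      run_start <<- NULL
    }
    for (i in seq_len(nrow(sub))) {
      if (!sig[i]) { flush(i - 1L); next }
      if (is.null(run_start)) { run_start <- i; next }
      if (sub$pos[i] - sub$pos[i - 1L] > max_gap) {
        flush(i - 1L)
        run_start <- i
      }
    }
    flush(nrow(sub))
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_cpgs = integer(0), member_cpgs = character(0),
                      stouffer_z = numeric(0), stouffer_p = numeric(0),
                      mean_delta_beta = numeric(0), direction = character(0),
                      mixed_sign = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$stouffer_p), , drop = FALSE]
  res$region_id <- sprintf("dmr_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("region_id", setdiff(names(res), "region_id"))]
}

summarise_region <- function(members) {
  mean_delta <- mean(members$delta_beta)
  dir_sign <- if (mean_delta >= 0) 1 else -1
  # one-sided p in the region's dominant direction
  p_one <- ifelse(sign(members$delta_beta) == dir_sign,
                  members$p_value / 2, 1 - members$p_value / 2)
  sc <- stouffer_combine(p_one)
  data.frame(chrom = members$chrom[1],
             start = min(members$pos), end = max(members$pos),
             n_cpgs = nrow(members),
             member_cpgs = paste(members$cpg_id, collapse = ","),
             stouffer_z = sc$z, stouffer_p = sc$p,
             mean_delta_beta = mean_delta,
             direction = if (mean_delta > 0) "hyper" else "hypo",
             mixed_sign = length(unique(sign(members$delta_beta))) > 1,
             stringsAsFactors = FALSE)
}

#' Convert a DMR table to/from BED intervals
#'
#' DMR coordinates are 1-based inclusive (first/last member CpG); BED is
#' 0-based half-open, so `bed_start = start - 1`, `bed_end = end`.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param bed data.frame with `chrom`, `start`, `end`, `name`.
#' @return `dmr_to_bed`: a BED-style data.frame; `bed_to_dmr_coords`:
#'   a data.frame with 1-based inclusive `start`/`end`.
#' @export
dmr_to_bed <- function(dmrs) {
  data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
             name = dmrs$region_id, stringsAsFactors = FALSE)
}

#' @rdname dmr_to_bed
#' @export
bed_to_dmr_coords <- function(bed) {
  data.frame(chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
             region_id = bed$name, stringsAsFactors = FALSE)
}
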