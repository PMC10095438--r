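#' Convert methylation beta values to M values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[eps, 1 - eps]` so the transform is total. Strictly increasing, with
#' `beta = 0.5` mapping to `M = 0`.
#'
#' @param beta numeric vector/matrix of beta values in `[0, 1]`.
#' @param eps clipping bound.
#' @return M values, same shape as the input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Specify the per-CpG differential-methylation design
#'
#' The group term is always present; covariates are drawn from the sample
#' table. Only five of the six cell fractions enter the design (they sum to
#' one, so all six would be collinear; granulocytes are the dropped
#' reference).
#'
#' @param scale response scale, `"beta"` (default) or `"m_value"`.
#' @param covariates character vector of covariate names: any of `"age"`,
#'   `"sex"` and the cell-fraction columns `CD8T`, `CD4T`, `NK`, `Bcell`,
#'   `Mono` (or the shorthand `"cell_fractions"` which expands to those
#'   five).
#' @return a `design_spec` list.
#' @export
design_spec <- function(scale = c("beta", "m_value"),
                        covariates = c("age", "sex", "cell_fractions")) {
  scale <- match.arg(scale)
  if ("cell_fractions" %in% covariates) {
    covariates <- c(setdiff(covariates, "cell_fractions"),
                    setdiff(CELL_TYPES, "Gran"))
  }
  structure(list(scale = scale, covariates = unique(covariates)),
            class = "design_spec")
}

build_design_matrix <- function(samples, design) {
  n <- nrow(samples)
  X <- cbind(intercept = rep(1, n),
             group = as.numeric(samples$group == "case"))
  for (cv in design$covariates) {
    if (!cv %in% names(samples))
      stop("covariate not in sample table: ", cv, call. = FALSE)
    col <- samples[[cv]]
    if (cv == "sex") col <- as.numeric(col == "M")
    X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- cv
  }
  if (anyNA(X)) stop("missing values in design columns", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Test each CpG for differential methylation
#'
#' Ordinary least squares of the response (beta values by default) on
#' intercept + group + covariates, per CpG, with a two-sided t test on the
#' group coefficient and Benjamini-Hochberg FDR across all tested CpGs.
#' `delta_beta` is always the covariate-adjusted group coefficient on the
#' beta scale, so direction labels stay interpretable when tests are run
#' on M values.
#'
#' CpGs with zero residual variance cannot carry a t statistic: their p and
#' FDR are `NA`, they are excluded from the FDR denominator, and flagged in
#' the `degenerate` column.
#'
#' @param beta CpG x sample matrix of beta values.
#' @param samples sample table with `group` and the design covariates.
#' @param design a [design_spec()].
#' @return data.frame (one row per CpG, sorted by p) with columns `cpg_id`,
#'   `delta_beta`, `t_stat`, `p_value`, `fdr`, `direction`, `degenerate`.
#' @export
fit_dmps <- function(beta, samples, design = design_spec()) {
  stopifnot(is.matrix(beta), ncol(beta) == nrow(samples))
  X <- build_design_matrix(samples, design)
  assert_that(nrow(X) > ncol(X) + 2,
              "need n_samples > n_covariates + 2")
  Y_beta <- t(beta)                       # n x p
  Y <- if (design$scale == "m_value") beta_to_m(Y_beta) else Y_beta

  fit <- fit_group_ols(X, Y)
  # beta-scale group coefficient for delta_beta, whatever the test scale
  delta_beta <- if (design$scale == "beta") fit$coef
                else fit_group_ols(X, Y_beta)$coef

  degenerate <- fit$sigma2 <= .Machine$double.eps * 100
  p <- ifelse(degenerate, NA_real_, fit$p)
  res <- data.frame(cpg_id = rownames(beta),
                    delta_beta = delta_beta,
                    t_stat = ifelse(degenerate, NA_real_, fit$t),
                    p_value = p,
                    fdr = bh_fdr(p),
                    direction = ifelse(delta_beta > 0, "hyper", "hypo"),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  res[order(res$p_value), , drop = FALSE]
}

# Shared OLS kernel: one design matrix, many response columns.
# Returns the group coefficient, its t statistic and two-sided p.
fit_group_ols <- function(X, Y) {
  n <- nrow(X); k <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)              # k x p
  resid <- Y - X %*% B
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  g <- match("group", colnames(X))
  se <- sqrt(sigma2 * XtXi[g, g])
  coef <- B[g, ]
  t <- coef / se
  list(coef = unname(coef), t = unname(t),
       p = unname(2 * stats::pt(-abs(t), df)), sigma2 = unname(sigma2),
       df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity, mapped back to input order.
#' `NA` entries (degenerate tests) pass through as `NA` and do not count
#' toward the adjustment denominator.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Is a CpG in a gene's promoter region?
#'
#' A CpG counts as promoter-associated when its annotated feature is 5'UTR
#' or first exon, or when it lies within the 1500 bp window immediately
#' upstream of the transcription start site (strand-oriented).
#'
#' @param cpg one-row data.frame / list with `chrom`, `pos`, `feature`.
#' @param gene one-row data.frame / list with `chrom`, `strand`, `tss`.
#' @return logical.
#' @export
annotate_promoter <- function(cpg, gene) {
  assert_that(cpg$chrom == gene$chrom, "CpG and gene on different chromosomes")
  if (cpg$feature %in% c("5UTR", "1stExon")) return(TRUE)
  if (!gene$strand %in% c("+", "-"))
    stop("unknown strand: ", gene$strand, call. = FALSE)
  if (gene$strand == "+")
    cpg$pos >= gene$tss - 1500 && cpg$pos <= gene$tss - 1
  else
    cpg$pos >= gene$tss + 1 && cpg$pos <= gene$tss + 1500
}

#' Estimate blood cell-type fractions from bulk methylation
#'
#' Reference-based deconvolution: each bulk beta profile over marker CpGs is
#' projected onto the reference cell-type profiles by least squares under
#' the constraints `fractions >= 0` and `sum(fractions) <= 1`. The
#' constrained quadratic program is solved exactly by enumerating active
#' sets (KKT systems), which is cheap at six cell types and deterministic.
#'
#' @param bulk_beta marker-CpG x sample matrix.
#' @param reference marker-CpG x cell-type matrix of reference profiles.
#' @return cell-type x sample matrix of fractions.
#' @export
estimate_cell_fractions <- function(bulk_beta, reference) {
  bulk_beta <- as.matrix(bulk_beta)
  reference <- as.matrix(reference)
  assert_that(nrow(reference) >= ncol(reference),
              "need at least as many marker CpGs as cell types")
  if (!is.null(rownames(bulk_beta)) && !is.null(rownames(reference))) {
    assert_that(all(rownames(bulk_beta) %in% rownames(reference)),
                "reference does not cover all marker CpGs")
    reference <- reference[rownames(bulk_beta), , drop = FALSE]
  }
  if (qr(reference)$rank < ncol(reference))
    stop("reference profile matrix is rank-deficient", call. = FALSE)
  out <- apply(bulk_beta, 2, function(b) ls_simplex(reference, b))
  rownames(out) <- colnames(reference)
  out
}

# Minimise ||A f - b||^2 subject to f >= 0 and sum(f) <= 1, by exhaustive
# active-set enumeration (exact for small ncol(A)).
ls_simplex <- function(A, b) {
  k <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^k - 1)) {
    zero <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    free <- setdiff(seq_len(k), zero)
    for (sum_active in c(FALSE, TRUE)) {
      f <- numeric(k)
      if (length(free) > 0) {
        Af <- A[, free, drop = FALSE]
        if (!sum_active) {
          sol <- tryCatch(qr.solve(Af, b), error = function(e) NULL)
        } else {
          # equality sum(f_free) = 1 via KKT system
          G <- crossprod(Af); d <- crossprod(Af, b)
          ones <- rep(1, length(free))
          K <- rbind(cbind(G, ones), c(ones, 0))
          sol <- tryCatch(solve(K, c(d, 1))[seq_along(free)],
                          error = function(e) NULL)
        }
        if (is.null(sol)) next
        f[free] <- sol
      } else if (sum_active) next
      if (any(f < -1e-10) || sum(f) > 1 + 1e-10) next
      obj <- sum((A %*% f - b)^2)
      if (obj < best_obj - 1e-15) { best_obj <- obj; best <- f }
    }
  }
  pmax(best, 0)
}
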