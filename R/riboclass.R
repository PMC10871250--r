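# Differential expression, translational-efficiency testing and the
# regulatory gene classification on paired RNA-seq/Ribo-seq counts.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with all-
#' positive counts) of the ratio between the sample's count and the gene's
#' geometric mean across samples.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return numeric vector of positive size factors, one per sample.
#' @export
sizeFactorsMoR <- function(counts) {
  stopIfNot(is.matrix(counts) && all(counts >= 0),
            "counts must be a nonnegative matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop(paste("no gene has positive counts in every sample; a",
               "pseudo-reference fallback would be needed and is not",
               "silently applied"))
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - geo)))
  unname(sf)
}

# Per-group method-of-moments dispersion: on normalized counts z = y/s,
# Var(z) ~ mu * mean(1/s) + alpha * mu^2 within a design cell; pooled over
# cells weighted by residual df.
dispersionMoM <- function(counts, sizeFactors, group) {
  z <- sweep(counts, 2, sizeFactors, "/")
  gs <- split(seq_len(ncol(counts)), group)
  gs <- Filter(function(i) length(i) >= 2, gs)
  num <- den <- numeric(nrow(counts))
  for (idx in gs) {
    m <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1, var)
    xi <- mean(1 / sizeFactors[idx])
    w <- length(idx) - 1
    num <- num + w * (v - m * xi)
    den <- den + w * m^2
  }
  ifelse(den > 0, num / den, NA_real_)  # unclamped: trend fitting needs the
}                                       # mean-zero noise of null genes

#' Estimate per-gene NB dispersions with a local mean trend
#'
#' Gene-wise method-of-moments estimates, a smooth mean-based local
#' regression of dispersion on log mean expression (the "local" fit), and
#' empirical-Bayes shrinkage of the gene-wise values toward that trend. The
#' shrinkage weight is set per gene from the ratio of the expected sampling
#' variance of the moment estimator to the total observed spread around the
#' trend, so that homogeneous dispersions collapse onto the trend while
#' genuine gene-to-gene dispersion differences are retained. Dispersions are
#' floored at 1e-8; all-zero genes are returned NA and flagged.
#'
#' @param counts genes x samples count matrix.
#' @param sizeFactors per-sample positive factors.
#' @param group design-cell label per sample (factor or character).
#' @param span span of the local trend fit (default 0.3).
#' @return data.frame with baseMean, dispGeneWise, dispTrend, dispersion,
#'   allZero.
#' @export
estimateDispersionsNB <- function(counts, sizeFactors, group, span = 0.3) {
  stopIfNot(length(sizeFactors) == ncol(counts) && all(sizeFactors > 0),
            "need one positive size factor per sample")
  nGroups <- length(unique(group))
  stopIfNot(ncol(counts) - nGroups >= 2,
            "need >= 2 residual degrees of freedom")
  z <- sweep(counts, 2, sizeFactors, "/")
  baseMean <- rowMeans(z)
  allZero <- rowSums(counts) == 0
  gwRaw <- dispersionMoM(counts, sizeFactors, group)
  gwRaw[allZero] <- NA_real_
  # mean-based local regression of the unclamped gene-wise values on log
  # mean: clamping or log-transforming first would bias the trend downward
  # at these small sample sizes (the estimates are heavily right-skewed)
  use <- !allZero & baseMean > 0 & is.finite(gwRaw)
  if (sum(use) >= 20) {
    lo <- stats::loess(y ~ x,
                       data = data.frame(x = log(baseMean[use]), y = gwRaw[use]),
                       span = span, degree = 1, family = "gaussian",
                       control = stats::loess.control(surface = "direct"))
    trend <- rep(NA_real_, length(gwRaw))
    xq <- pmin(pmax(log(pmax(baseMean, 1e-8)), min(lo$x)), max(lo$x))
    trend <- stats::predict(lo, newdata = data.frame(x = xq))
  } else {
    trend <- rep(if (any(use)) mean(gwRaw[use]) else 0.01, length(gwRaw))
  }
  trend <- pmax(trend, 1e-8)
  residDf <- ncol(counts) - nGroups
  # sampling variance of the moment estimator: ~ 2 (alpha + E[1/s]/mu)^2 / df
  xi <- mean(1 / sizeFactors)
  sampVar <- 2 * (trend + xi / pmax(baseMean, 1e-8))^2 / residDf
  excess <- mean((gwRaw[use] - trend[use])^2 - sampVar[use], na.rm = TRUE)
  tau2 <- max(excess, 0)
  w <- sampVar / (sampVar + tau2)
  disp <- pmax(w * trend + (1 - w) * pmax(gwRaw, 0), 1e-8)
  disp[allZero] <- NA_real_
  data.frame(baseMean = baseMean, dispGeneWise = pmax(gwRaw, 0),
             dispTrend = trend, dispersion = disp, allZero = allZero,
             row.names = rownames(counts))
}

# Per-gene NB GLM with fixed dispersion and log link; returns natural-log
# coefficients and their Wald SEs from the Fisher information.
nbGlmFit <- function(y, X, offset, alpha) {
  fam <- if (alpha <= 1e-8) stats::poisson(link = "log")
         else MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(coef = fit$coefficients, se = sqrt(pmax(diag(cov), 0)))
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-gene NB log-linear model with log size factors as offsets and
#' dispersions from [estimateDispersionsNB()]. The Wald statistic is the
#' chosen coefficient over its standard error, with a two-sided normal
#' p-value and Benjamini-Hochberg adjustment. Effects are reported in log2.
#'
#' @param counts genes x samples count matrix.
#' @param condition per-sample condition label; the first level of
#'   \code{factor(condition)} (or \code{reference}) is the baseline.
#' @param sizeFactors optional; median-of-ratios by default.
#' @param dispersions optional per-gene dispersions; estimated by default.
#' @param reference optional reference condition level.
#' @return data.frame (DEResult) with baseMean, log2FC, lfcSE, stat, pvalue,
#'   padj; non-converged or all-zero genes carry NA statistics.
#' @export
nbWaldTest <- function(counts, condition, sizeFactors = NULL,
                       dispersions = NULL, reference = NULL) {
  condition <- as.character(condition)
  stopIfNot(length(condition) == ncol(counts),
            "one condition label per sample is required")
  stopIfNot(length(unique(condition)) == 2, "exactly two conditions")
  if (is.null(reference)) reference <- sort(unique(condition))[1]
  cond <- factor(condition, levels = c(reference,
                                       setdiff(unique(condition), reference)))
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMoR(counts)
  if (is.null(dispersions))
    dispersions <- estimateDispersionsNB(counts, sizeFactors, cond)$dispersion
  X <- stats::model.matrix(~cond)
  off <- log(sizeFactors)
  baseMean <- rowMeans(sweep(counts, 2, sizeFactors, "/"))
  m <- nrow(counts)
  l2 <- se <- stat <- p <- rep(NA_real_, m)
  for (g in seq_len(m)) {
    if (baseMean[g] == 0 || is.na(dispersions[g])) next
    fit <- nbGlmFit(counts[g, ], X, off, dispersions[g])
    if (is.null(fit)) next
    l2[g] <- fit$coef[2] / log(2)
    se[g] <- fit$se[2] / log(2)
    if (se[g] > 0) {
      stat[g] <- l2[g] / se[g]
      p[g] <- 2 * pnorm(-abs(stat[g]))
    }
  }
  data.frame(baseMean = baseMean, log2FC = l2, lfcSE = se, stat = stat,
             pvalue = p, padj = bhAdjust(p), row.names = rownames(counts))
}

#' Shrink log2 fold changes with a zero-centered normal prior
#'
#' Empirical-Bayes MAP under LFC ~ N(0, tau^2) with the normal likelihood
#' approximation LFC_hat ~ N(LFC, lfcSE^2): the estimate is scaled by
#' tau^2 / (tau^2 + lfcSE^2), so genes with uncertain (low-count) estimates
#' are pulled toward zero while well-measured ones are nearly untouched.
#' The prior variance is fit from the observed LFC distribution by moment
#' matching (var(LFC_hat) minus the median squared SE). P-values are not
#' altered.
#'
#' @param deResult data.frame from [nbWaldTest()].
#' @return The input with an added \code{log2FCShrunk} column.
#' @export
shrinkLFC <- function(deResult) {
  stopIfNot(all(c("log2FC", "lfcSE") %in% names(deResult)),
            "deResult needs log2FC and lfcSE")
  ok <- is.finite(deResult$log2FC) & is.finite(deResult$lfcSE)
  tau2 <- max(var(deResult$log2FC[ok]) - median(deResult$lfcSE[ok]^2),
              1e-3)
  shrunk <- deResult$log2FC * tau2 / (tau2 + deResult$lfcSE^2)
  deResult$log2FCShrunk <- shrunk
  deResult
}

#' Translation-efficiency interaction test
#'
#' Joint per-gene NB model over RNA-seq and Ribo-seq samples with terms
#' condition + assay + condition:assay, assay-specific size-factor offsets
#' and a single shared dispersion per gene (the Riborex simplification). The
#' TE log2 fold change is the interaction coefficient: the part of the
#' ribosome-occupancy change not explained by the mRNA-abundance change.
#'
#' @param rnaCounts,riboCounts genes x samples count matrices sharing genes.
#' @param rnaCondition,riboCondition per-sample condition labels.
#' @param reference optional reference condition level.
#' @return data.frame (TEResult) with baseMean, te_log2FC, lfcSE, stat,
#'   pvalue, padj.
#' @export
teInteractionTest <- function(rnaCounts, riboCounts, rnaCondition,
                              riboCondition, reference = NULL) {
  stopIfNot(identical(rownames(rnaCounts), rownames(riboCounts)),
            "RNA and Ribo matrices must share gene ids")
  condition <- c(as.character(rnaCondition), as.character(riboCondition))
  stopIfNot(length(unique(condition)) == 2, "exactly two conditions")
  both <- table(c(rep("RNA", ncol(rnaCounts)), rep("RIBO", ncol(riboCounts))),
                condition)
  stopIfNot(all(both > 0), "every (assay, condition) cell needs samples")
  if (is.null(reference)) reference <- sort(unique(condition))[1]
  counts <- cbind(rnaCounts, riboCounts)
  assay <- factor(c(rep("RNA", ncol(rnaCounts)),
                    rep("RIBO", ncol(riboCounts))),
                  levels = c("RNA", "RIBO"))
  cond <- factor(condition, levels = c(reference,
                                       setdiff(unique(condition), reference)))
  sf <- c(sizeFactorsMoR(rnaCounts), sizeFactorsMoR(riboCounts))
  disp <- estimateDispersionsNB(counts, sf, interaction(assay, cond))$dispersion
  X <- stats::model.matrix(~ cond * assay)
  off <- log(sf)
  baseMean <- rowMeans(sweep(counts, 2, sf, "/"))
  m <- nrow(counts)
  l2 <- se <- stat <- p <- rep(NA_real_, m)
  for (g in seq_len(m)) {
    if (baseMean[g] == 0 || is.na(disp[g])) next
    fit <- nbGlmFit(counts[g, ], X, off, disp[g])
    if (is.null(fit)) next
    l2[g] <- fit$coef[4] / log(2)
    se[g] <- fit$se[4] / log(2)
    if (se[g] > 0) {
      stat[g] <- l2[g] / se[g]
      p[g] <- 2 * pnorm(-abs(stat[g]))
    }
  }
  data.frame(baseMean = baseMean, te_log2FC = l2, lfcSE = se, stat = stat,
             pvalue = p, padj = bhAdjust(p), row.names = rownames(counts))
}

#' Classify genes into translational-regulation categories
#'
#' Applies the category rules on the RNA-seq, Ribo-seq and TE test results:
#' only genes with RNA baseMean and Ribo baseMean above
#' \code{baseMeanMin} are considered; \emph{Buffering up/down} requires RNA
#' padj < \code{padjBuffering} with the matching RNA LFC sign and no
#' significant ribosome-occupancy change (Ribo padj >= \code{padjSig});
#' \emph{Ribo ocp up/down} requires Ribo padj < \code{padjSig};
#' \emph{RNA abundance up/down} requires padj < \code{padjSig} in both assays
#' with concordant LFC signs (discordant significant pairs are flagged but
#' receive no canonical direction); \emph{TE up/down} requires TE padj <
#' \code{padjSig}. Flags are independent and multi-label; the canonical
#' label resolves overlaps by the precedence
#' RNA_abundance > Buffering > TE > Ribo_ocp (buffering - an RNA change with
#' flat ribosome occupancy - is the more specific call than the TE change it
#' implies).
#'
#' @param rna,ribo data.frames from [nbWaldTest()] (shared gene ids).
#' @param te data.frame from [teInteractionTest()].
#' @param baseMeanMin expression filter (default 20).
#' @param padjBuffering RNA padj cutoff for buffering (default 0.01).
#' @param padjSig padj cutoff for the other rules (default 0.05).
#' @return data.frame (GeneClassification) with the eight logical flags,
#'   \code{discordant}, \code{passed_basemean_filter} and \code{label}.
#' @export
classifyGenes <- function(rna, ribo, te, baseMeanMin = 20,
                          padjBuffering = 0.01, padjSig = 0.05) {
  stopIfNot(identical(rownames(rna), rownames(ribo)) &&
              identical(rownames(rna), rownames(te)),
            "rna, ribo and te must share gene ids")
  sig <- function(padj, cut) !is.na(padj) & padj < cut
  pass <- rna$baseMean > baseMeanMin & ribo$baseMean > baseMeanMin
  rnaSig <- sig(rna$padj, padjSig)
  riboSig <- sig(ribo$padj, padjSig)
  rnaBuf <- sig(rna$padj, padjBuffering)
  teSig <- sig(te$padj, padjSig)
  riboQuiet <- is.na(ribo$padj) | ribo$padj >= padjSig
  up <- function(x) !is.na(x) & x > 0
  dn <- function(x) !is.na(x) & x < 0
  fl <- data.frame(
    te_up = pass & teSig & up(te$te_log2FC),
    te_down = pass & teSig & dn(te$te_log2FC),
    rna_abundance_up = pass & rnaSig & riboSig & up(rna$log2FC) & up(ribo$log2FC),
    rna_abundance_down = pass & rnaSig & riboSig & dn(rna$log2FC) & dn(ribo$log2FC),
    buffering_up = pass & rnaBuf & up(rna$log2FC) & riboQuiet,
    buffering_down = pass & rnaBuf & dn(rna$log2FC) & riboQuiet,
    ribo_ocp_up = pass & riboSig & up(ribo$log2FC),
    ribo_ocp_down = pass & riboSig & dn(ribo$log2FC),
    row.names = rownames(rna))
  fl$discordant <- pass & rnaSig & riboSig &
    ((up(rna$log2FC) & dn(ribo$log2FC)) | (dn(rna$log2FC) & up(ribo$log2FC)))
  lab <- rep("NS", nrow(fl))
  lab[fl$ribo_ocp_up] <- "Ribo ocp up"
  lab[fl$ribo_ocp_down] <- "Ribo ocp down"
  lab[fl$te_up] <- "TE up"
  lab[fl$te_down] <- "TE down"
  lab[fl$buffering_up] <- "Buffering up"
  lab[fl$buffering_down] <- "Buffering down"
  lab[fl$rna_abundance_up] <- "RNA abundance up"
  lab[fl$rna_abundance_down] <- "RNA abundance down"
  fl$passed_basemean_filter <- pass
  fl$label <- lab
  fl
}

#' Regression of TE changes on RNA changes
#'
#' Ordinary least squares of per-gene delta-TE on delta-RNA with the adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - 2).
#'
#' @param teLfc,rnaLfc per-gene log2 fold changes (equal length, >= 3
#'   finite pairs).
#' @return list with slope, intercept, r2, adjR2, n.
#' @importFrom stats lm coef
#' @export
deltaTeRnaRegression <- function(teLfc, rnaLfc) {
  ok <- is.finite(teLfc) & is.finite(rnaLfc)
  stopIfNot(sum(ok) >= 3, "need >= 3 genes with finite values")
  x <- rnaLfc[ok]; y <- teLfc[ok]
  stopIfNot(var(x) > 0, "zero variance in delta-RNA")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, adjR2 = s$adj.r.squared, n = sum(ok))
}

#' Spearman correlation
#'
#' Pearson correlation of ranks with average ranks for ties (via
#' \code{stats::cor}); constant vectors yield NA with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Spearman's rho, or NA for degenerate input.
#' @importFrom stats cor
#' @export
spearmanCorrelation <- function(x, y) {
  stopIfNot(length(x) == length(y) && length(x) >= 3,
            "x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity (delegates to
#' \code{stats::p.adjust}); NAs are preserved.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values.
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
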