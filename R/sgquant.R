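# Stress-granule segmentation and per-cell quantification.

# 8-connected labeling: 4-connected pass (EBImage::bwlabel) followed by
# union-find merging of labels that touch diagonally.
label8 <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  K <- max(lab)
  if (K <= 1L) return(relabelContiguous(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  cc <- lab[-nr, -1]; d <- lab[-1, -nc]
  s1 <- a > 0 & b > 0 & a != b
  s2 <- cc > 0 & d > 0 & cc != d
  pairs <- rbind(cbind(a[s1], b[s1]), cbind(cc[s2], d[s2]))
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(K), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  relabelContiguous(out)
}

sizeFilterLabels <- function(lab, minArea, maxArea = Inf) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < minArea | areas > maxArea)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabelContiguous(lab)
}

#' Rescale image intensities by a constant factor
#'
#' @param image numeric matrix.
#' @param factor positive scalar divisor.
#' @return The image with every pixel divided by \code{factor}.
#' @export
rescaleIntensity <- function(image, factor) {
  stopIfNot(is.numeric(factor) && length(factor) == 1L && factor > 0,
            "factor must be a positive scalar")
  image / factor
}

#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Bins intensities into \code{nbins} equal-width bins over the observed
#' range and returns the cut maximizing the between-class variance
#' \eqn{w_1 w_2 (\mu_1 - \mu_2)^2}. Ties are broken toward the lower
#' threshold. A histogram (list with \code{counts} and \code{mids}) may be
#' supplied instead of an image.
#'
#' @param x numeric matrix/vector of intensities, or a list with elements
#'   \code{counts} and \code{mids} (e.g. from [graphics::hist()]).
#' @param nbins number of histogram bins (ignored for histogram input).
#' @return The threshold value: pixels strictly above it are foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  if (is.list(x) && all(c("counts", "mids") %in% names(x))) {
    ct <- as.numeric(x$counts)
    centers <- as.numeric(x$mids)
  } else {
    v <- as.numeric(x)
    v <- v[is.finite(v)]
    rng <- range(v)
    if (diff(rng) == 0)
      stop("degenerate input: constant image has no Otsu threshold")
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    bin <- pmin(nbins, pmax(1L, findInterval(v, br, rightmost.closed = TRUE)))
    ct <- as.numeric(tabulate(bin, nbins))
    centers <- (br[-1] + br[-(nbins + 1L)]) / 2
  }
  ct <- as.numeric(ct)
  n <- length(ct)
  if (sum(ct > 0) < 2L)
    stop("degenerate input: need at least two distinct intensity values")
  w1 <- cumsum(ct)
  m1 <- cumsum(ct * centers)
  tot <- w1[n]; mt <- m1[n]
  tcand <- seq_len(n - 1L)
  w1t <- w1[tcand]; w2t <- tot - w1t
  valid <- w1t > 0 & w2t > 0
  mu1 <- m1[tcand] / w1t
  mu2 <- (mt - m1[tcand]) / w2t
  bcv <- ifelse(valid, w1t * w2t * (mu1 - mu2)^2, -Inf)
  tbest <- tcand[which.max(bcv)]    # which.max: first maximum = lower cut
  (centers[tbest] + centers[tbest + 1L]) / 2
}

#' Segment nuclei by Otsu thresholding
#'
#' Otsu-thresholds the nuclear channel, fills holes, labels 8-connected
#' components and removes components outside the area bounds.
#'
#' @param nuclear numeric matrix, nuclear-stain channel.
#' @param minArea,maxArea retained component area bounds in px^2.
#' @return A [LabelMask-class] of kind "nuclei".
#' @export
segmentNuclei <- function(nuclear, minArea = 50, maxArea = Inf) {
  thr <- tryCatch(otsuThreshold(nuclear), error = function(e) NULL)
  empty <- function() {
    warning("no nuclei found; returning empty mask")
    labelMask(matrix(0L, nrow(nuclear), ncol(nuclear)), "nuclei")
  }
  if (is.null(thr)) return(empty())
  fg <- nuclear > thr
  if (!any(fg)) return(empty())
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  lab <- sizeFilterLabels(label8(fg), minArea, maxArea)
  if (max(lab) == 0L) return(empty())
  labelMask(lab, "nuclei")
}

#' Segment single cells by propagation from nuclear seeds
#'
#' Seeded propagation (the CellProfiler-style algorithm, via
#' \code{EBImage::propagate}) grows each nucleus label across the cytoplasmic
#' foreground, trading local intensity differences against geometric distance
#' through \code{regularization}. The foreground is the Otsu-thresholded
#' reporter channel; cell regions partition it and each cell contains exactly
#' its seeding nucleus.
#'
#' @param cyto numeric matrix, reporter/cytoplasm channel.
#' @param nuclei [LabelMask-class] of nuclear seeds.
#' @param regularization nonnegative weight of geometric distance relative to
#'   intensity differences (0 = pure intensity propagation).
#' @return A [LabelMask-class] of kind "cells" sharing label ids with
#'   \code{nuclei}.
#' @export
segmentCells <- function(cyto, nuclei, regularization = 0.05) {
  stopIfNot(identical(dim(cyto), dim(labels2d(nuclei))),
            "cyto and nuclei dimensions differ")
  seeds <- labels2d(nuclei)
  if (max(seeds) == 0L)
    return(labelMask(matrix(0L, nrow(cyto), ncol(cyto)), "cells"))
  thr <- tryCatch(otsuThreshold(cyto), error = function(e) min(cyto) - 1)
  fg <- cyto > thr | seeds > 0
  rng <- range(cyto)
  cytoN <- if (diff(rng) > 0) (cyto - rng[1]) / diff(rng) else cyto * 0
  p <- EBImage::propagate(EBImage::Image(cytoN), seeds = seeds, mask = fg,
                          lambda = regularization)
  lab <- EBImage::imageData(p)
  storage.mode(lab) <- "integer"
  labelMask(lab, "cells")
}

#' Detect foci by speckle enhancement and thresholding
#'
#' Enhances punctate structures with a white top-hat transform (disk
#' structuring element of radius \code{speckleRadius}), thresholds the
#' enhanced image (Otsu or a manual value), labels 8-connected components and
#' removes those below \code{minArea}. Structures wider than the disk are
#' suppressed by the top-hat, giving the size selectivity that distinguishes
#' granules from cell-scale intensity variation.
#'
#' @param reporter numeric matrix, reporter channel.
#' @param speckleRadius disk radius in px (default 6, about twice the
#'   expected focus radius).
#' @param thresholdMode "otsu" or "manual".
#' @param manualThreshold threshold on the top-hat image; required when
#'   \code{thresholdMode = "manual"}.
#' @param minArea minimum retained component area, px^2.
#' @return A [LabelMask-class] of kind "foci".
#' @export
detectFoci <- function(reporter, speckleRadius = 6,
                       thresholdMode = c("otsu", "manual"),
                       manualThreshold = NULL, minArea = 5) {
  thresholdMode <- match.arg(thresholdMode)
  stopIfNot(speckleRadius >= 1, "speckleRadius must be >= 1")
  if (thresholdMode == "manual" && is.null(manualThreshold))
    stop("manualThreshold is required when thresholdMode = \"manual\"")
  brush <- EBImage::makeBrush(2L * as.integer(speckleRadius) + 1L, "disc")
  empty0 <- labelMask(matrix(0L, nrow(reporter), ncol(reporter)), "foci")
  rng <- range(reporter)
  if (diff(rng) == 0) return(empty0)
  # grayscale morphology operates on [0, 1]; opening commutes with the affine
  # rescale, so the top-hat maps back to photon units exactly
  imgN <- (reporter - rng[1]) / diff(rng)
  th <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(imgN),
                                                brush)) * diff(rng)
  thr <- if (thresholdMode == "manual") manualThreshold
         else tryCatch(otsuThreshold(th), error = function(e) NULL)
  empty <- labelMask(matrix(0L, nrow(reporter), ncol(reporter)), "foci")
  if (is.null(thr)) return(empty)
  fg <- th > thr
  if (!any(fg)) return(empty)
  labelMask(sizeFilterLabels(label8(fg), minArea), "foci")
}

#' Filter foci by eccentricity and tabulate them
#'
#' Computes each focus' area, ellipse-equivalent eccentricity from second
#' central moments, intensity-weighted centroid and mean intensity, and
#' retains foci with eccentricity strictly below \code{maxEccentricity}
#' (default 0.875), removing elongated segmentation artifacts.
#'
#' @param foci [LabelMask-class] of kind "foci".
#' @param reporter numeric matrix used for intensity statistics.
#' @param maxEccentricity retain foci with eccentricity < this value.
#' @return data.frame (FociTable) with columns focus_id, cell_id (0 until
#'   assigned), area, eccentricity, row, col, mean_intensity.
#' @export
filterFoci <- function(foci, reporter, maxEccentricity = 0.875) {
  lab <- labels2d(foci)
  stopIfNot(identical(dim(lab), dim(reporter)),
            "foci mask and reporter dimensions differ")
  shape <- regionMoments(lab)
  if (!nrow(shape))
    return(data.frame(focus_id = integer(), cell_id = integer(),
                      area = numeric(), eccentricity = numeric(),
                      row = numeric(), col = numeric(),
                      mean_intensity = numeric()))
  wpos <- regionMoments(lab, weights = reporter)
  mi <- as.numeric(tapply(reporter[lab > 0], lab[lab > 0], mean))
  out <- data.frame(focus_id = shape$label, cell_id = 0L, area = shape$area,
                    eccentricity = shape$eccentricity,
                    row = wpos$row, col = wpos$col, mean_intensity = mi)
  out <- out[out$eccentricity < maxEccentricity, , drop = FALSE]
  out$focus_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign foci to cells and summarize per cell
#'
#' Each focus is assigned to the cell label under its intensity-weighted
#' centroid (0 = background, counted as unassigned). Every cell appears in
#' the output, with zeros when it carries no retained focus.
#'
#' @param fociTable data.frame from [filterFoci()].
#' @param cells [LabelMask-class] of kind "cells".
#' @param reporter numeric matrix for per-cell mean reporter intensity.
#' @return list with \code{cellTable} (cell_id, foci_count, total_foci_area,
#'   reporter_mean, has_foci), the updated \code{fociTable} (cell_id filled
#'   in), and \code{nUnassigned}.
#' @export
assignAndSummarize <- function(fociTable, cells, reporter) {
  lab <- labels2d(cells)
  stopIfNot(identical(dim(lab), dim(reporter)),
            "cells mask and reporter dimensions differ")
  K <- nObjects(cells)
  if (nrow(fociTable)) {
    ri <- pmin(nrow(lab), pmax(1L, as.integer(round(fociTable$row))))
    ci <- pmin(ncol(lab), pmax(1L, as.integer(round(fociTable$col))))
    fociTable$cell_id <- lab[cbind(ri, ci)]
  }
  repMean <- rep(NA_real_, K)
  if (K > 0) {
    mm <- tapply(reporter[lab > 0], lab[lab > 0], mean)
    repMean[as.integer(names(mm))] <- as.numeric(mm)
  }
  cnt <- area <- numeric(K)
  if (nrow(fociTable)) {
    assigned <- fociTable[fociTable$cell_id > 0, , drop = FALSE]
    if (nrow(assigned)) {
      tc <- tapply(rep(1, nrow(assigned)), assigned$cell_id, sum)
      ta <- tapply(assigned$area, assigned$cell_id, sum)
      cnt[as.integer(names(tc))] <- as.numeric(tc)
      area[as.integer(names(ta))] <- as.numeric(ta)
    }
  }
  cellTable <- data.frame(cell_id = seq_len(K), foci_count = as.integer(cnt),
                          total_foci_area = area, reporter_mean = repMean,
                          has_foci = cnt >= 1)
  list(cellTable = cellTable, fociTable = fociTable,
       nUnassigned = if (nrow(fociTable)) sum(fociTable$cell_id == 0) else 0L)
}

#' Run the whole per-field segmentation and quantification pipeline
#'
#' Convenience wrapper: intensity rescaling, nuclear Otsu segmentation,
#' propagation-based cell segmentation, top-hat focus detection, eccentricity
#' filtering and per-cell summarization.
#'
#' @param nuclear,reporter channel matrices.
#' @param rescaleFactor divisor applied to both channels before processing.
#' @param nucleusMinArea,nucleusMaxArea nuclear size gate, px^2.
#' @param regularization propagation regularization.
#' @param speckleRadius,thresholdMode,manualThreshold,fociMinArea focus
#'   detection parameters (see [detectFoci()]).
#' @param maxEccentricity focus eccentricity filter (see [filterFoci()]).
#' @return list with \code{nuclei}, \code{cells}, \code{fociMask} label
#'   masks, \code{fociTable}, \code{cellTable}, \code{nUnassigned}.
#' @export
quantifyField <- function(nuclear, reporter, rescaleFactor = 1,
                          nucleusMinArea = 50, nucleusMaxArea = Inf,
                          regularization = 0.05, speckleRadius = 6,
                          thresholdMode = "otsu", manualThreshold = NULL,
                          fociMinArea = 5, maxEccentricity = 0.875) {
  nuclear <- rescaleIntensity(nuclear, rescaleFactor)
  reporter <- rescaleIntensity(reporter, rescaleFactor)
  nuclei <- segmentNuclei(nuclear, nucleusMinArea, nucleusMaxArea)
  cells <- segmentCells(reporter, nuclei, regularization)
  fociMask <- detectFoci(reporter, speckleRadius, thresholdMode,
                         manualThreshold, fociMinArea)
  foci <- filterFoci(fociMask, reporter, maxEccentricity)
  res <- assignAndSummarize(foci, cells, reporter)
  list(nuclei = nuclei, cells = cells, fociMask = fociMask,
       fociTable = res$fociTable, cellTable = res$cellTable,
       nUnassigned = res$nUnassigned)
}

#' Summarize foci metrics per condition and timepoint
#'
#' Replicate-level percentages of cells with foci and means of per-cell foci
#' area/count are averaged across replicates; SEM = sd / sqrt(N_replicates)
#' over replicate-level values. QC flags mark conditions with fewer than 3
#' replicates or fewer than \code{minCells} cells in any replicate.
#'
#' @param cellData data.frame with one row per cell: columns condition,
#'   replicate, foci_count, total_foci_area, and optionally timepoint.
#' @param minCells per-replicate cell-count QC threshold (default 100).
#' @return data.frame per (condition, timepoint): pct_cells_with_foci (mean
#'   across replicates), pct_sem, mean_foci_area, area_sem, mean_foci_count,
#'   count_sem, n_replicates, min_cells, flag_few_replicates, flag_low_cells.
#' @export
summarizeCondition <- function(cellData, minCells = 100L) {
  stopIfNot(all(c("condition", "replicate", "foci_count",
                  "total_foci_area") %in% names(cellData)),
            "cellData needs condition, replicate, foci_count, total_foci_area")
  if (!"timepoint" %in% names(cellData)) cellData$timepoint <- NA_real_
  tpKey <- ifelse(is.na(cellData$timepoint), "", format(cellData$timepoint))
  grp <- paste(cellData$condition, tpKey, sep = "\001")
  out <- lapply(unique(grp), function(g) {
    d <- cellData[grp == g, , drop = FALSE]
    reps <- split(d, d$replicate)
    reps <- Filter(function(r) nrow(r) > 0, reps)
    pct <- vapply(reps, function(r) 100 * mean(r$foci_count >= 1), numeric(1))
    mar <- vapply(reps, function(r) mean(r$total_foci_area), numeric(1))
    mcn <- vapply(reps, function(r) mean(r$foci_count), numeric(1))
    ncl <- vapply(reps, nrow, integer(1))
    nrep <- length(reps)
    semOf <- function(v) if (nrep >= 2) sd(v) / sqrt(nrep) else NA_real_
    data.frame(condition = d$condition[1], timepoint = d$timepoint[1],
               pct_cells_with_foci = mean(pct), pct_sem = semOf(pct),
               mean_foci_area = mean(mar), area_sem = semOf(mar),
               mean_foci_count = mean(mcn), count_sem = semOf(mcn),
               n_replicates = nrep, min_cells = min(ncl),
               flag_few_replicates = nrep < 3,
               flag_low_cells = any(ncl < minCells))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

significanceTier <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 0.01) "**" else if (x < 0.05) "*" else "ns"
  }, character(1))
}

#' Compare per-cell metrics between conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of each condition's pooled
#' per-cell values against the reference condition, with the conventional
#' significance tiers (* p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001).
#'
#' @param values numeric per-cell metric.
#' @param group condition label per cell.
#' @param reference the reference condition.
#' @return data.frame with condition, n, p (floored at the smallest positive
#'   double), tier.
#' @importFrom stats wilcox.test
#' @export
compareConditions <- function(values, group, reference) {
  group <- as.character(group)
  stopIfNot(reference %in% group, "reference condition not present")
  ref <- values[group == reference]
  others <- setdiff(unique(group), reference)
  out <- lapply(others, function(g) {
    v <- values[group == g]
    stopIfNot(length(v) >= 2 && length(ref) >= 2,
              "each group needs >= 2 cells")
    p <- suppressWarnings(wilcox.test(v, ref, exact = FALSE)$p.value)
    p <- max(p, .Machine$double.xmin)
    data.frame(condition = g, n = length(v), p = p,
               tier = significanceTier(p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check reporter-expression matching across conditions
#'
#' Fractional deviation of each condition's median reporter intensity from
#' the reference median; conditions deviating by more than \code{threshold}
#' (strictly) are flagged, the expression-matching control used to exclude
#' expression-level confounds when comparing granule phenotypes.
#'
#' @param values numeric per-cell reporter means.
#' @param group condition label per cell.
#' @param reference reference condition.
#' @param threshold flag deviations strictly greater than this (default 0.25).
#' @return data.frame with condition, median, deviation, flagged.
#' @export
checkExpressionDeviation <- function(values, group, reference,
                                     threshold = 0.25) {
  group <- as.character(group)
  stopIfNot(reference %in% group, "reference condition not present")
  medRef <- median(values[group == reference])
  stopIfNot(is.finite(medRef) && medRef != 0,
            "reference median is zero or undefined")
  conds <- unique(group)
  dev <- vapply(conds, function(g)
    abs(median(values[group == g]) - medRef) / medRef, numeric(1))
  data.frame(condition = conds,
             median = vapply(conds, function(g)
               median(values[group == g]), numeric(1)),
             deviation = dev, flagged = dev > threshold, row.names = NULL)
}
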