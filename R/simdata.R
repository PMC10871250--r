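#' @importFrom stats rnorm rpois rnbinom runif dnorm pnorm median quantile
#'   lowess approx var sd
NULL

# ---- field generation --------------------------------------------------

placeCells <- function(spec) {
  n <- spec@nCells
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  if (n == 0L)
    return(data.frame(cell_id = integer(), row = numeric(), col = numeric(),
                      radius = numeric(), nucleus_radius = numeric()))
  cr <- pmax(spec@cellRadius[1] / 2,
             rnorm(n, spec@cellRadius[1], spec@cellRadius[2]))
  nr <- pmax(3, rnorm(n, spec@nucleusRadius[1], spec@nucleusRadius[2]))
  nr <- pmin(nr, 0.6 * cr)
  rows <- cols <- numeric(n)
  attempts <- 0L
  maxAttempts <- 500L * n
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(sprintf(paste0("could not place %d cells of radius ~%g in a ",
                            "%d x %d field without overlap; reduce nCells ",
                            "or cellRadius in the FieldSpec"),
                     n, spec@cellRadius[1], H, W))
      r <- runif(1, cr[i] + 1, H - cr[i] - 1)
      c <- runif(1, cr[i] + 1, W - cr[i] - 1)
      if (i == 1L) { rows[i] <- r; cols[i] <- c; break }
      j <- seq_len(i - 1L)
      if (all(sqrt((rows[j] - r)^2 + (cols[j] - c)^2) >= cr[j] + cr[i] + 2)) {
        rows[i] <- r; cols[i] <- c; break
      }
    }
  }
  data.frame(cell_id = seq_len(n), row = rows, col = cols, radius = cr,
             nucleus_radius = nr)
}

sampleFoci <- function(spec, cells, lambda) {
  out <- list()
  fid <- 0L
  for (i in seq_len(nrow(cells))) {
    k <- if (spec@fociExact) as.integer(round(lambda)) else rpois(1, lambda)
    if (k == 0L) next
    placed <- matrix(numeric(0), 0, 3)  # row, col, a
    for (f in seq_len(k)) {
      a <- max(1, rnorm(1, spec@focusRadius[1], spec@focusRadius[2]))
      b <- a * spec@focusAxisRatio
      theta <- runif(1, 0, pi)
      inner <- cells$nucleus_radius[i] + a + 1
      outer <- cells$radius[i] - a - 1
      if (outer <= inner) next
      ok <- FALSE
      for (try in 1:50) {
        rad <- sqrt(runif(1, (inner / outer)^2, 1)) * outer
        ang <- runif(1, 0, 2 * pi)
        fr <- cells$row[i] + rad * sin(ang)
        fc <- cells$col[i] + rad * cos(ang)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - fr)^2 + (placed[, 2] - fc)^2) >=
                placed[, 3] + a + 2)) { ok <- TRUE; break }
      }
      if (!ok) next
      placed <- rbind(placed, c(fr, fc, a))
      fid <- fid + 1L
      out[[length(out) + 1L]] <-
        data.frame(focus_id = fid, cell_id = cells$cell_id[i],
                   row = fr, col = fc, a = a, b = b, theta = theta)
    }
  }
  if (!length(out))
    return(data.frame(focus_id = integer(), cell_id = integer(),
                      row = numeric(), col = numeric(), a = numeric(),
                      b = numeric(), theta = numeric(), area = numeric(),
                      eccentricity = numeric()))
  foci <- do.call(rbind, out)
  foci$area <- NA_real_
  foci$eccentricity <- sqrt(1 - (foci$b / foci$a)^2)
  foci
}

renderField <- function(spec, cells, foci) {
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  ints <- spec@intensities
  nuclear <- matrix(ints[["background"]], H, W)
  reporter <- matrix(ints[["background"]], H, W)
  dims <- c(H, W)
  for (i in seq_len(nrow(cells))) {
    cellPx <- rasterEllipse(cells$row[i], cells$col[i], cells$radius[i],
                            cells$radius[i], 0, dims)
    nucPx <- rasterEllipse(cells$row[i], cells$col[i],
                           cells$nucleus_radius[i], cells$nucleus_radius[i],
                           0, dims)
    reporter[cellPx] <- ints[["background"]] + ints[["cytoplasm"]]
    # nuclei are dimmer than cytoplasm in the reporter channel, which is what
    # lets propagation from nuclear seeds find the cytoplasmic boundary
    reporter[nucPx] <- ints[["background"]] + 0.6 * ints[["cytoplasm"]]
    nuclear[nucPx] <- ints[["background"]] + ints[["nucleus"]]
  }
  fociLayer <- matrix(0, H, W)
  if (nrow(foci)) {
    for (f in seq_len(nrow(foci))) {
      px <- rasterEllipse(foci$row[f], foci$col[f], foci$a[f], foci$b[f],
                          foci$theta[f], dims)
      foci$area[f] <- nrow(px)
      fociLayer[px] <- ints[["focus"]]
    }
    # hard-edged ellipses mildly blurred to emulate optics; the truth area is
    # the pre-blur rasterized pixel count
    fociLayer <- gaussianBlur(fociLayer, 0.5)
    reporter <- reporter + fociLayer
  }
  list(nuclear = nuclear, reporter = reporter, foci = foci)
}

#' Generate one synthetic microscopy field
#'
#' Places non-overlapping cells (disk cytoplasm, dimmer disk nucleus in the
#' reporter channel, bright nucleus in the nuclear channel), samples elliptical
#' foci inside each cell's cytoplasmic annulus, renders them hard-edged plus a
#' 0.5 px Gaussian blur, and adds Gaussian read noise. The returned ground
#' truth describes the rendered geometry exactly (areas are rasterized pixel
#' counts).
#'
#' Determinism: for a fixed (spec, seed, timepoint) the output is
#' bit-identical; the caller's RNG state is untouched.
#'
#' @param spec a [FieldSpec-class].
#' @param seed integer seed.
#' @param timepoint acquisition time in minutes, or NULL (default) for a
#'   static field with foci unconditionally present. When given, foci are
#'   present only within \code{[condensationOnset, condensationOffset]}.
#' @return A [SyntheticField-class].
#' @examples
#' f <- generateField(fieldSpec(nCells = 3L, imageSize = c(128L, 128L),
#'                              cellRadius = c(22, 1)), seed = 1)
#' nrow(truthCells(f))
#' @export
generateField <- function(spec, seed, timepoint = NULL) {
  validObject(spec)
  cells <- withSeed(stageSeed(seed, "cells"), placeCells(spec))
  active <- is.null(timepoint) ||
    (timepoint >= spec@condensationOnset && timepoint <= spec@condensationOffset)
  lambda <- if (active) spec@fociPerCell else 0
  tkey <- if (is.null(timepoint)) "static" else format(timepoint)
  foci <- withSeed(stageSeed(seed, paste0("foci-", tkey)),
                   sampleFoci(spec, cells, lambda))
  rend <- renderField(spec, cells, foci)
  noisy <- withSeed(stageSeed(seed, paste0("noise-", tkey)), {
    n1 <- rend$nuclear +
      matrix(rnorm(length(rend$nuclear), 0, spec@noiseSd), nrow(rend$nuclear))
    n2 <- rend$reporter +
      matrix(rnorm(length(rend$reporter), 0, spec@noiseSd), nrow(rend$reporter))
    list(pmax(n1, 0), pmax(n2, 0))
  })
  cells$reporter_mean <- vapply(seq_len(nrow(cells)), function(i) {
    px <- rasterEllipse(cells$row[i], cells$col[i], cells$radius[i],
                        cells$radius[i], 0, spec@imageSize)
    mean(rend$reporter[px])
  }, numeric(1))
  cells$foci_count <- vapply(cells$cell_id, function(id)
    sum(rend$foci$cell_id == id), integer(1))
  new("SyntheticField", nuclearChannel = noisy[[1]],
      reporterChannel = noisy[[2]], truthCells = cells,
      truthFoci = rend$foci,
      timepoint = if (is.null(timepoint)) NA_real_ else timepoint)
}

#' Generate a live-imaging time course
#'
#' One field per timepoint in \code{spec@timepoints}. Cell positions persist
#' across timepoints (they depend only on spec and seed); foci are present
#' only between \code{condensationOnset} and \code{condensationOffset},
#' emulating transient granule assembly and disassembly under acute stress.
#'
#' @inheritParams generateField
#' @return A list of [SyntheticField-class], one per timepoint.
#' @export
generateTimecourse <- function(spec, seed) {
  stopIfNot(length(spec@timepoints) > 0, "spec@timepoints must be nonempty")
  lapply(spec@timepoints, function(tp) generateField(spec, seed, timepoint = tp))
}

# ---- count generation --------------------------------------------------

#' Design of a paired RNA-seq/Ribo-seq simulation
#'
#' Describes a two-condition experiment assayed by RNA-seq and ribosome
#' profiling with planted per-gene regulatory classes. Class semantics (log2
#' effects applied in the stressed/perturbed condition):
#' \describe{
#'   \item{NULL}{no change in either assay.}
#'   \item{TE_UP / TE_DOWN}{ribosome occupancy shifted by ±effect, RNA flat.}
#'   \item{BUFFERING_UP / BUFFERING_DOWN}{RNA shifted by ±effect, ribosome
#'     occupancy flat (mRNA abundance changes are translationally buffered).}
#'   \item{RNA_ABUNDANCE_UP / RNA_ABUNDANCE_DOWN}{both assays shifted
#'     concordantly by ±effect.}
#'   \item{RIBO_OCP_UP / RIBO_OCP_DOWN}{ribosome occupancy shifted, RNA flat
#'     (occupancy-only change).}
#' }
#'
#' @param nGenes number of genes.
#' @param classes named integer vector of planted class counts (names from
#'   the list above); genes not covered are NULL. Alternatively a length-
#'   \code{nGenes} character vector of explicit labels.
#' @param effectLfc absolute log2 effect applied to planted classes.
#' @param baselineMean per-gene baseline expression: a scalar, a length-
#'   \code{nGenes} vector, or NULL to draw log-normal means
#'   (meanlog log(100), sdlog 1).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2): scalar,
#'   per-gene vector, or NULL for the mean-dependent trend
#'   \code{0.01 + 2 / mu}.
#' @param nReplicates replicates per (assay, condition).
#' @param conditions two condition labels, reference first.
#' @param assays assay labels (RNA, RIBO).
#' @param genotype genotype label recorded in the metadata.
#' @param sizeFactors per-sample positive scale factors, or NULL for a mild
#'   deterministic spread exp(seq(-0.2, 0.2)).
#' @param seed integer seed stored in the design.
#' @return A list of class \code{"CountDesign"}.
#' @export
countDesign <- function(nGenes = 2000L,
                        classes = c(TE_UP = 0L),
                        effectLfc = 2,
                        baselineMean = NULL,
                        dispersion = NULL,
                        nReplicates = 3L,
                        conditions = c("control", "stress"),
                        assays = c("RNA", "RIBO"),
                        genotype = "WT",
                        sizeFactors = NULL,
                        seed = 1L) {
  known <- c("NULL", "TE_UP", "TE_DOWN", "BUFFERING_UP", "BUFFERING_DOWN",
             "RNA_ABUNDANCE_UP", "RNA_ABUNDANCE_DOWN", "RIBO_OCP_UP",
             "RIBO_OCP_DOWN")
  if (is.character(classes) && length(classes) == nGenes) {
    labels <- classes
  } else {
    stopIfNot(all(names(classes) %in% known),
              paste("unknown class in design; use one of:",
                    paste(known, collapse = ", ")))
    stopIfNot(sum(classes) <= nGenes, "more planted genes than nGenes")
    labels <- rep("NULL", nGenes)
    at <- 1L
    for (cl in names(classes)) {
      k <- classes[[cl]]
      if (k > 0) labels[at:(at + k - 1L)] <- cl
      at <- at + k
    }
  }
  stopIfNot(all(labels %in% known), "invalid class label")
  stopIfNot(nReplicates >= 2L, "need >= 2 replicates per (assay, condition)")
  stopIfNot(length(conditions) == 2L, "exactly two conditions")
  samples <- expand.grid(replicate = seq_len(nReplicates),
                         condition = conditions, assay = assays,
                         stringsAsFactors = FALSE)
  samples$genotype <- genotype
  samples$sample <- sprintf("%s_%s_%s_r%d", genotype, samples$assay,
                            samples$condition, samples$replicate)
  if (is.null(sizeFactors))
    sizeFactors <- exp(seq(-0.2, 0.2, length.out = nrow(samples)))
  stopIfNot(length(sizeFactors) == nrow(samples) && all(sizeFactors > 0),
            "sizeFactors must be positive, one per sample")
  if (!is.null(dispersion))
    stopIfNot(all(dispersion > 0), "dispersion must be positive")
  structure(list(nGenes = as.integer(nGenes), labels = labels,
                 effectLfc = effectLfc, baselineMean = baselineMean,
                 dispersion = dispersion, samples = samples,
                 conditions = conditions, sizeFactors = sizeFactors,
                 seed = as.integer(seed)),
            class = "CountDesign")
}

classLfc <- function(labels, effect) {
  rna <- ribo <- numeric(length(labels))
  rna[labels %in% c("BUFFERING_UP", "RNA_ABUNDANCE_UP")] <- effect
  rna[labels %in% c("BUFFERING_DOWN", "RNA_ABUNDANCE_DOWN")] <- -effect
  ribo[labels %in% c("TE_UP", "RNA_ABUNDANCE_UP", "RIBO_OCP_UP")] <- effect
  ribo[labels %in% c("TE_DOWN", "RNA_ABUNDANCE_DOWN", "RIBO_OCP_DOWN")] <- -effect
  list(rna = rna, ribo = ribo)
}

#' Generate paired RNA/Ribo negative-binomial counts with known truth
#'
#' Counts are drawn as NB(mean = sf_s * q_g * 2^lfc, dispersion alpha_g) with
#' variance mu + alpha mu^2 (the DESeq2 parameterization). The noiseless mean
#' matrix is returned alongside the counts so class semantics can be checked
#' exactly.
#'
#' @param design a [countDesign()] object.
#' @param seed optional override of \code{design$seed}.
#' @return A \code{SummarizedExperiment} with assays \code{counts} (integer)
#'   and \code{mu} (noiseless means), \code{colData} columns sample, assay,
#'   genotype, condition, replicate, sizeFactor, and \code{rowData} columns
#'   class, rna_lfc, ribo_lfc, baseline_mean, dispersion.
#' @examples
#' se <- generateCounts(countDesign(nGenes = 50L, classes = c(TE_UP = 5L)))
#' dim(SummarizedExperiment::assay(se, "counts"))
#' @export
generateCounts <- function(design, seed = design$seed) {
  stopIfNot(inherits(design, "CountDesign"), "design must come from countDesign()")
  m <- design$nGenes
  smp <- design$samples
  withSeed(seed, {
    q <- design$baselineMean
    if (is.null(q)) q <- exp(rnorm(m, log(100), 1))
    if (length(q) == 1L) q <- rep(q, m)
    alpha <- design$dispersion
    if (is.null(alpha)) alpha <- 0.01 + 2 / q
    if (length(alpha) == 1L) alpha <- rep(alpha, m)
    lfc <- classLfc(design$labels, design$effectLfc)
    stressed <- smp$condition == design$conditions[2]
    mu <- matrix(0, m, nrow(smp))
    for (s in seq_len(nrow(smp))) {
      l <- if (smp$assay[s] == "RIBO") lfc$ribo else lfc$rna
      mu[, s] <- design$sizeFactors[s] * q * 2^(l * stressed[s])
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha), m)
    gid <- sprintf("gene%05d", seq_len(m))
    dimnames(counts) <- dimnames(mu) <- list(gid, smp$sample)
    cd <- S4Vectors::DataFrame(smp[, c("sample", "assay", "genotype",
                                       "condition", "replicate")],
                               sizeFactor = design$sizeFactors,
                               row.names = smp$sample)
    rd <- S4Vectors::DataFrame(class = design$labels, rna_lfc = lfc$rna,
                               ribo_lfc = lfc$ribo, baseline_mean = q,
                               dispersion = alpha, row.names = gid)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts, mu = mu), colData = cd, rowData = rd)
  })
}

# ---- melt curves -------------------------------------------------------

#' Generate a synthetic thermal melt curve
#'
#' A logistic unfolding transition sampled on the instrument grid
#' (25 to 95 degrees C in 0.2 degree increments) plus Gaussian noise. The true
#' melting temperature is attached as attribute \code{trueTm}.
#'
#' @param trueTm melting temperature in degrees C, within [25, 95].
#' @param steepness logistic rate per degree C (default 2, a 2-3 degree
#'   transition width typical of small-domain unfolding by dye fluorescence).
#' @param noiseSd Gaussian noise sd in fluorescence units.
#' @param seed integer seed.
#' @param amplitude,baseline fluorescence scale of the transition.
#' @return data.frame with columns \code{temperature} and
#'   \code{fluorescence}; attribute \code{trueTm}.
#' @export
generateMeltCurve <- function(trueTm, steepness = 2, noiseSd = 0, seed = 1L,
                              amplitude = 1000, baseline = 100) {
  stopIfNot(trueTm >= 25 && trueTm <= 95, "trueTm must lie in [25, 95] C")
  stopIfNot(steepness > 0, "steepness must be positive")
  temperature <- seq(25, 95, by = 0.2)
  fl <- baseline + amplitude / (1 + exp(-steepness * (temperature - trueTm)))
  if (noiseSd > 0)
    fl <- fl + withSeed(seed, rnorm(length(fl), 0, noiseSd))
  structure(data.frame(temperature = temperature, fluorescence = fl),
            trueTm = trueTm)
}
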