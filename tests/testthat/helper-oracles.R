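# Independent brute-force oracles and fixture builders. These deliberately
# re-derive each quantity from its definition with straightforward loops so
# they share no code path with the package implementations they check.

# Otsu: try every histogram cut, computing class weights/means directly.
oracleOtsu <- function(counts, mids) {
  counts <- as.numeric(counts)
  n <- length(counts)
  best <- -Inf
  bestT <- NA_integer_
  for (t in 1:(n - 1)) {
    w1 <- sum(counts[1:t])
    w2 <- sum(counts[(t + 1):n])
    if (w1 == 0 || w2 == 0) next
    mu1 <- sum(counts[1:t] * mids[1:t]) / w1
    mu2 <- sum(counts[(t + 1):n] * mids[(t + 1):n]) / w2
    bcv <- w1 * w2 * (mu1 - mu2)^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  (mids[bestT] + mids[bestT + 1]) / 2
}

# GSEA enrichment score: walk the ranked list accumulating the running sum.
oracleES <- function(scores, hitIdx, weightP) {
  N <- length(scores)
  K <- length(hitIdx)
  wsum <- sum(abs(scores[hitIdx])^weightP)
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (i %in% hitIdx) {
      w <- if (wsum == 0) 1 / K else abs(scores[i])^weightP / wsum
      rs <- rs + w
    } else {
      rs <- rs - 1 / (N - K)
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# Benjamini-Hochberg from the step-up definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail from the probability mass sum.
oracleHyperUpper <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# Spearman rho with average ranks, written out from the definition.
oracleSpearman <- function(x, y) {
  avgRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Pixel-by-pixel ellipse rasterizer (double loop, no vectorized sharing).
oracleEllipsePixels <- function(row, col, a, b, theta, dim) {
  px <- matrix(0L, 0, 2)
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
    u <- (r - row) * cos(theta) + (c - col) * sin(theta)
    v <- -(r - row) * sin(theta) + (c - col) * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) px <- rbind(px, c(r, c))
  }
  px
}

# Build a labeled mask from a list of pixel matrices.
mkLabelMask <- function(pixelSets, dim, kind = "foci") {
  m <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(pixelSets)) m[pixelSets[[i]]] <- i
  sgribo:::labelMask(m, kind)
}

# Small paired RNA/Ribo design shortcut.
quickDesign <- function(nGenes, classes = c(TE_UP = 0L), effectLfc = 2,
                        baselineMean = 200, dispersion = 0.05, seed = 1L,
                        nReplicates = 3L, sizeFactors = NULL) {
  countDesign(nGenes = nGenes, classes = classes, effectLfc = effectLfc,
              baselineMean = baselineMean, dispersion = dispersion,
              nReplicates = nReplicates, sizeFactors = sizeFactors,
              seed = seed)
}

assaySplit <- function(se) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  list(counts = cnt, colData = cd,
       rna = cnt[, cd$assay == "RNA", drop = FALSE],
       ribo = cnt[, cd$assay == "RIBO", drop = FALSE],
       rnaCond = cd$condition[cd$assay == "RNA"],
       riboCond = cd$condition[cd$assay == "RIBO"],
       truth = SummarizedExperiment::rowData(se))
}

# Map truth cells to measured cell labels through the cell mask.
matchCells <- function(field, cellsMask) {
  tc <- truthCells(field)
  lab <- labels2d(cellsMask)
  lab[cbind(pmin(nrow(lab), pmax(1, round(tc$row))),
            pmin(ncol(lab), pmax(1, round(tc$col))))]
}
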