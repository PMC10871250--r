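# Preranked gene-set enrichment with a gene-permutation null, and
# hypergeometric over-representation against a TPM-defined background.

#' Transcripts per million
#'
#' TPM_gs = 1e6 * (count_gs / length_g) / sum_g (count_gs / length_g); each
#' column sums to one million.
#'
#' @param counts genes x samples count matrix.
#' @param geneLengths per-gene lengths in bases (positive, aligned to rows).
#' @return numeric matrix of TPMs with the same dimnames as \code{counts}.
#' @export
computeTPM <- function(counts, geneLengths) {
  stopIfNot(length(geneLengths) == nrow(counts),
            "need one length per gene")
  stopIfNot(all(geneLengths > 0), "gene lengths must be positive")
  rate <- counts / geneLengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Expressed-gene background from TPMs
#'
#' Genes whose TPM strictly exceeds \code{threshold} in at least one sample.
#'
#' @param tpm matrix from [computeTPM()] with gene rownames.
#' @param threshold strict TPM cutoff (default 1).
#' @return character vector of background gene ids.
#' @export
buildBackground <- function(tpm, threshold = 1) {
  stopIfNot(!is.null(rownames(tpm)), "tpm needs gene rownames")
  rownames(tpm)[apply(tpm, 1, max) > threshold]
}

#' Build a ranked gene list
#'
#' Stable sort by decreasing score with ties broken by gene id (ascending),
#' so the enrichment statistic is reproducible under reordering of the input.
#'
#' @param scores named numeric vector (names = unique gene ids).
#' @return Named numeric vector sorted for [prerankedGSEA()].
#' @export
rankGenes <- function(scores) {
  stopIfNot(!is.null(names(scores)) && !anyDuplicated(names(scores)),
            "scores must be named with unique gene ids")
  stopIfNot(all(is.finite(scores)), "scores must be finite")
  scores[order(-scores, names(scores), method = "radix")]
}

# Weighted Kolmogorov-Smirnov running sum. hitIdx indexes the ranked list;
# returns the signed extremum and the peak position.
esRunningSum <- function(scores, hitIdx, weightP) {
  N <- length(scores)
  K <- length(hitIdx)
  w <- abs(scores[hitIdx])^weightP
  if (sum(w) == 0) w <- rep(1, K)
  step <- rep(-1 / (N - K), N)
  step[hitIdx] <- w / sum(w)
  rs <- cumsum(step)
  peak <- which.max(abs(rs))
  list(es = rs[peak], peak = peak, running = rs)
}

#' Preranked gene-set enrichment analysis
#'
#' The enrichment score is the signed extremum of the weighted
#' Kolmogorov-Smirnov running sum over the ranked list: hits increment by
#' |score|^weightP (normalized to sum 1 within the set), misses decrement by
#' 1/(N - K). The null is built per set from \code{nPerm} random same-size
#' gene sets; the permutation p-value is sign-conditional,
#' p = (1 + #same-sign null ES at least as extreme) / (1 + #same-sign null),
#' so it is at least 1/(nPerm + 1) and approximately uniform under random
#' scores. NES divides ES by the mean |null ES| of the matching sign. The
#' leading edge collects the hit genes up to (positive ES) or after
#' (negative ES) the running-sum extremum.
#'
#' @param ranked named numeric vector from [rankGenes()] (or any named,
#'   decreasingly sorted scores).
#' @param geneSets named list of character vectors.
#' @param weightP hit-weight exponent (default 1; 0 gives the classic KS
#'   statistic).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation null.
#' @return data.frame with set, size, ES, NES, pval, padj, leadingEdge
#'   (comma-joined). Sets disjoint from the universe get NA statistics.
#' @export
prerankedGSEA <- function(ranked, geneSets, weightP = 1, nPerm = 10000L,
                          seed = 1L) {
  stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  stopIfNot(!is.null(names(ranked)), "ranked must be a named vector")
  genes <- names(ranked)
  N <- length(genes)
  rows <- withSeed(seed, lapply(names(geneSets), function(nm) {
    hitIdx <- which(genes %in% geneSets[[nm]])
    K <- length(hitIdx)
    if (K == 0L || K == N)
      return(data.frame(set = nm, size = K, ES = NA_real_, NES = NA_real_,
                        pval = NA_real_, padj = NA_real_,
                        leadingEdge = "", untestable = TRUE))
    obs <- esRunningSum(ranked, hitIdx, weightP)
    nullEs <- vapply(seq_len(nPerm), function(i)
      esRunningSum(ranked, sort.int(sample.int(N, K)), weightP)$es,
      numeric(1))
    same <- if (obs$es >= 0) nullEs >= 0 else nullEs < 0
    pval <- (1 + sum(same & abs(nullEs) >= abs(obs$es))) / (1 + sum(same))
    denom <- mean(abs(nullEs[same]))
    nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
    le <- if (obs$es >= 0) hitIdx[hitIdx <= obs$peak]
          else hitIdx[hitIdx >= obs$peak]
    data.frame(set = nm, size = K, ES = obs$es, NES = nes, pval = pval,
               padj = NA_real_, leadingEdge = paste(genes[le], collapse = ","),
               untestable = FALSE)
  }))
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$pval)
  rownames(out) <- NULL
  out
}

#' GO-style over-representation analysis
#'
#' Hypergeometric upper-tail test for each term: the probability of at least
#' k study hits when drawing n study genes from an N-gene background
#' containing K term members. Terms are evaluated after intersecting with the
#' background; BH-adjusted p-values with significance at padj < 0.05.
#'
#' @param study character vector of study gene ids (must be contained in
#'   \code{background}).
#' @param background character vector of background gene ids.
#' @param annotation named list mapping term -> member gene ids.
#' @param padjCutoff significance cutoff on padj (default 0.05).
#' @return data.frame with term, k, K, n, N, pval, padj, significant.
#' @importFrom stats phyper
#' @export
goOverrepresentation <- function(study, background, annotation,
                                 padjCutoff = 0.05) {
  study <- unique(study)
  background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing))
    stop("study genes absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  N <- length(background)
  n <- length(study)
  rows <- lapply(names(annotation), function(tm) {
    members <- intersect(unique(annotation[[tm]]), background)
    K <- length(members)
    k <- length(intersect(members, study))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, pval = p,
               padj = NA_real_)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$pval)
  out$significant <- !is.na(out$padj) & out$padj < padjCutoff
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in attribute
#'   \code{"description"}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param geneSets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional per-set description strings.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(geneSets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(geneSets))
  lines <- vapply(seq_along(geneSets), function(i)
    paste(c(names(geneSets)[i], descriptions[i], geneSets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
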