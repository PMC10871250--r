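# Internal helpers shared across modules.

# Evaluate expr under a local RNG stream: the caller's .Random.seed is
# restored afterwards, so generators never leak global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed for a named pipeline stage; stays below 2^31.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + h * 10007) %% 2147483629) + 1L
}

# Pixel-center rasterization of a filled ellipse; returns an n x 2 matrix of
# (row, col) indices inside the ellipse. theta in radians, a >= b semi-axes.
rasterEllipse <- function(row, col, a, b, theta, dim) {
  r0 <- max(1L, floor(row - a)); r1 <- min(dim[1], ceiling(row + a))
  c0 <- max(1L, floor(col - a)); c1 <- min(dim[2], ceiling(col + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(), col = integer()))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

# Separable Gaussian blur with replicate padding; sigma in pixels.
gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  convRows <- function(m) {
    pad <- m[c(rep(1, half), seq_len(nrow(m)), rep(nrow(m), half)), ,
             drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(convRows(t(convRows(mat))))
}

# Per-label area, centroid and ellipse-equivalent eccentricity from second
# central moments of the pixel coordinates (the foci-filter statistic).
regionMoments <- function(labels, weights = NULL) {
  K <- max(0L, as.integer(labels))
  if (K == 0L)
    return(data.frame(label = integer(), area = numeric(), row = numeric(),
                      col = numeric(), eccentricity = numeric()))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  w <- if (is.null(weights)) rep(1, length(lab)) else weights[labels > 0]
  sw <- tapply(w, lab, sum)
  area <- tapply(rep(1, length(lab)), lab, sum)
  mr <- tapply(w * idx[, 1], lab, sum) / sw
  mc <- tapply(w * idx[, 2], lab, sum) / sw
  res <- data.frame(label = as.integer(names(area)), area = as.numeric(area),
                    row = as.numeric(mr), col = as.numeric(mc),
                    eccentricity = NA_real_)
  # unweighted second central moments for shape (+1/12 pixel-area correction)
  ur <- tapply(idx[, 1], lab, mean); uc <- tapply(idx[, 2], lab, mean)
  for (i in seq_len(nrow(res))) {
    sel <- lab == res$label[i]
    dr <- idx[sel, 1] - ur[[i]]; dc <- idx[sel, 2] - uc[[i]]
    mu20 <- mean(dr^2) + 1 / 12
    mu02 <- mean(dc^2) + 1 / 12
    mu11 <- mean(dr * dc)
    tr <- mu20 + mu02
    det <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
    l1 <- (tr + det) / 2
    l2 <- (tr - det) / 2
    res$eccentricity[i] <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  }
  rownames(res) <- NULL
  res
}

# Relabel a nonnegative integer matrix so positive labels are contiguous 1..K.
relabelContiguous <- function(labels) {
  u <- sort(unique(as.integer(labels[labels > 0])))
  if (!length(u)) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  out[labels > 0] <- map[as.integer(labels[labels > 0])]
  storage.mode(out) <- "integer"
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
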