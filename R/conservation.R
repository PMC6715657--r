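## Conservation scoring of summit-centered windows, fixed-bin score
## distributions, and a Mann-Whitney U test with midranks, tie correction,
## continuity correction, and an exact-enumeration mode for small samples.

#' Average conservation around peak summits
#'
#' For each peak, the mean stored score over the window
#' `[summit - flank, summit + flank]` (2 * flank + 1 bases, 201 for the
#' default +/- 100), clipped at chromosome bounds. Positions with no stored
#' score contribute 0 while still counting in the denominator (unaligned
#' bases are treated as unconserved).
#'
#' @param track A [ConservationTrack-class].
#' @param peaks `GRanges` with a `summit` column.
#' @param flank Window half-width in bases.
#' @param chromSizes Optional named chromosome lengths for upper clipping;
#'   without them the window is clipped at position 1 only.
#' @return Numeric vector of per-peak means in `[0, 1]`.
#' @export
peakConservation <- function(track, peaks, flank = 100L, chromSizes = NULL) {
  stopifnot(is(track, "ConservationTrack"), flank >= 0)
  vapply(seq_along(peaks), function(i) {
    chrom <- as.character(seqnames(peaks))[i]
    s <- max(1L, peaks$summit[i] - flank)
    e <- peaks$summit[i] + flank
    if (!is.null(chromSizes) && chrom %in% names(chromSizes))
      e <- min(e, chromSizes[[chrom]])
    v <- trackScore(track, chrom, s:e)
    sum(v, na.rm = TRUE) / (e - s + 1L)
  }, numeric(1))
}

#' Distribution of per-peak conservation means over fixed bins
#'
#' Bins `[0, 0.2), [0.2, 0.4), ..., [0.8, 1.0]` by default (half-open,
#' left-closed, last bin closed, so a mean of exactly 0.8 falls in the top
#' bin). Set `boundary = "right"` for right-closed bins `(0, 0.2], ...`.
#'
#' @param means Per-peak means, all in `[0, 1]`.
#' @param binWidth Bin width (default 0.2).
#' @param boundary `"left"` (default) or `"right"` closure convention.
#' @return `data.frame` with `bin_start`, `bin_end`, `count`, `fraction`;
#'   fractions sum to 1.
#' @export
scoreDistribution <- function(means, binWidth = 0.2, boundary = c("left", "right")) {
  boundary <- match.arg(boundary)
  if (!length(means)) stop("no conservation means")
  if (any(means < 0 | means > 1)) stop("conservation mean outside [0,1]")
  nbins <- ceiling(1 / binWidth - 1e-9)
  ## tolerance guards against binary representation of bin edges
  ## (e.g. 0.6 / 0.2 slightly above or below 3)
  idx <- if (boundary == "left") {
    pmin(floor(means / binWidth + 1e-9), nbins - 1L)
  } else {
    pmax(ceiling(means / binWidth - 1e-9) - 1L, 0L)
  }
  counts <- tabulate(idx + 1L, nbins)
  data.frame(bin_start = (seq_len(nbins) - 1L) * binWidth,
             bin_end = pmin(seq_len(nbins) * binWidth, 1),
             count = counts,
             fraction = counts / length(means))
}

#' Summary of per-peak conservation
#'
#' @inheritParams scoreDistribution
#' @return List with `bins` (see [scoreDistribution()]) and `grand_mean`
#'   (the unweighted mean of the per-peak means).
#' @export
conservationSummary <- function(means, binWidth = 0.2,
                                boundary = c("left", "right")) {
  list(bins = scoreDistribution(means, binWidth, match.arg(boundary)),
       grand_mean = mean(means))
}

#' Mann-Whitney U test
#'
#' Computes U from midranks, with a tie-corrected, continuity-corrected
#' normal approximation for the p value. For small untied samples
#' (`min(n1, n2) <= 8`) an exact enumeration over all assignments is
#' available and used automatically.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (U measures how
#'   often `a` exceeds `b`).
#' @param method `"auto"` (exact when small and untied), `"normal"`, or
#'   `"exact"` (errors on ties).
#' @return List with `U`, `z` (normal-approximation z value), `p`, and
#'   `method` used for `p`.
#' @export
mannWhitneyU <- function(a, b, alternative = c("two.sided", "less", "greater"),
                         method = c("auto", "normal", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1L, n2 >= 1L)
  comb <- c(a, b)
  r <- rank(comb)  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(comb)
  tiecorr <- sum(ties^3 - ties)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tiecorr / (N * (N - 1)))
  if (sigma2 <= 0) {
    ## both samples constant and equal: no evidence of a shift
    return(list(U = U, z = 0, p = 1, method = "degenerate"))
  }
  cc <- 0.5
  d <- U - mu
  z <- if (d == 0) 0 else (d - sign(d) * cc) / sqrt(sigma2)
  p_norm <- switch(alternative,
                   two.sided = min(1, 2 * pnorm(-abs(z))),
                   greater = pnorm((U - mu - cc) / sqrt(sigma2), lower.tail = FALSE),
                   less = pnorm((U - mu + cc) / sqrt(sigma2)))
  hasTies <- tiecorr > 0
  useExact <- switch(method,
                     auto = !hasTies && min(n1, n2) <= 8L && N <= 20L,
                     exact = TRUE, normal = FALSE)
  if (useExact) {
    if (hasTies) stop("exact Mann-Whitney enumeration requires untied samples")
    p <- .exactMannWhitneyP(U, n1, n2, alternative)
    return(list(U = U, z = z, p = p, method = "exact"))
  }
  list(U = U, z = z, p = p_norm, method = "normal")
}

## exact null distribution of U by enumeration of all rank assignments
.exactMannWhitneyP <- function(U, n1, n2, alternative) {
  N <- n1 + n2
  cmb <- combn(N, n1)
  Us <- colSums(matrix(seq_len(N)[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  switch(alternative,
         two.sided = {
           lo <- mean(Us <= U); hi <- mean(Us >= U)
           min(1, 2 * min(lo, hi))
         },
         greater = mean(Us >= U),
         less = mean(Us <= U))
}
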