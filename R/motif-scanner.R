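## PWM construction from aligned sites, palindromic dimer composition,
## both-strand scanning at a relative-score threshold, per-peak motif
## frequencies, IUPAC pattern counting and MEME-format motif I/O.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")

## sequence -> integer codes 1..4 (A,C,G,T), NA for anything else
.seqToIdx <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
  match(chars, c("A", "C", "G", "T"))
}

## reverse-complement of a weight matrix: reverse columns, swap A<->T, C<->G
.rcWeights <- function(w) {
  w <- w[c("T", "G", "C", "A"), rev(seq_len(ncol(w))), drop = FALSE]
  rownames(w) <- c("A", "C", "G", "T")
  w
}

#' Build a PWM from aligned binding sites
#'
#' The weight of base `b` at position `i` is the count of `b` at position `i`
#' across the sites (a frequency matrix). Sites must be equal-length ACGT
#' strings; ambiguity codes are rejected.
#'
#' @param sites Character vector (or `DNAStringSet`) of aligned sites.
#' @param name Optional motif name.
#' @return A [MotifMatrix-class].
#' @export
buildPWM <- function(sites, name = "motif") {
  sites <- toupper(as.character(sites))
  if (!length(sites)) stop("need at least one site")
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("aligned sites must have equal lengths")
  mat <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in sites) {
    idx <- .seqToIdx(s)
    if (anyNA(idx)) stop("non-ACGT character in site: ", s)
    for (j in seq_len(L)) mat[idx[j], j] <- mat[idx[j], j] + 1
  }
  m <- new("MotifMatrix", weights = mat, name = name)
  validObject(m)
  m
}

#' Relative profile score of a window
#'
#' `100 * raw / max_score`, where `raw` is the sum of the window's
#' per-position weights and `max_score` the sum of per-position maxima; the
#' consensus scores 100.
#'
#' @param pwm A [MotifMatrix-class].
#' @param window Sequence of length `pwmLength(pwm)` (ACGT, case-folded).
#' @return Percent in `[0, 100]` (`NA` if the window contains non-ACGT).
#' @export
relativeScore <- function(pwm, window) {
  w <- pwmWeights(pwm)
  idx <- .seqToIdx(window)
  if (length(idx) != ncol(w))
    stop("window length ", length(idx), " != motif length ", ncol(w))
  raw <- sum(w[cbind(idx, seq_len(ncol(w)))])
  100 * raw / pwmMaxScore(pwm)
}

## sliding relative scores of every window of `idx` against weights `w`;
## vectorized over offsets, NA where a window touches a non-ACGT base
.slideScores <- function(w, idx, maxScore) {
  L <- ncol(w)
  m <- length(idx) - L + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (j in seq_len(L)) {
    wj <- w[, j]
    sc <- sc + wj[idx[j:(j + m - 1L)]]
  }
  100 * sc / maxScore
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports every offset whose plus-strand window, or whose
#' reverse-complemented window (minus strand), has a relative score strictly
#' greater than the threshold. Offsets are 1-based plus-strand coordinates of
#' the window start; windows containing non-ACGT bases are skipped.
#' Lower-case (soft-masked) bases are case-folded.
#'
#' @param pwm A [MotifMatrix-class].
#' @param seq Sequence (character or `DNAString`).
#' @param threshold Relative-score threshold in percent (strict `>`).
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return `data.frame` with columns `offset`, `strand`, `score`, ordered by
#'   offset then strand.
#' @export
scanSequence <- function(pwm, seq, threshold = 75, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  w <- pwmWeights(pwm)
  idx <- .seqToIdx(seq)
  ms <- pwmMaxScore(pwm)
  out <- list()
  if (strands %in% c("both", "+")) {
    sc <- .slideScores(w, idx, ms)
    hit <- which(!is.na(sc) & sc > threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(offset = hit, strand = "+",
                                            score = sc[hit])
  }
  if (strands %in% c("both", "-")) {
    ## scoring the reverse-complement of a window with the PWM equals scoring
    ## the window itself with the reverse-complemented PWM
    sc <- .slideScores(.rcWeights(w), idx, ms)
    hit <- which(!is.na(sc) & sc > threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(offset = hit, strand = "-",
                                            score = sc[hit])
  }
  if (!length(out))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Compose a palindromic dimer motif
#'
#' Builds a composite PWM of length `2 * L + spacer` from a monomer
#' half-site: the first `L` columns are the monomer, the middle `spacer`
#' columns carry uniform weights (each base gets max monomer column total /
#' 4, making the spacer score-neutral), and the last `L` columns are the
#' reverse complement of the monomer. The composite consensus (half-site +
#' any spacer + inverted half-site) always scores 100.
#'
#' @param monomer The half-site [MotifMatrix-class].
#' @param spacer Spacer width in bases (default 4).
#' @param name Optional motif name.
#' @return A [PalindromeMotif-class].
#' @export
buildPalindromePWM <- function(monomer, spacer = 4L,
                               name = paste0(monomer@name, "_palindrome")) {
  stopifnot(is(monomer, "MotifMatrix"))
  if (spacer < 0) stop("spacer must be >= 0")
  spacer <- as.integer(spacer)
  w <- pwmWeights(monomer)
  u <- max(colSums(w)) / 4
  sp <- matrix(u, 4L, spacer, dimnames = list(rownames(w), NULL))
  comp <- cbind(w, sp, .rcWeights(w))
  m <- new("PalindromeMotif", weights = comp, name = name,
           monomer = monomer, spacer = spacer)
  validObject(m)
  m
}

#' Fraction of peaks containing a motif
#'
#' Scans each peak's sequence (the full peak interval by default, or a
#' summit-centered +/- 50 bp window) on both strands and reports the percent
#' of peaks with at least one hit above the threshold.
#'
#' @param peaks `GRanges` with `summit` column.
#' @param genome `DNAStringSet` keyed by chromosome.
#' @param pwm A [MotifMatrix-class].
#' @param threshold Relative-score threshold (strict `>`).
#' @param window `"peak"` (full interval) or `"summit50"`.
#' @return Percent of peaks with a hit, in `[0, 100]`.
#' @export
motifPeakFrequency <- function(peaks, genome, pwm, threshold = 75,
                               window = c("peak", "summit50")) {
  window <- match.arg(window)
  if (!length(peaks)) stop("motif frequency needs at least one peak")
  hitFlags <- peakMotifHits(peaks, genome, pwm, threshold, window)
  100 * sum(hitFlags) / length(peaks)
}

#' Per-peak motif hit indicator
#'
#' @inheritParams motifPeakFrequency
#' @return Logical vector: does each peak contain at least one hit?
#' @export
peakMotifHits <- function(peaks, genome, pwm, threshold = 75,
                          window = c("peak", "summit50")) {
  window <- match.arg(window)
  vapply(seq_along(peaks), function(i) {
    chrom <- as.character(seqnames(peaks))[i]
    if (!chrom %in% names(genome)) stop("peak on unknown chromosome: ", chrom)
    clen <- length(genome[[chrom]])
    if (window == "peak") {
      s <- start(peaks)[i]; e <- end(peaks)[i]
    } else {
      s <- max(1L, peaks$summit[i] - 50L); e <- min(clen, peaks$summit[i] + 50L)
    }
    if (e > clen || s < 1L) stop("peak ", peaks$name[i], " beyond chromosome end")
    seq <- as.character(subseq(genome[[chrom]], s, e))
    nrow(scanSequence(pwm, seq, threshold = threshold)) > 0L
  }, logical(1))
}

#' Count IUPAC pattern occurrences on both strands
#'
#' Counts plus-strand and minus-strand occurrences of an IUPAC pattern
#' (overlapping allowed); a palindromic pattern is counted once per strand.
#' Ambiguity codes in the subject sequence are treated literally.
#'
#' @param seq Subject sequence (character or `DNAString`).
#' @param pattern IUPAC pattern.
#' @return Total count over both strands.
#' @export
iupacMatchCount <- function(seq, pattern) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1L]], names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code in pattern: ", paste(bad, collapse = ", "))
  subject <- DNAString(toupper(as.character(seq)))
  plus <- Biostrings::countPattern(pattern, subject, fixed = "subject")
  minus <- Biostrings::countPattern(pattern, reverseComplement(subject),
                                    fixed = "subject")
  plus + minus
}

#' Write / read a motif in MEME minimal format
#'
#' The weight matrix is stored as a letter-probability matrix with `nsites`
#' equal to the maximum column total; reading multiplies back. Count
#' matrices with uniform column totals (including palindromic composites)
#' round-trip exactly.
#'
#' @param pwm A [MotifMatrix-class].
#' @param path File path.
#' @export
writeMemeMotif <- function(pwm, path) {
  w <- pwmWeights(pwm)
  n <- max(colSums(w))
  probs <- w / n
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "",
             paste("MOTIF", pwm@name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
                     ncol(w), format(n, digits = 15)),
             apply(probs, 2L, function(p)
               paste(format(p, digits = 15, scientific = FALSE), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMemeMotif
#' @return `readMemeMotif()` returns a [MotifMatrix-class].
#' @export
readMemeMotif <- function(path) {
  lines <- readLines(path)
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) stop("no MOTIF record in ", path)
  name <- sub("^MOTIF\\s+", "", lines[mi[1L]])
  hi <- grep("^letter-probability matrix:", lines)
  if (!length(hi)) stop("no letter-probability matrix in ", path)
  hdr <- lines[hi[1L]]
  w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
  n <- as.numeric(sub(".*\\bnsites=\\s*([0-9.eE+-]+).*", "\\1", hdr))
  rows <- lines[(hi[1L] + 1L):(hi[1L] + w)]
  probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
  mat <- t(probs) * n
  rownames(mat) <- c("A", "C", "G", "T")
  m <- new("MotifMatrix", weights = mat, name = name)
  validObject(m)
  m
}
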