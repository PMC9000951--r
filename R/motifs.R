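#' Read a position weight matrix
#'
#' Tab-delimited, 4 rows (A, C, G, T) by motif-length columns, with or
#' without a first row-name column; columns must sum to one.
#'
#' @param path PWM file path.
#' @return Numeric 4 x L matrix with rownames `A,C,G,T`.
#' @export
read_pwm <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(raw[[1]])) {
    rn <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  } else rn <- c("A", "C", "G", "T")
  m <- as.matrix(raw)
  rownames(m) <- rn
  storage.mode(m) <- "double"
  validate_pwm(m)
  m
}

validate_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  cs <- colSums(pwm)
  if (any(abs(cs - 1) > 1e-6))
    stop("PWM columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  invisible(pwm)
}

pwm_correlation_distance <- function(pwm1, pwm2) {
  # ungapped sliding alignment of the two matrices; distance = 1 - max r
  # over offsets, computed on the flattened overlapping columns
  l1 <- ncol(pwm1); l2 <- ncol(pwm2)
  best <- -Inf
  for (off in (-(l2 - 1)):(l1 - 1)) {
    a0 <- max(1, 1 + off); a1 <- min(l1, l2 + off)
    if (a1 - a0 + 1 < 3) next  # require >= 3 overlapping columns
    b0 <- a0 - off; b1 <- a1 - off
    r <- suppressWarnings(cor(as.vector(pwm1[, a0:a1]),
                              as.vector(pwm2[, b0:b1])))
    if (!is.na(r) && r > best) best <- r
  }
  if (!is.finite(best)) stop("PWMs have no alignable overlap")
  1 - best
}

#' Choose the best-matching PWM pair for two paralogs
#'
#' When several in vitro PWMs exist per TF, the cross pair with the
#' smallest correlation distance (highest correlation between the
#' length-aligned, flattened matrices) represents the pair.
#'
#' @param pwms_p1,pwms_p2 lists of PWMs (see [read_pwm()]).
#' @return List with `pwm1`, `pwm2`, their list indices `i`, `j`, and the
#'   `distance`.
#' @export
choose_pwm_pair <- function(pwms_p1, pwms_p2) {
  stopifnot(length(pwms_p1) >= 1, length(pwms_p2) >= 1)
  best <- NULL
  for (i in seq_along(pwms_p1)) for (j in seq_along(pwms_p2)) {
    d <- pwm_correlation_distance(pwms_p1[[i]], pwms_p2[[j]])
    if (is.null(best) || d < best$distance)
      best <- list(pwm1 = pwms_p1[[i]], pwm2 = pwms_p2[[j]],
                   i = i, j = j, distance = d)
  }
  best
}

#' Simplify a PWM to its five most informative positions
#'
#' Information content per column is `2 + sum(p * log2(p))` (0 log 0 = 0).
#' The five highest-IC columns keep their most probable base; all other
#' columns become `N`, yielding a pattern for exact-match scanning.
#'
#' @param pwm a 4 x L PWM (L >= 5), columns summing to one.
#' @return Object of class `simplified_motif`: `pattern` (string over
#'   `A,C,G,T,N`), `informative_positions` (5 column indices) and `ic`
#'   (per-column information content).
#' @export
simplify_pwm <- function(pwm) {
  validate_pwm(pwm)
  L <- ncol(pwm)
  if (L < 5) stop("PWM must have at least 5 columns")
  ic <- apply(pwm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  keep <- sort(order(-ic, seq_len(L))[1:5])
  bases <- rownames(pwm)[apply(pwm, 2, which.max)]
  pattern <- rep("N", L)
  pattern[keep] <- bases[keep]
  structure(list(pattern = paste(pattern, collapse = ""),
                 informative_positions = keep, ic = ic),
            class = "simplified_motif")
}

#' @export
print.simplified_motif <- function(x, ...) {
  cat("simplified_motif:", x$pattern, "\n")
  invisible(x)
}

nonoverlapping_starts <- function(starts, width) {
  # greedy left-to-right selection (regular-expression semantics)
  keep <- integer(0)
  last_end <- -1L
  for (s in sort(starts)) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + width - 1L
    }
  }
  keep
}

#' Scan promoters for exact matches to a simplified motif
#'
#' Matches the pattern (with `N` as a single-base wildcard) on both
#' strands, keeping left-to-right non-overlapping matches per strand.
#' Plus/minus matches at the same position (palindromes) are
#' deduplicated to a single occurrence, and only matches fully inside a
#' promoter interval are retained.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param motif a [simplify_pwm()] result, or a pattern string.
#' @param promoters a [define_promoters()] result.
#' @param overlapping keep overlapping matches instead of the greedy
#'   non-overlapping set.
#' @return Data frame of class `motif_occurrences` with columns `chrom`,
#'   `position` (0-based match start), `strand`, `gene_id`; the motif
#'   length is carried in `attr(, "motif_length")`.
#' @export
scan_motif <- function(genome, motif, promoters, overlapping = FALSE) {
  pattern <- if (inherits(motif, "simplified_motif")) motif$pattern
             else as.character(motif)
  if (inherits(genome, "DNAStringSet")) {
    seqs <- genome
  } else {
    seqs <- Biostrings::DNAStringSet(genome)
  }
  L <- nchar(pattern)
  pat <- Biostrings::DNAString(pattern)
  rcpat <- Biostrings::reverseComplement(pat)

  res <- list()
  for (ch in names(seqs)) {
    subj <- seqs[[ch]]
    plus <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                       fixed = FALSE))
    minus <- Biostrings::start(Biostrings::matchPattern(rcpat, subj,
                                                        fixed = FALSE))
    if (!overlapping) {
      plus <- nonoverlapping_starts(plus, L)
      minus <- nonoverlapping_starts(minus, L)
    }
    df <- rbind(
      if (length(plus)) data.frame(chrom = ch, position = plus - 1L,
                                   strand = "+", stringsAsFactors = FALSE),
      if (length(minus)) data.frame(chrom = ch, position = minus - 1L,
                                    strand = "-", stringsAsFactors = FALSE))
    if (is.null(df) || !nrow(df)) next
    # palindromic double-strand matches collapse to one occurrence
    df <- df[order(df$position, df$strand), , drop = FALSE]
    df <- df[!duplicated(df$position), , drop = FALSE]
    res[[ch]] <- df
  }
  occ <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), position = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  rownames(occ) <- NULL

  # keep matches fully inside a promoter; annotate the containing gene
  gene <- rep(NA_character_, nrow(occ))
  keep <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    pm <- promoters[promoters$chrom == occ$chrom[i] &
                      promoters$start <= occ$position[i] &
                      promoters$end >= occ$position[i] + L, , drop = FALSE]
    if (nrow(pm)) {
      keep[i] <- TRUE
      gene[i] <- pm$gene_id[1]
    }
  }
  occ <- occ[keep, , drop = FALSE]
  occ$gene_id <- gene[keep]
  rownames(occ) <- NULL
  class(occ) <- c("motif_occurrences", "data.frame")
  attr(occ, "motif_length") <- L
  occ
}

occurrence_centers <- function(occurrences, motif_length = NULL) {
  L <- if (is.null(motif_length)) attr(occurrences, "motif_length")
       else motif_length
  if (is.null(L)) stop("motif length unknown; pass motif_length")
  occurrences$position + (L - 1L) %/% 2L  # 0-based center
}

#' Mean cut-site signal around motif occurrences
#'
#' Extracts the signal in a window around each occurrence midpoint
#' (minus-strand occurrences are orientation-flipped) and averages over
#' occurrences; out-of-bounds occurrences are dropped and counted.
#'
#' @param track a [coverage_track()].
#' @param occurrences a [scan_motif()] result.
#' @param window half-width in bp (default 300; the vector has
#'   `2 * window + 1` entries).
#' @param motif_length override for the motif length attribute.
#' @return Numeric vector of length `2 * window + 1` (positions -window
#'   .. +window relative to the motif center), with `attr(, "n_used")`
#'   and `attr(, "n_dropped")`.
#' @export
meta_signal <- function(track, occurrences, window = 300,
                        motif_length = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (!nrow(occurrences)) stop("no motif occurrences to average over")
  centers <- occurrence_centers(occurrences, motif_length)
  acc <- numeric(2 * window + 1)
  used <- 0L
  for (i in seq_len(nrow(occurrences))) {
    v <- track$values[[occurrences$chrom[i]]]
    c1 <- centers[i] + 1L  # 1-based
    if (c1 - window < 1 || c1 + window > length(v)) next
    w <- v[(c1 - window):(c1 + window)]
    if (occurrences$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  if (used == 0) stop("all occurrences fall too close to contig edges")
  out <- acc / used
  attr(out, "n_used") <- used
  attr(out, "n_dropped") <- nrow(occurrences) - used
  out
}

#' Percent of promoter signal near motif occurrences
#'
#' Fraction (as percent) of the total cut-site signal in the selected
#' promoters that falls within `halfwidth` bp of a motif occurrence
#' center; overlapping windows are counted once.
#'
#' @param track a [coverage_track()].
#' @param promoters a [define_promoters()] result.
#' @param occurrences a [scan_motif()] result.
#' @param genes promoter subset (default: all promoters with an
#'   occurrence).
#' @param halfwidth window half-width in bp (default 50).
#' @param motif_length override for the motif length attribute.
#' @return Percent in `[0, 100]`; `NaN` with a warning when the selected
#'   promoters carry no signal.
#' @export
pct_signal_near_motifs <- function(track, promoters, occurrences,
                                   genes = NULL, halfwidth = 50,
                                   motif_length = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(genes)) genes <- unique(occurrences$gene_id)
  pm <- promoters[promoters$gene_id %in% genes, , drop = FALSE]
  if (!nrow(pm)) stop("empty promoter subset")
  centers <- occurrence_centers(occurrences, motif_length)
  total <- near <- 0
  for (ch in unique(pm$chrom)) {
    v <- track$values[[ch]]
    pmask <- region_mask(length(v), pm$start[pm$chrom == ch],
                         pm$end[pm$chrom == ch])
    sel <- occurrences$chrom == ch
    wmask <- region_mask(length(v), centers[sel] - halfwidth,
                         centers[sel] + halfwidth + 1L)
    total <- total + sum(v[pmask])
    near <- near + sum(v[pmask & wmask])
  }
  if (total == 0) {
    warning("selected promoters carry no signal; percent undefined")
    return(NaN)
  }
  100 * near / total
}

#' Export motif occurrences as BED6
#'
#' @param occurrences a [scan_motif()] result.
#' @param path output path.
#' @param motif_length override for the motif length attribute.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occurrences, path, motif_length = NULL) {
  L <- if (is.null(motif_length)) attr(occurrences, "motif_length")
       else motif_length
  gr <- GenomicRanges::GRanges(
    occurrences$chrom,
    IRanges::IRanges(occurrences$position + 1L, width = L),
    strand = occurrences$strand)
  names(gr) <- occurrences$gene_id
  GenomicRanges::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
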