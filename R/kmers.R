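## Canonical 7-mer indexing and in vivo k-mer binding preferences.
##
## Every genomic position is identified by the 7-mer centered on it
## (-3..+3); a 7-mer and its reverse complement share one canonical
## index, giving 4^7 / 2 = 8192 double-stranded words.

kmer_k <- 7L
kmer_codes_n <- 4L^7L  # 16384

decode_kmer <- function(code, k = kmer_k) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(code))
  for (i in seq_along(code)) {
    c0 <- code[i]
    chars <- character(k)
    for (j in k:1) {
      chars[j] <- bases[c0 %% 4 + 1]
      c0 <- c0 %/% 4
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

revcomp_code <- function(code, k = kmer_k) {
  # reverse the base-4 digits and complement each (b -> 3 - b)
  rc <- integer(length(code))
  c0 <- code
  for (j in seq_len(k)) {
    rc <- rc * 4L + (3L - c0 %% 4L)
    c0 <- c0 %/% 4L
  }
  rc
}

kmer_lookup <- function() {
  if (!is.null(.pb_cache$kmer_lookup)) return(.pb_cache$kmer_lookup)
  code <- 0:(kmer_codes_n - 1L)
  canon <- pmin(code, revcomp_code(code))
  u <- sort(unique(canon))
  lut <- list(index = match(canon, u) - 1L,         # code -> 0-based index
              kmer = decode_kmer(u))                # index -> canonical kmer
  .pb_cache$kmer_lookup <- lut
  lut
}

#' Canonical index of a 7-mer
#'
#' Maps a 7-mer and its reverse complement to the same index in
#' `[0, 8191]` (the index of the lexicographically smaller of the two
#' under the 2-bit encoding A=0, C=1, G=2, T=3).
#'
#' @param seq7 character vector of 7-mers over `{A,C,G,T}`.
#' @return Integer vector of 0-based canonical indices.
#' @export
#' @examples
#' canonical_kmer_index("AAAAAAA") == canonical_kmer_index("TTTTTTT")
canonical_kmer_index <- function(seq7) {
  stopifnot(all(nchar(seq7) == kmer_k))
  lut <- kmer_lookup()
  vapply(seq7, function(s) {
    b <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T")) - 1L
    if (anyNA(b)) stop("ambiguous base in 7-mer: ", s)
    code <- 0L
    for (d in b) code <- code * 4L + d
    lut$index[code + 1L]
  }, integer(1), USE.NAMES = FALSE)
}

#' Canonical 7-mer strings in index order
#'
#' @return Character vector of length 8192; element `i` is the canonical
#'   7-mer with index `i - 1`.
#' @export
canonical_kmers <- function() kmer_lookup()$kmer

genome_base_codes <- function(genome) {
  # named list of integer vectors (0..3, NA for ambiguous)
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    seqs <- genome
  }
  lapply(seqs, function(s) {
    b <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T")) - 1L
    b
  })
}

region_mask <- function(len, starts, ends) {
  # logical mask of 0-based half-open [start, end) intervals
  m <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      s <- max(starts[i], 0) + 1L
      e <- min(ends[i], len)
      if (e >= s) m[s:e] <- TRUE
    }
  }
  m
}

moving_average <- function(x, w) {
  # centered moving average via running sums (exact for count data);
  # positions whose window pokes out of the contig become NA
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  s <- c(0, cumsum(x))
  n <- length(x)
  out <- rep(NA_real_, n)
  i <- (1 + half_lo):(n - half_hi)
  out[i] <- (s[i + half_hi + 1L] - s[i - half_lo]) / w
  out
}

#' In vivo binding-preference scores of canonical 7-mers
#'
#' The cut-site signal is passed through a footprint-aware filter that
#' subtracts the 7 nt moving average from the 21 nt moving average at
#' each position: a TF bound at a 7-mer protects it from MNase while
#' cutting accumulates in the vicinity, so the filter rewards flanking
#' cuts and punishes cuts inside the word. Negative filter responses are
#' set to zero and each promoter position (ORFs excluded) contributes its
#' response to the canonical index of the 7-mer centered on it; the score
#' of an index is the mean contribution over its positions.
#'
#' @param track a normalized [coverage_track()].
#' @param genome `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param promoters a [define_promoters()] result.
#' @param annotation optional gene table whose ORFs (`orf_start`,
#'   `orf_end`, `chrom`) are masked out; promoters already exclude ORFs
#'   by construction, but overlapping ORFs of other genes are removed
#'   here as well.
#' @param window_small,window_large moving-average windows (7 and 21 nt).
#' @return Object of class `kmer_table`: `scores` (length 8192, named by
#'   canonical 7-mer), `counts` (contributing positions per index), and
#'   the window parameters.
#' @export
kmer_scores <- function(track, genome, promoters, annotation = NULL,
                        window_small = 7, window_large = 21) {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$normalized) stop("kmer_scores requires a normalized track")
  codes <- genome_base_codes(genome)
  sums <- numeric(kmer_codes_n / 2)
  counts <- numeric(kmer_codes_n / 2)
  lut <- kmer_lookup()
  half <- 3L
  edge <- 10L  # both moving-average windows must fit inside the contig

  for (ch in names(track$values)) {
    x <- track$values[[ch]]
    len <- length(x)
    if (len < 2 * edge + 1) next
    b <- codes[[ch]]
    if (length(b) != len)
      stop("sequence/track length mismatch on ", ch)

    pm <- promoters[promoters$chrom == ch, , drop = FALSE]
    if (!nrow(pm)) next
    mask <- region_mask(len, pm$start, pm$end)
    if (!is.null(annotation)) {
      orf <- annotation[annotation$chrom == ch, , drop = FALSE]
      if (nrow(orf))
        mask <- mask & !region_mask(len, orf$orf_start, orf$orf_end)
    }
    pos <- which(mask)
    pos <- pos[pos > edge & pos <= len - edge]
    if (!length(pos)) next

    filt <- moving_average(x, window_large) - moving_average(x, window_small)
    filt[is.na(filt)] <- 0
    filt[filt < 0] <- 0

    # 7-mer code centered on each position, via digit shifts
    code <- integer(length(pos))
    ok <- rep(TRUE, length(pos))
    for (j in (-half):half) {
      bj <- b[pos + j]
      ok <- ok & !is.na(bj)
      bj[is.na(bj)] <- 0L
      code <- code * 4L + bj
    }
    pos <- pos[ok]; code <- code[ok]
    if (!length(pos)) next
    idx <- lut$index[code + 1L] + 1L  # 1-based bin
    sums <- sums + unname(tapply(filt[pos], factor(idx, levels = seq_len(8192)),
                                 sum, default = 0))
    counts <- counts + tabulate(idx, nbins = 8192)
  }

  scores <- ifelse(counts > 0, sums / counts, 0)
  names(scores) <- lut$kmer
  structure(list(scores = scores, counts = counts, k = kmer_k,
                 window_small = window_small, window_large = window_large),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  top <- head(sort(x$scores, decreasing = TRUE), 5)
  cat(sprintf("kmer_table: 8192 canonical 7-mers, %d with signal\n",
              sum(x$scores > 0)))
  cat("  top:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a k-mer table as TSV
#'
#' @param table a [kmer_scores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_tsv <- function(table, path) {
  write.table(data.frame(kmer = names(table$scores),
                         score = unname(table$scores),
                         n_positions = table$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
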