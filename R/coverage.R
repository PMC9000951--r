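#' Per-base cut-site coverage track
#'
#' A `coverage_track` holds per-base, per-chromosome counts (or normalized
#' densities) of MNase cut sites, as produced by ChEC-seq fragment-end
#' mapping. Coordinates are 0-based half-open throughout the package, so
#' `values[[chrom]][i]` is the signal at 0-based position `i - 1`.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param normalized logical; `TRUE` once the genome-wide mean is one.
#' @param sample_id character label for the sample/repeat.
#' @param n_fragments integer number of sequenced fragments that produced
#'   the track (each fragment contributes its two end positions).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, normalized = FALSE, sample_id = "",
                           n_fragments = NA_integer_) {
  stopifnot(is.list(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))))
  for (v in values) {
    stopifnot(is.numeric(v))
    if (any(v < 0)) stop("coverage values must be non-negative")
  }
  structure(list(
    values = lapply(values, as.numeric),
    chrom_lengths = vapply(values, length, integer(1)),
    normalized = isTRUE(normalized),
    sample_id = as.character(sample_id),
    n_fragments = as.integer(n_fragments)
  ), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chrom(s), %s bp, %s, %s fragments\n",
              x$sample_id, length(x$values),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              if (x$normalized) "normalized (mean 1)" else "raw counts",
              format(x$n_fragments, big.mark = ",")))
  invisible(x)
}

genome_mean <- function(track) {
  tot <- sum(vapply(track$values, sum, numeric(1)))
  tot / sum(as.numeric(track$chrom_lengths))
}

#' Normalize coverage to genome-wide mean one
#'
#' Divides every per-base value by the genome-wide mean so that the mean
#' coverage over the (nuclear) genome equals one. Idempotent; all
#' downstream promoter-binding quantities assume this normalization.
#'
#' @param track a [coverage_track()].
#' @return The track with `normalized = TRUE` and mean exactly one.
#' @export
normalize_coverage <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  m <- genome_mean(track)
  if (m == 0) stop("cannot normalize an all-zero coverage track")
  track$values <- lapply(track$values, function(v) v / m)
  track$normalized <- TRUE
  track
}

#' Load fragment-end positions or per-base coverage from BED / BedGraph
#'
#' BED input is interpreted as sequenced fragments: each record increments
#' the count at its two end positions (first and last covered base), which
#' for ChEC-seq correspond to the actual MNase cutting sites. BedGraph
#' input is read as a ready per-base track.
#'
#' @param path path to a BED or BedGraph file; format inferred from the
#'   extension (`.bed` vs `.bedgraph`/`.bg`) unless given.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param format `"auto"`, `"bed"` or `"bedgraph"`.
#' @return A raw-count [coverage_track()] (`normalized = FALSE`).
#' @export
load_fragment_ends <- function(path, chrom_lengths, format = c("auto", "bed", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "bed"
  }
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  vals <- lapply(chrom_lengths, function(n) numeric(n))
  names(vals) <- names(chrom_lengths)
  n_frag <- 0L

  if (file.size(path) > 0) {
    gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "bedGraph")
    if (length(gr) > 0) {
      chs <- as.character(GenomicRanges::seqnames(gr))
      bad <- setdiff(unique(chs), names(chrom_lengths))
      if (length(bad)) {
        stop("unknown chromosome(s) in ", path, ": ", paste(bad, collapse = ", "))
      }
      st <- GenomicRanges::start(gr)  # 1-based
      en <- GenomicRanges::end(gr)    # 1-based last base
      oob <- st < 1 | en > chrom_lengths[chs]
      if (any(oob)) {
        i <- which(oob)[1]
        stop(sprintf("record %d (%s:%d-%d) out of chromosome bounds in %s",
                     i, chs[i], st[i] - 1L, en[i], path))
      }
      if (format == "bed") {
        for (ch in unique(chs)) {
          sel <- chs == ch
          ends <- c(st[sel], en[sel])
          vals[[ch]] <- vals[[ch]] + tabulate(ends, nbins = chrom_lengths[[ch]])
        }
        n_frag <- length(gr)
      } else {
        sc <- GenomicRanges::mcols(gr)$score
        for (ch in unique(chs)) {
          sel <- which(chs == ch)
          for (i in sel) vals[[ch]][st[i]:en[i]] <- sc[i]
        }
        n_frag <- NA_integer_
      }
    }
  }
  coverage_track(vals, normalized = FALSE,
                 sample_id = sub("\\.[^.]+$", "", basename(path)),
                 n_fragments = n_frag)
}

#' Write a coverage track as BedGraph
#'
#' Adjacent positions with equal values are merged into one record;
#' zero-valued runs are omitted.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)          # 1-based inclusive
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep] - 1L, ends[keep],
                       format(r$values[keep], trim = TRUE, scientific = FALSE,
                              digits = 15)), con)
  }
  invisible(path)
}

#' Bundle biological repeats of one strain
#'
#' @param tracks list of [coverage_track()] objects for one strain.
#' @return An object of class `repeat_set` with `qc_pass` and `internal_r`
#'   unset until [qc_repeats()] is run.
#' @export
repeat_set <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "coverage_track")))
  structure(list(tracks = tracks,
                 qc_pass = rep(NA, length(tracks)),
                 internal_r = NULL),
            class = "repeat_set")
}

pbs_vector <- function(track, promoters) {
  tr <- if (track$normalized) track else normalize_coverage(track)
  profile_pbs(tr, promoters)$pbs
}

#' Quality-control biological repeats
#'
#' A repeat passes if it has more than `min_fragments` fragments or its
#' mean pairwise promoter-binding-signal (pbs) correlation with the other
#' repeats exceeds `min_r` (defaults 200,000 and 0.9). Promoter-level
#' correlation is used rather than raw per-base correlation, which is
#' depth-dominated. Track values are never modified.
#'
#' @param repeats a [repeat_set()].
#' @param promoters a [promoter_set][define_promoters()] used to compute pbs.
#' @param min_fragments fragment-count criterion.
#' @param min_r mean pairwise pbs Pearson correlation criterion.
#' @return The `repeat_set` with `qc_pass` and the symmetric `internal_r`
#'   matrix filled in.
#' @export
qc_repeats <- function(repeats, promoters, min_fragments = 200000, min_r = 0.9) {
  stopifnot(inherits(repeats, "repeat_set"))
  n <- length(repeats$tracks)
  pbs_mat <- vapply(repeats$tracks, pbs_vector, numeric(nrow(promoters)),
                    promoters = promoters)
  r <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rij <- suppressWarnings(cor(pbs_mat[, i], pbs_mat[, j]))
      r[i, j] <- r[j, i] <- if (is.na(rij)) 0 else rij
    }
  }
  mean_r <- if (n >= 2) (rowSums(r) - 1) / (n - 1) else rep(NA_real_, n)
  frag_ok <- vapply(repeats$tracks, function(t)
    !is.na(t$n_fragments) && t$n_fragments > min_fragments, logical(1))
  corr_ok <- !is.na(mean_r) & mean_r > min_r
  repeats$qc_pass <- frag_ok | corr_ok
  repeats$internal_r <- r
  repeats
}

#' Mean strain profile over passing repeats
#'
#' Per-base arithmetic mean of the normalized, QC-passing repeats; at
#' least two passing repeats are required.
#'
#' @param repeats a QC'ed [repeat_set()].
#' @return A normalized [coverage_track()].
#' @export
mean_profile <- function(repeats) {
  stopifnot(inherits(repeats, "repeat_set"))
  if (all(is.na(repeats$qc_pass)))
    stop("run qc_repeats() before mean_profile()")
  keep <- which(repeats$qc_pass %in% TRUE)
  if (length(keep) < 2)
    stop("mean_profile() needs at least two QC-passing repeats (got ",
         length(keep), ")")
  tracks <- lapply(repeats$tracks[keep], function(t)
    if (t$normalized) t else normalize_coverage(t))
  vals <- tracks[[1]]$values
  for (t in tracks[-1]) {
    for (ch in names(vals)) vals[[ch]] <- vals[[ch]] + t$values[[ch]]
  }
  vals <- lapply(vals, function(v) v / length(tracks))
  coverage_track(vals, normalized = TRUE,
                 sample_id = paste0(tracks[[1]]$sample_id, "_mean"),
                 n_fragments = sum(vapply(tracks, function(t) t$n_fragments,
                                          integer(1))))
}

#' Flag strains with no reliable binding profile
#'
#' A strain whose repeats agree only at chance level carries no
#' sequence-specific binding information (e.g. a TF that binds DNA only as
#' a heterodimer with its now-deleted paralog). The flag requires at least
#' `min_repeats` repeats with mean internal pbs correlation below `max_r`.
#'
#' @param repeats a QC'ed [repeat_set()].
#' @param min_repeats minimum repeats for the call (default 4).
#' @param max_r internal-correlation ceiling (default 0.2).
#' @return `TRUE` if the strain has no reliable profile.
#' @export
no_reliable_profile <- function(repeats, min_repeats = 4, max_r = 0.2) {
  stopifnot(inherits(repeats, "repeat_set"))
  if (is.null(repeats$internal_r)) stop("run qc_repeats() first")
  n <- length(repeats$tracks)
  if (n < min_repeats) return(FALSE)
  off <- repeats$internal_r[upper.tri(repeats$internal_r)]
  mean(off) < max_r
}
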