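#' Specify a synthetic ChEC-seq scenario
#'
#' Bundles and validates the parameters of the synthetic-data generator:
#' a genome with regularly spaced genes, one planted motif instance per
#' promoter, and cut-site tracks in which a bound TF protects a footprint
#' around its motif while MNase cuts accumulate in two flanking bands.
#'
#' @param n_genes number of genes.
#' @param genome_length chromosome length in bp (>= `n_genes * 1500`).
#' @param motif motif string over `{A,C,G,T,N}` planted in promoters
#'   (`N` resolved randomly per instance).
#' @param shared_target_fraction fraction of ancestral targets retained
#'   by both paralogs.
#' @param asymmetry in `[0, 1]`: 0 splits the non-shared ancestral
#'   targets evenly between the paralogs, 1 gives them all to P1 (the
#'   intended direction of `|corr(P1, orth) - corr(P2, orth)|`).
#' @param new_target_fraction_P2 novel (non-ancestral) targets gained by
#'   P2, as a fraction of the ancestral set size.
#' @param footprint_halfwidth protected half-width around a bound motif
#'   center, bp; the default 3 protects the 7-mer core the TF sits on,
#'   so cuts start immediately beside the motif as in ChEC-seq.
#' @param cut_band width of each cut band flanking the footprint, bp.
#' @param background_rate expected background cuts per bp.
#' @param reads_per_repeat sequenced fragments per repeat (each
#'   contributes its two end positions).
#' @param n_repeats biological repeats per strain (>= 2).
#' @param seed global integer seed; all sub-streams derive from it.
#' @param n_ancestral_targets size of the ancestral target set (default
#'   5% of the genes, at least 8).
#' @param orf_length ORF length in bp.
#' @param affinity_sdlog log-normal spread of relative target
#'   affinities.
#' @return A validated list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_genes = 300, genome_length = n_genes * 1500,
                          motif = "TGACTCA",
                          shared_target_fraction = 0.5, asymmetry = 0,
                          new_target_fraction_P2 = 0,
                          footprint_halfwidth = 3, cut_band = 20,
                          background_rate = 0.2, reads_per_repeat = 500000,
                          n_repeats = 2, seed = 1,
                          n_ancestral_targets = max(8, round(0.05 * n_genes)),
                          orf_length = 500, affinity_sdlog = 0.25) {
  spec <- list(n_genes = as.integer(n_genes),
               genome_length = as.integer(genome_length),
               motif = toupper(motif),
               shared_target_fraction = shared_target_fraction,
               asymmetry = asymmetry,
               new_target_fraction_P2 = new_target_fraction_P2,
               footprint_halfwidth = as.integer(footprint_halfwidth),
               cut_band = as.integer(cut_band),
               background_rate = background_rate,
               reads_per_repeat = as.integer(reads_per_repeat),
               n_repeats = as.integer(n_repeats),
               seed = as.integer(seed),
               n_ancestral_targets = as.integer(n_ancestral_targets),
               orf_length = as.integer(orf_length),
               affinity_sdlog = affinity_sdlog)
  for (f in c("shared_target_fraction", "asymmetry",
              "new_target_fraction_P2")) {
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  }
  if (spec$n_genes < 0) stop("n_genes must be non-negative")
  if (spec$n_genes > 0 && spec$genome_length < spec$n_genes * 1500)
    stop("genome too short: need at least ", spec$n_genes * 1500,
         " bp for ", spec$n_genes, " genes")
  if (spec$n_repeats < 2) stop("n_repeats must be at least 2")
  if (!grepl("^[ACGTN]+$", spec$motif)) stop("motif must be over {A,C,G,T,N}")
  if (spec$n_genes > 0 &&
      spec$n_ancestral_targets > spec$n_genes)
    stop("n_ancestral_targets exceeds n_genes")
  class(spec) <- "scenario_spec"
  spec
}

resolve_motif_instance <- function(motif) {
  ch <- strsplit(motif, "")[[1]]
  ch[ch == "N"] <- sample(c("A", "C", "G", "T"), sum(ch == "N"),
                          replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a synthetic genome and gene annotation
#'
#' Genes are laid out with fixed spacing on alternating strands; each
#' gene gets an ORF, a TSS 20-200 bp upstream of the start codon, and
#' one planted instance of the scenario motif in the central part of its
#' promoter. Promoter sequence elsewhere is scrubbed of chance motif
#' matches (on either strand) so that the planted occurrences are
#' exactly the promoter occurrences.
#'
#' @param spec a [scenario_spec()].
#' @return List with `genome` (`DNAStringSet`), `annotation` (gene
#'   table: `gene_id`, `chrom`, `orf_start`, `orf_end`, `strand`, `tss`;
#'   0-based half-open) and `motifs` (planted instances: `gene_id`,
#'   `chrom`, `start`, `center`, `strand`, `instance`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(substream_seed(spec$seed, "genome"))
  empty_motifs <- data.frame(gene_id = character(0), chrom = character(0),
                             start = integer(0), center = integer(0),
                             strand = character(0), instance = character(0),
                             stringsAsFactors = FALSE)
  if (spec$n_genes == 0) {
    return(list(genome = Biostrings::DNAStringSet(),
                annotation = data.frame(gene_id = character(0),
                                        chrom = character(0),
                                        orf_start = integer(0),
                                        orf_end = integer(0),
                                        strand = character(0),
                                        tss = integer(0),
                                        stringsAsFactors = FALSE),
                motifs = empty_motifs))
  }
  L <- spec$genome_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  spacing <- L %/% spec$n_genes
  mlen <- nchar(spec$motif)

  i <- seq_len(spec$n_genes)
  slot0 <- (i - 1L) * spacing
  plus <- i %% 2L == 1L
  u <- sample(20:200, spec$n_genes, replace = TRUE)
  d <- sample(250:450, spec$n_genes, replace = TRUE)  # motif center offset
  orf_start <- ifelse(plus, slot0 + 900L, slot0 + 100L)
  orf_end <- orf_start + spec$orf_length
  tss <- ifelse(plus, orf_start - u, orf_end - 1L + u)
  center <- ifelse(plus, orf_start - d, orf_end + d)
  inst <- vapply(i, function(k) resolve_motif_instance(spec$motif),
                 character(1))
  m0 <- as.integer(center - (mlen - 1L) %/% 2L)
  for (k in i) {
    bases[(m0[k] + 1L):(m0[k] + mlen)] <- strsplit(inst[k], "")[[1]]
  }
  annotation <- data.frame(gene_id = sprintf("g%04d", i), chrom = "chrI",
                           orf_start = orf_start, orf_end = orf_end,
                           strand = ifelse(plus, "+", "-"), tss = tss,
                           stringsAsFactors = FALSE)
  motifs <- data.frame(gene_id = annotation$gene_id, chrom = "chrI",
                       start = m0, center = as.integer(center),
                       strand = "+", instance = inst,
                       stringsAsFactors = FALSE)
  bases <- scrub_spurious_matches(bases, spec$motif, annotation, motifs)
  genome <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""),
                                              "chrI"))
  list(genome = genome, annotation = annotation, motifs = motifs)
}

scrub_spurious_matches <- function(bases, motif, annotation, motifs) {
  # remove chance promoter matches (either strand) of the motif pattern
  # that were not planted, by mutating one base outside planted instances
  mlen <- nchar(motif)
  prom <- define_promoters(annotation)
  pat <- Biostrings::DNAString(motif)
  rcpat <- Biostrings::reverseComplement(pat)
  planted <- unlist(lapply(seq_len(nrow(motifs)), function(i)
    motifs$start[i]:(motifs$start[i] + mlen - 1L)))
  pmask <- region_mask(length(bases), prom$start, prom$end)
  for (iter in 1:25) {
    subj <- Biostrings::DNAString(paste(bases, collapse = ""))
    starts <- sort(unique(c(
      Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE)),
      Biostrings::start(Biostrings::matchPattern(rcpat, subj,
                                                 fixed = FALSE))))) - 1L
    spurious <- starts[!(starts %in% motifs$start) &
                         vapply(starts, function(s)
                           all(pmask[(s + 1):(s + mlen)]), logical(1))]
    if (!length(spurious)) break
    pat_ch <- strsplit(motif, "")[[1]]
    rc_ch <- strsplit(as.character(rcpat), "")[[1]]
    informative <- which(pat_ch != "N" & rc_ch != "N") - 1L
    for (s in spurious) {
      # mutate only positions that are informative on both strands (an N
      # in the pattern matches any base, so changing it breaks nothing)
      cand <- setdiff(s + informative, planted)
      if (!length(cand)) next  # overlaps a planted instance entirely
      p <- cand[(length(cand) + 1L) %/% 2L]
      bases[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                      bases[p + 1L]), 1)
    }
  }
  bases
}
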