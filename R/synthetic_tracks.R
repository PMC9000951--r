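#' Simulate ChEC-seq cut-site tracks for each TF and repeat
#'
#' Each sequenced fragment spans a bound motif: its two end positions
#' (the MNase cut sites) are drawn uniformly from two symmetric bands of
#' width `cut_band` flanking a fully protected footprint of half-width
#' `footprint_halfwidth` centered on the motif. Fragments are allocated
#' to a TF's targets in proportion to the recorded relative affinities;
#' the remainder of the read budget is uniform background (expected
#' `background_rate` cuts/bp, capped by the budget). Repeats are
#' independent draws from per-(TF, repeat) RNG sub-streams, so every
#' track has exactly `2 * reads_per_repeat` cut events.
#'
#' @param genome `DNAStringSet` from [make_genome()] (only lengths used).
#' @param annotation gene table from [make_genome()].
#' @param truth ground-truth list with `target_sets` (TF -> gene ids),
#'   `relative_affinities` (TF -> named positive vector) and `motifs`
#'   (planted-instance table).
#' @param spec the [scenario_spec()].
#' @param tfs which TFs to simulate (default: all in `truth`).
#' @return Named list (per TF) of lists (per repeat) of raw-count
#'   [coverage_track()] objects.
#' @export
make_chec_tracks <- function(genome, annotation, truth, spec,
                             tfs = names(truth$target_sets)) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$reads_per_repeat <= 0)
    stop("reads_per_repeat must be positive; empty tracks are not useful")
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  L <- sum(as.numeric(chrom_lengths))
  missing <- setdiff(unlist(truth$target_sets[tfs]), truth$motifs$gene_id)
  if (length(missing))
    stop("target genes without planted motifs: ",
         paste(head(missing, 3), collapse = ", "))

  centers <- setNames(truth$motifs$center, truth$motifs$gene_id)
  chroms <- setNames(truth$motifs$chrom, truth$motifs$gene_id)
  fh <- spec$footprint_halfwidth
  cb <- spec$cut_band

  out <- list()
  for (tf in tfs) {
    reps <- vector("list", spec$n_repeats)
    for (r in seq_len(spec$n_repeats)) {
      set.seed(substream_seed(spec$seed, "tracks", tf, r))
      n_frag <- spec$reads_per_repeat
      p_bg <- min(1, spec$background_rate * L / (2 * n_frag))
      n_bg <- rbinom(1, n_frag, p_bg)
      n_sig <- n_frag - n_bg

      cuts <- lapply(chrom_lengths, function(n) integer(0))
      targets <- truth$target_sets[[tf]]
      if (length(targets) && n_sig > 0) {
        aff <- truth$relative_affinities[[tf]][targets]
        counts <- as.vector(rmultinom(1, n_sig, aff / sum(aff)))
        for (k in seq_along(targets)) {
          if (counts[k] == 0) next
          g <- targets[k]
          c0 <- centers[[g]]
          left <- c0 - fh - sample.int(cb, counts[k], replace = TRUE)
          right <- c0 + fh + sample.int(cb, counts[k], replace = TRUE)
          cuts[[chroms[[g]]]] <- c(cuts[[chroms[[g]]]], left, right)
        }
      } else {
        n_bg <- n_frag  # unbound TF: the whole budget is background
      }
      if (n_bg > 0) {
        pos <- sample.int(L, 2 * n_bg, replace = TRUE) - 1L
        off <- 0
        for (ch in names(chrom_lengths)) {
          sel <- pos >= off & pos < off + chrom_lengths[[ch]]
          cuts[[ch]] <- c(cuts[[ch]], pos[sel] - off)
          off <- off + chrom_lengths[[ch]]
        }
      }
      vals <- lapply(names(chrom_lengths), function(ch)
        as.numeric(tabulate(cuts[[ch]] + 1L, nbins = chrom_lengths[[ch]])))
      names(vals) <- names(chrom_lengths)
      reps[[r]] <- coverage_track(vals, normalized = FALSE,
                                  sample_id = sprintf("%s_rep%d", tf, r),
                                  n_fragments = n_frag)
    }
    out[[tf]] <- reps
  }
  out
}

#' Simulate a full paralog-divergence scenario
#'
#' Splits an ancestral target set between two paralogs and simulates
#' cut-site tracks for five strains: each paralog in the wild type
#' (`P1`, `P2`), each paralog in the other's deletion background
#' (`P1_d2`, `P2_d1`), and the ancestral-proxy ortholog (`orth`, bound
#' at the full ancestral set). A `shared_target_fraction` of the
#' ancestral targets stays shared; the remainder is divided according to
#' `asymmetry` (1 = all to P1); P2 additionally gains
#' `new_target_fraction_P2 * n_ancestral` novel targets. Ancestral
#' targets keep their ancestral relative affinities in the descendant
#' TFs, so binding correlations against the ortholog reflect target-set
#' overlap.
#'
#' @param spec a [scenario_spec()].
#' @param deletion_response named character vector with entries `P1` and
#'   `P2` describing how each paralog reacts to the other's deletion:
#'   `"independent"` (unchanged targets), `"competitive_release"` (gains
#'   the deleted paralog's exclusive targets), `"dependent"` (loses the
#'   shared targets, as for an obligate heterodimer) or
#'   `"loss_of_specificity"` (no sequence-specific binding left; pure
#'   background).
#' @param strains which of `P1`, `P2`, `P1_d2`, `P2_d1`, `orth` to
#'   simulate tracks for (truth is always complete).
#' @return List with `genome`, `annotation`, `motifs`, `tracks` (per
#'   strain key, a list of repeat tracks) and `truth` (target sets,
#'   relative affinities, planted-motif table, scenario parameters).
#' @export
make_paralog_scenario <- function(spec,
                                  deletion_response = c(P1 = "independent",
                                                        P2 = "independent"),
                                  strains = c("P1", "P2", "P1_d2", "P2_d1",
                                              "orth")) {
  stopifnot(inherits(spec, "scenario_spec"))
  modes <- c("independent", "competitive_release", "dependent",
             "loss_of_specificity")
  stopifnot(all(deletion_response %in% modes),
            all(c("P1", "P2") %in% names(deletion_response)))
  gen <- make_genome(spec)
  genes <- gen$annotation$gene_id
  n_anc <- spec$n_ancestral_targets
  n_new <- round(spec$new_target_fraction_P2 * n_anc)
  if (n_anc + n_new > length(genes))
    stop("scenario needs ", n_anc + n_new, " target genes but only ",
         length(genes), " genes exist")

  set.seed(substream_seed(spec$seed, "scenario"))
  anc <- sample(genes, n_anc)
  n_shared <- round(spec$shared_target_fraction * n_anc)
  shared <- anc[seq_len(n_shared)]
  rest <- setdiff(anc, shared)
  r1 <- round(length(rest) * (0.5 + spec$asymmetry / 2))
  R1 <- rest[seq_len(r1)]
  R2 <- setdiff(rest, R1)
  new_set <- if (n_new > 0) sample(setdiff(genes, anc), n_new) else character(0)

  p1_set <- c(shared, R1)
  p2_set <- c(shared, R2, new_set)

  aff_anc <- setNames(stats::rlnorm(n_anc, 0, spec$affinity_sdlog), anc)
  aff_new <- setNames(stats::rlnorm(length(new_set), 0, spec$affinity_sdlog),
                      new_set)
  aff_all <- c(aff_anc, aff_new)

  del_set <- function(tf_set, other_exclusive, mode) {
    switch(mode,
           independent = tf_set,
           competitive_release = union(tf_set, other_exclusive),
           dependent = setdiff(tf_set, shared),
           loss_of_specificity = character(0))
  }
  p1_d2 <- del_set(p1_set, setdiff(p2_set, p1_set), deletion_response[["P1"]])
  p2_d1 <- del_set(p2_set, setdiff(p1_set, p2_set), deletion_response[["P2"]])

  target_sets <- list(P1 = p1_set, P2 = p2_set, P1_d2 = p1_d2,
                      P2_d1 = p2_d1, orth = anc)
  # released targets are bound at half their intrinsic affinity
  aff_for <- function(set, released = character(0)) {
    a <- aff_all[set]
    a[names(a) %in% released] <- a[names(a) %in% released] * 0.5
    a
  }
  relative_affinities <- list(
    P1 = aff_for(p1_set), P2 = aff_for(p2_set),
    P1_d2 = aff_for(p1_d2, released = setdiff(p1_d2, p1_set)),
    P2_d1 = aff_for(p2_d1, released = setdiff(p2_d1, p2_set)),
    orth = aff_anc)

  truth <- list(target_sets = target_sets,
                relative_affinities = relative_affinities,
                motifs = gen$motifs,
                shared_targets = shared, new_targets_P2 = new_set,
                ancestral_targets = anc,
                deletion_response = deletion_response, spec = spec)
  strains <- match.arg(strains, several.ok = TRUE)
  tracks <- make_chec_tracks(gen$genome, gen$annotation, truth, spec,
                             tfs = strains)
  list(genome = gen$genome, annotation = gen$annotation,
       motifs = gen$motifs, tracks = tracks, truth = truth)
}
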