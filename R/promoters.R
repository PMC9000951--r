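#' Define promoter intervals from an ORF/TSS annotation
#'
#' The promoter of a gene runs from its start codon upstream to `window`
#' bp upstream of the TSS (or of the start codon when no TSS is
#' available), truncated at the nearest verified ORF. Minus-strand genes
#' are handled strand-mirrored. Promoters of divergent gene pairs may
#' overlap each other (they share intergenic bases) but never overlap an
#' annotated ORF.
#'
#' @param annotation data frame with columns `gene_id`, `chrom`,
#'   `orf_start`, `orf_end` (0-based half-open), `strand` (`"+"`/`"-"`)
#'   and optional `tss` (0-based position of the TSS base, `NA` if
#'   unknown).
#' @param window bp to extend upstream of the TSS (default 700).
#' @return A data frame of class `promoter_set` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `tss_used`,
#'   `truncated_by`. Genes whose TSS lies downstream of the start codon
#'   are skipped with a warning.
#' @export
define_promoters <- function(annotation, window = 700) {
  req <- c("gene_id", "chrom", "orf_start", "orf_end", "strand")
  stopifnot(all(req %in% names(annotation)))
  ann <- as.data.frame(annotation)
  if (is.null(ann$tss)) ann$tss <- NA_real_
  stopifnot(all(ann$strand %in% c("+", "-")),
            all(ann$orf_end > ann$orf_start))

  n <- nrow(ann)
  has_tss <- !is.na(ann$tss)
  plus <- ann$strand == "+"

  bad <- (plus & has_tss & ann$tss >= ann$orf_start) |
         (!plus & has_tss & ann$tss < ann$orf_end)
  for (g in ann$gene_id[bad])
    warning("TSS downstream of start codon for gene ", g, "; gene skipped")

  # mirror-symmetric rule: the promoter covers the TSS base and `window`
  # bases upstream of it, down to the start codon
  anchor <- ifelse(has_tss, ann$tss, ifelse(plus, ann$orf_start, NA))
  start <- ifelse(plus, pmax(anchor - window, 0), ann$orf_end)
  end <- ifelse(plus, ann$orf_start,
                ifelse(has_tss, ann$tss + 1, ann$orf_end) + window)
  tss_used <- has_tss
  truncated_by <- rep(NA_character_, n)

  # truncate at the nearest other verified ORF on the same chromosome
  prom_gr <- GenomicRanges::GRanges(ann$chrom,
                                    IRanges::IRanges(start + 1,
                                                     pmax(end, start + 1)))
  orf_gr <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$orf_start + 1,
                                                    ann$orf_end))
  hits <- GenomicRanges::findOverlaps(prom_gr, orf_gr)
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    j <- S4Vectors::subjectHits(hits)[h]
    if (i == j || bad[i] || end[i] <= start[i]) next
    os <- ann$orf_start[j]; oe <- ann$orf_end[j]
    if (oe <= start[i] || os >= end[i]) next
    if (plus[i]) {
      # keep the sub-interval adjacent to the gene's ORF start
      if (oe < end[i]) start[i] <- max(start[i], oe) else start[i] <- end[i]
    } else {
      if (os > start[i]) end[i] <- min(end[i], os) else end[i] <- start[i]
    }
    truncated_by[i] <- ann$gene_id[j]
  }
  end <- pmax(end, start)

  out <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    start = start, end = end, strand = ann$strand,
                    tss_used = tss_used, truncated_by = truncated_by,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Export promoters as BED6
#'
#' @param promoters a [define_promoters()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start + 1, promoters$end),
    strand = promoters$strand)
  names(gr) <- promoters$gene_id
  GenomicRanges::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Promoter-binding signal (pbs)
#'
#' The pbs of a gene is the sum of mean-1-normalized coverage over its
#' promoter interval; a promoter of length L has expectation L under a
#' featureless track.
#'
#' @param track a normalized [coverage_track()].
#' @param promoters a [define_promoters()] result.
#' @param tf_id label for the profiled TF.
#' @return An object of class `binding_profile` with the `pbs` vector
#'   filled in (z-scores etc. via [zscore_and_maxnorm()]).
#' @export
pbs <- function(track, promoters, tf_id = track$sample_id) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(promoters, "promoter_set"))
  if (!track$normalized)
    stop("pbs requires a normalized track; call normalize_coverage() first")
  v <- numeric(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    ch <- promoters$chrom[i]
    if (!ch %in% names(track$values))
      stop("promoter chromosome not in track: ", ch)
    s <- promoters$start[i]; e <- promoters$end[i]
    v[i] <- if (e > s) sum(track$values[[ch]][(s + 1):e]) else 0
  }
  names(v) <- promoters$gene_id
  structure(list(tf_id = tf_id, pbs = v, z = NULL, max_norm = NULL,
                 targets = NULL, threshold_used = NA_real_),
            class = "binding_profile")
}

profile_pbs <- pbs

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("binding_profile '%s': %d promoters%s\n", x$tf_id,
              length(x$pbs),
              if (!is.null(x$targets))
                sprintf(", %d targets (z > %.3g)", length(x$targets),
                        x$threshold_used) else ""))
  invisible(x)
}

#' Add z-scores and max-normalized signal to a binding profile
#'
#' z-scores are computed over all promoters of the TF using the
#' population (n-denominator) standard deviation; `max_norm` rescales pbs
#' to the promoter with the highest signal.
#'
#' @param profile a [pbs()] result.
#' @return The profile with `z` and `max_norm` filled in.
#' @export
zscore_and_maxnorm <- function(profile) {
  stopifnot(inherits(profile, "binding_profile"))
  v <- profile$pbs
  if (length(v) < 2) stop("need at least two promoters for z-scores")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("constant pbs vector: z-scores undefined")
  profile$z <- (v - mean(v)) / s
  profile$max_norm <- if (max(v) > 0) v / max(v) else v
  profile
}

#' Call significantly bound promoters
#'
#' The target threshold is the 99% quantile of the z-scores, capped at
#' 3.5; targets are the promoters with z strictly above it.
#'
#' @param profile a [zscore_and_maxnorm()] result.
#' @param quantile quantile of z used as threshold (default 0.99).
#' @param cap upper bound on the threshold (default 3.5).
#' @return The profile with `targets` and `threshold_used` filled in.
#' @export
call_targets <- function(profile, quantile = 0.99, cap = 3.5) {
  stopifnot(inherits(profile, "binding_profile"))
  if (is.null(profile$z)) stop("run zscore_and_maxnorm() first")
  thr <- min(stats::quantile(profile$z, quantile, names = FALSE), cap)
  profile$threshold_used <- thr
  profile$targets <- names(profile$z)[profile$z > thr]
  profile
}

#' Select the jointly top-bound promoters of a paralog pair
#'
#' Ranks promoters by a pair score (default: the larger of the two
#' z-scores) and returns the `n` best. Ties are broken lexicographically
#' by gene id for determinism.
#'
#' @param profile1,profile2 [zscore_and_maxnorm()] results sharing the
#'   promoter universe.
#' @param n number of promoters to return (default 40).
#' @param rule `"max"` (default) or `"sum"` of the two z-scores.
#' @return Character vector of gene ids, best first.
#' @export
select_top_promoters <- function(profile1, profile2, n = 40,
                                 rule = c("max", "sum")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile1, "binding_profile"),
            inherits(profile2, "binding_profile"))
  if (is.null(profile1$z) || is.null(profile2$z))
    stop("run zscore_and_maxnorm() on both profiles first")
  g <- names(profile1$z)
  if (!identical(sort(g), sort(names(profile2$z))))
    stop("profiles do not share the promoter universe")
  z2 <- profile2$z[g]
  score <- switch(rule, max = pmax(profile1$z, z2), sum = profile1$z + z2)
  if (n > length(g)) {
    warning("n exceeds promoter count; returning all ", length(g))
    n <- length(g)
  }
  if (n <= 0) return(character(0))
  ord <- order(-score, g)
  g[ord][seq_len(n)]
}

circuit_edge_names <- c("auto1", "cross12", "cross21", "auto2")

canonical_circuit <- function(edges) {
  # edges: logical (auto1, cross12, cross21, auto2); equivalence under
  # simultaneous paralog swap (auto1<->auto2, cross12<->cross21)
  a <- as.integer(edges)
  b <- a[c(4, 3, 2, 1)]
  ka <- paste(a, collapse = "")
  kb <- paste(b, collapse = "")
  if (ka <= kb) ka else kb
}

#' Classify the regulatory circuit of a paralog pair
#'
#' The four directed promoter-binding edges among two paralogous TFs
#' (each TF's own promoter and the paralog's promoter) define a circuit;
#' circuits are identified up to exchanging the two paralogs, giving ten
#' equivalence classes of which nine are non-empty.
#'
#' @param p1_profile,p2_profile [call_targets()] results for the two TFs.
#' @param p1_gene,p2_gene gene ids encoding the two TFs.
#' @return An object of class `circuit_class` with fields `label`
#'   (canonical edge string over `auto1, cross12, cross21, auto2`),
#'   `edges` (named logical) and `n_edges`.
#' @export
classify_circuit <- function(p1_profile, p2_profile, p1_gene, p2_gene) {
  stopifnot(inherits(p1_profile, "binding_profile"),
            inherits(p2_profile, "binding_profile"))
  if (is.null(p1_profile$targets) || is.null(p2_profile$targets))
    stop("run call_targets() on both profiles first")
  g <- names(p1_profile$pbs)
  if (!all(c(p1_gene, p2_gene) %in% g))
    stop("TF gene absent from the promoter universe")
  edges <- c(auto1 = p1_gene %in% p1_profile$targets,
             cross12 = p2_gene %in% p1_profile$targets,
             cross21 = p1_gene %in% p2_profile$targets,
             auto2 = p2_gene %in% p2_profile$targets)
  structure(list(label = canonical_circuit(edges), edges = edges,
                 n_edges = sum(edges)),
            class = "circuit_class")
}

#' Enumerate all circuit equivalence classes
#'
#' Walks all 16 subsets of the four directed edges and collapses them
#' under paralog exchange.
#'
#' @return Data frame with one row per edge subset: `edges` (binary
#'   string), `label` (canonical class) and `n_edges`.
#' @export
enumerate_circuit_classes <- function() {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  names(combos) <- circuit_edge_names
  lab <- apply(combos, 1, canonical_circuit)
  data.frame(edges = apply(combos, 1, function(e)
    paste(as.integer(e), collapse = "")),
    label = lab, n_edges = rowSums(combos), stringsAsFactors = FALSE)
}

#' Write a binding profile as TSV
#'
#' @param profile a [call_targets()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(gene_id = names(profile$pbs), pbs = unname(profile$pbs),
                   z = if (is.null(profile$z)) NA else unname(profile$z),
                   max_norm = if (is.null(profile$max_norm)) NA
                              else unname(profile$max_norm),
                   is_target = if (is.null(profile$targets)) NA
                               else names(profile$pbs) %in% profile$targets)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
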