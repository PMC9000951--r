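#' Read / write the gene annotation table
#'
#' Tab-delimited with columns `gene_id`, `chrom`, `orf_start`,
#' `orf_end`, `strand`, `tss` (0-based half-open ORF coordinates; `tss`
#' may be `NA`).
#'
#' @param path file path.
#' @return `read_annotation_tsv`: the annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "orf_start", "orf_end", "strand")
  stopifnot(all(req %in% names(ann)))
  ann
}

#' @rdname read_annotation_tsv
#' @param annotation annotation data frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full synthetic scenario to disk
#'
#' Genome as FASTA, annotation as TSV, every track as BedGraph, and the
#' ground truth (target sets and affinities) as TSV.
#'
#' @param scenario a [make_paralog_scenario()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_scenario <- function(scenario, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(scenario$genome,
                              file.path(outdir, "genome.fa"))
  write_annotation_tsv(scenario$annotation,
                       file.path(outdir, "annotation.tsv"))
  write.table(scenario$motifs, file.path(outdir, "planted_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (tf in names(scenario$tracks)) {
    for (r in seq_along(scenario$tracks[[tf]])) {
      write_bedgraph(scenario$tracks[[tf]][[r]],
                     file.path(outdir, sprintf("%s_rep%d.bedgraph", tf, r)))
    }
  }
  rows <- do.call(rbind, lapply(names(scenario$truth$target_sets),
    function(tf) {
      g <- scenario$truth$target_sets[[tf]]
      if (!length(g)) return(NULL)
      data.frame(tf = tf, gene_id = g,
                 affinity = unname(scenario$truth$relative_affinities[[tf]][g]),
                 stringsAsFactors = FALSE)
    }))
  write.table(rows, file.path(outdir, "truth_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path file with columns chrom, length (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}
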