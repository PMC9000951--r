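# Small hand-built fixtures used across test files.

# a single-chromosome track from a plain numeric vector
toy_track <- function(v, chrom = "chrI", normalized = FALSE, ...) {
  coverage_track(setNames(list(as.numeric(v)), chrom),
                 normalized = normalized, ...)
}

# annotation with one plus-strand gene whose promoter is [p_start, p_end)
toy_annotation <- function(orf_start = 10000, tss = NA, chrom = "chrI",
                           gene_id = "gA", strand = "+",
                           orf_len = 500) {
  data.frame(gene_id = gene_id, chrom = chrom, orf_start = orf_start,
             orf_end = orf_start + orf_len, strand = strand, tss = tss,
             stringsAsFactors = FALSE)
}

# a promoter_set built directly from intervals (bypassing annotation rules)
toy_promoters <- function(gene_id, start, end, chrom = "chrI",
                          strand = "+") {
  out <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                    end = end, strand = strand, tss_used = FALSE,
                    truncated_by = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

# a binding_profile directly from a named z vector (pbs = z for simplicity)
profile_from_z <- function(z, tf_id = "tf") {
  structure(list(tf_id = tf_id, pbs = z, z = z, max_norm = z / max(z),
                 targets = NULL, threshold_used = NA_real_),
            class = "binding_profile")
}

# small fast scenario for unit tests (not the acceptance conditions)
small_scenario_spec <- function(seed = 11, ...) {
  scenario_spec(n_genes = 60, reads_per_repeat = 50000, seed = seed, ...)
}
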