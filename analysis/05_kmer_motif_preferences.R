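#!/usr/bin/env Rscript

# Stage 5: sequence preferences. Scores all 8192 canonical 7-mers from
# the footprint-filtered cut-site signal in promoters, compares the
# paralog's and ortholog's 7-mer preferences, simplifies a PWM built
# around the planted motif, scans promoters for it, and quantifies the
# in vivo signal around the motif occurrences.

suppressMessages(library(paralobind))

spec <- scenario_spec(seed = 42, shared_target_fraction = 0.5,
                      asymmetry = 0.5, new_target_fraction_P2 = 0.25)
scenario <- make_paralog_scenario(
  spec, deletion_response = c(P1 = "competitive_release",
                              P2 = "independent"),
  strains = c("P1", "orth"))
promoters <- define_promoters(scenario$annotation)
dir.create("results", showWarnings = FALSE)

mean_track <- function(strain) {
  mean_profile(qc_repeats(repeat_set(scenario$tracks[[strain]]), promoters))
}
tr_p1 <- mean_track("P1")
tr_orth <- mean_track("orth")

k_p1 <- kmer_scores(tr_p1, scenario$genome, promoters,
                    annotation = scenario$annotation)
k_orth <- kmer_scores(tr_orth, scenario$genome, promoters,
                      annotation = scenario$annotation)
write_kmer_tsv(k_p1, "results/kmers_P1.tsv")
write_kmer_tsv(k_orth, "results/kmers_orth.tsv")

motif_idx <- canonical_kmer_index(spec$motif) + 1
rank_p1 <- rank(-k_p1$scores)[motif_idx]
cat(sprintf("planted motif %s ranks %d of 8192 in the P1 7-mer table\n",
            spec$motif, as.integer(rank_p1)))
cat(sprintf("7-mer preference correlation P1 vs ortholog: r = %.3f\n",
            cor(k_p1$scores, k_orth$scores)))

# a PWM centered on the planted motif with noisy flanks, as an in vitro
# proxy; its 5 most informative positions recover the motif core
base_freq <- function(b, p) { v <- rep((1 - p) / 3, 4); v[b] <- p; v }
motif_ch <- match(strsplit(spec$motif, "")[[1]], c("A", "C", "G", "T"))
pwm <- cbind(base_freq(1, 0.3),
             vapply(motif_ch, base_freq, numeric(4), p = 0.9),
             base_freq(3, 0.3))
rownames(pwm) <- c("A", "C", "G", "T")
simp <- simplify_pwm(pwm)
cat("simplified motif:", simp$pattern, "\n")

occ <- scan_motif(scenario$genome, simp, promoters)
cat(sprintf("%d promoter occurrences (%d planted)\n", nrow(occ),
            nrow(scenario$motifs)))

meta <- meta_signal(tr_p1, occ, window = 300)
write.table(data.frame(offset = -300:300, mean_signal = as.numeric(meta)),
            "results/meta_signal_P1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
target_genes <- intersect(occ$gene_id, scenario$truth$target_sets$P1)
pct <- pct_signal_near_motifs(tr_p1, promoters, occ, genes = target_genes)
cat(sprintf("%.1f%% of target-promoter signal lies within 50 bp of a motif\n",
            pct))
cat("wrote results/kmers_*.tsv and results/meta_signal_P1.tsv\n")
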