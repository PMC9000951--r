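#' Run the full pipeline on one synthetic scenario and score recovery
#'
#' Simulates a paralog scenario (`P1`, `P2`, ortholog at the scenario's
#' read depth), runs the complete analysis — normalization, repeat QC,
#' mean profiles, pbs, z-scores, target calling, repeat-aware
#' correlations and fate classification — and compares the results with
#' the generator's ground truth. Also performs a planted
#' proportionality check of the robust binding-change adjustment: the
#' wild-type profile is halved with a single strong target zeroed out,
#' and the recovered slope and flagged target are scored.
#'
#' @param spec a [scenario_spec()].
#' @return One-row data frame: `seed`, `repeat_r` (pbs correlation of
#'   the two P1 repeats), `corr_P1_P2`, `asymmetry_measured`,
#'   `conserved_called`, `conserved_true`, `conserved_ok`,
#'   `fate_label`, `pct_new_P2`, `shared_est`, `shared_true`, `slope`,
#'   `slope_err`, `lost_target_flagged`.
#' @export
evaluate_scenario_recovery <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sc <- make_paralog_scenario(spec, strains = c("P1", "P2", "orth"))
  pr <- define_promoters(sc$annotation)

  reps <- lapply(sc$tracks, function(tr)
    lapply(tr, function(t) pbs(normalize_coverage(t), pr)$pbs))
  profs <- lapply(names(sc$tracks), function(tf) {
    rs <- qc_repeats(repeat_set(sc$tracks[[tf]]), pr)
    zscore_and_maxnorm(pbs(mean_profile(rs), pr, tf))
  })
  names(profs) <- names(sc$tracks)

  repeat_r <- cor(reps$P1[[1]], reps$P1[[2]])
  fate <- classify_fate(reps$P1, reps$P2, reps$orth,
                        p1_profile = profs$P1, p2_profile = profs$P2,
                        orth_profile = profs$orth)

  # conserved paralog in truth: the copy retaining more ancestral targets
  anc <- sc$truth$ancestral_targets
  n1 <- length(intersect(sc$truth$target_sets$P1, anc))
  n2 <- length(intersect(sc$truth$target_sets$P2, anc))
  conserved_true <- if (n1 == n2) NA_character_ else
    if (n1 > n2) "P1" else "P2"

  t1 <- call_targets(profs$P1)$targets
  t2 <- call_targets(profs$P2)$targets
  to <- call_targets(profs$orth)$targets
  shared_est <- length(intersect(t1, t2)) / max(1, length(to))
  shared_true <- length(sc$truth$shared_targets) / length(anc)

  # planted proportionality: mutant = wild-type / 2 with one lost target
  wt <- profs$P1$pbs
  lost <- names(sort(wt, decreasing = TRUE))[1]
  mut <- 0.5 * wt
  mut[lost] <- 0
  ch <- adjust_deletion_profile(wt, mut, profs$P1$z)

  data.frame(seed = spec$seed, repeat_r = repeat_r,
             corr_P1_P2 = fate$corr_P1_P2,
             asymmetry_measured = fate$divergence_asymmetry,
             conserved_called = fate$conserved_paralog,
             conserved_true = conserved_true,
             conserved_ok = identical(fate$conserved_paralog,
                                      conserved_true),
             fate_label = fate$fate_label,
             pct_new_P2 = fate$pct_new_P2,
             shared_est = shared_est, shared_true = shared_true,
             slope = ch$slope, slope_err = abs(ch$slope - 0.5),
             lost_target_flagged = lost %in% ch$significant,
             stringsAsFactors = FALSE)
}

#' Multi-seed parameter-recovery study
#'
#' Repeats [evaluate_scenario_recovery()] over a set of seeds with
#' otherwise identical scenario parameters.
#'
#' @param seeds integer vector of scenario seeds.
#' @param ... scenario parameters passed to [scenario_spec()].
#' @return Data frame with one row per seed.
#' @export
recovery_study <- function(seeds, ...) {
  do.call(rbind, lapply(seeds, function(s)
    evaluate_scenario_recovery(scenario_spec(seed = s, ...))))
}
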