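#' Repeat-aware correlation between two strains
#'
#' Computes the Pearson correlation of promoter-binding signals between
#' every repeat of strain A and every repeat of strain B (nA x nB pairs)
#' and returns their mean and standard deviation, which is how strain
#' similarity and its error bar are quantified throughout the pipeline.
#'
#' @param repsA,repsB lists of named pbs vectors (one per repeat) on a
#'   shared promoter universe. A single vector is treated as one repeat.
#' @param same_strain if `TRUE`, pairs with the same repeat index are
#'   excluded (a strain compared to itself).
#' @return Object of class `correlation_result` with `mean_r`, `sd_r`,
#'   `n_pairs` and the individual `r` values.
#' @export
strain_correlation <- function(repsA, repsB, same_strain = FALSE) {
  if (is.numeric(repsA)) repsA <- list(repsA)
  if (is.numeric(repsB)) repsB <- list(repsB)
  stopifnot(length(repsA) >= 1, length(repsB) >= 1)
  g <- names(repsA[[1]])
  rs <- numeric(0)
  for (i in seq_along(repsA)) for (j in seq_along(repsB)) {
    if (same_strain && i == j) next
    a <- repsA[[i]]
    b <- if (is.null(g)) repsB[[j]] else repsB[[j]][g]
    if (sd(a) == 0 || sd(b) == 0) {
      warning("zero-variance pbs vector; pair (", i, ",", j, ") excluded")
      next
    }
    rs <- c(rs, cor(a, b))
  }
  if (!length(rs)) stop("no valid repeat pairs to correlate")
  structure(list(mean_r = mean(rs),
                 sd_r = if (length(rs) > 1) sd(rs) else 0,
                 n_pairs = length(rs), r = rs),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: mean r = %.4f (sd %.4f, %d repeat pairs)\n",
              x$mean_r, x$sd_r, x$n_pairs))
  invisible(x)
}

#' Adjust a mutant binding profile for global signal redistribution
#'
#' ChEC-seq coverage is mean-normalized, so losing binding at some
#' targets inflates the relative signal everywhere else. Assuming similar
#' absolute binding at most strong targets, a robust linear regression
#' (bisquare weights, tuning constant 4.685) of the mutant pbs on the
#' wild-type pbs is fitted over the 50 strongest wild-type promoters (or
#' more, if their z exceeds `z_gate`); the slope rescales the mutant
#' profile, and gene-specific changes are
#' `log2((pbs_adjusted + 700) / (pbs_wt + 700))`. The pseudocount of 700
#' equals the expected pbs of an average-length promoter under a
#' featureless mean-1 track.
#'
#' @param pbs_wt,pbs_mut named pbs vectors on a shared universe
#'   (wild-type and mutant: paralog deletion or DBD swap).
#' @param z_wt wild-type z-scores (from [zscore_and_maxnorm()]).
#' @param n_fit number of strongest promoters used for the fit.
#' @param z_gate z-score above which further promoters join the fit set.
#' @param pseudocount additive constant of the log-ratio.
#' @return Object of class `binding_change` with `slope`, `pbs_adjusted`,
#'   `log2_change`, `fit_genes`, `top_fit_genes` (the `n_fit` strongest,
#'   used for the significance baseline) and `significant` (from
#'   [significant_changes()]).
#' @export
adjust_deletion_profile <- function(pbs_wt, pbs_mut, z_wt, n_fit = 50,
                                    z_gate = 3.5, pseudocount = 700) {
  stopifnot(is.numeric(pbs_wt), is.numeric(pbs_mut),
            !is.null(names(pbs_wt)))
  if (length(pbs_wt) < n_fit)
    stop("need at least ", n_fit, " promoters (got ", length(pbs_wt), ")")
  pbs_mut <- pbs_mut[names(pbs_wt)]
  z_wt <- z_wt[names(pbs_wt)]
  ord <- order(-pbs_wt, names(pbs_wt))
  top <- names(pbs_wt)[ord][seq_len(n_fit)]
  fit_genes <- union(top, names(pbs_wt)[!is.na(z_wt) & z_wt > z_gate])
  x <- pbs_wt[fit_genes]; y <- pbs_mut[fit_genes]
  fit <- withCallingHandlers(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 200),
    warning = function(w) {
      # an (almost) exact linear relation drives the residual scale to
      # zero and the IRLS declares non-convergence although the slope is
      # settled; keep any other warning
      if (grepl("failed to converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (stats::mad(stats::resid(fit), center = 0) >
      1e-6 * max(abs(y)) && !fit$converged)
    warning("robust regression did not converge")
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate robust fit: slope = ", format(slope))
  adj <- pbs_mut / slope
  lc <- log2((adj + pseudocount) / (pbs_wt + pseudocount))
  out <- structure(list(slope = slope, pbs_adjusted = adj, log2_change = lc,
                        fit_genes = fit_genes, top_fit_genes = top,
                        pseudocount = pseudocount, significant = NULL),
                   class = "binding_change")
  out$significant <- significant_changes(out)
  out
}

#' Genes with significant binding changes
#'
#' A gene changes significantly if its absolute log2 binding change
#' exceeds the mean of the absolute changes over the strongest-bound
#' promoters by at least one standard deviation.
#'
#' @param change an [adjust_deletion_profile()] result.
#' @return Character vector of gene ids.
#' @export
significant_changes <- function(change) {
  stopifnot(inherits(change, "binding_change"))
  ref <- abs(change$log2_change[change$top_fit_genes])
  thr <- mean(ref) + sd(ref)
  if (!is.finite(thr)) return(character(0))
  names(change$log2_change)[abs(change$log2_change) > thr]
}

#' Binding robustness or fragility upon paralog deletion
#'
#' Compares a TF's similarity to its paralog before and after deleting
#' that paralog. An increase (`r_after > r_before`) indicates robustness:
#' the TF gains access to the paralog's targets once competition (or
#' another dependency) is removed; a decrease indicates fragility.
#'
#' @param tf_wt,tf_del,paralog_wt lists of repeat pbs vectors: the TF in
#'   the wild type, the same TF in the paralog-deletion background, and
#'   the paralog in the wild type.
#' @param loss_of_specificity set `TRUE` when the deletion-background
#'   strain has no reliable profile ([no_reliable_profile()]); the
#'   comparison is then meaningless and a flag is returned instead.
#' @return List with `r_before`, `r_after` ([strain_correlation()]
#'   results), `delta` and `verdict` (`"robust"`, `"fragile"`,
#'   `"unchanged"`), or a `loss_of_specificity` flag.
#' @export
robustness_fragility <- function(tf_wt, tf_del, paralog_wt,
                                 loss_of_specificity = FALSE) {
  if (isTRUE(loss_of_specificity)) {
    return(list(loss_of_specificity = TRUE, r_before = NULL, r_after = NULL,
                delta = NA_real_, verdict = "no_reliable_profile"))
  }
  r_before <- strain_correlation(tf_wt, paralog_wt)
  r_after <- strain_correlation(tf_del, paralog_wt)
  delta <- r_after$mean_r - r_before$mean_r
  list(loss_of_specificity = FALSE, r_before = r_before, r_after = r_after,
       delta = delta,
       verdict = if (delta > 0) "robust" else if (delta < 0) "fragile"
                 else "unchanged")
}

#' Percentage of paralog targets absent from the ortholog's targets
#'
#' Strong paralog targets are called at z > `z_paralog` (default 4.5) and
#' ortholog targets at z > `z_ortholog` (default 3.5); the returned
#' percentage of paralog targets not among the ortholog targets is the
#' "new"-target fraction used for fate classification.
#'
#' @param paralog_profile,ortholog_profile [zscore_and_maxnorm()] results.
#' @param z_paralog,z_ortholog z thresholds.
#' @return Percent in `[0, 100]`, or `NaN` with a warning when the
#'   paralog has no strong targets.
#' @export
new_target_fraction <- function(paralog_profile, ortholog_profile,
                                z_paralog = 4.5, z_ortholog = 3.5) {
  stopifnot(inherits(paralog_profile, "binding_profile"),
            inherits(ortholog_profile, "binding_profile"))
  if (is.null(paralog_profile$z) || is.null(ortholog_profile$z))
    stop("run zscore_and_maxnorm() on both profiles first")
  tp <- names(paralog_profile$z)[paralog_profile$z > z_paralog]
  to <- names(ortholog_profile$z)[ortholog_profile$z > z_ortholog]
  if (!length(tp)) {
    warning("paralog has no strong targets; new-target fraction undefined")
    return(NaN)
  }
  100 * length(setdiff(tp, to)) / length(tp)
}

#' Classify the divergence fate of a paralog pair
#'
#' Correlates each paralog with the ancestral-proxy ortholog (in the
#' paralog-deletion background when available) and combines the
#' divergence asymmetry `|corr(P1, orth) - corr(P2, orth)|` with the
#' new-target fractions into a fate label: `conserved` when the paralogs
#' still correlate strongly with each other (r >= 0.8), `neo` when one
#' paralog stayed ancestral while the other gained mostly new targets,
#' `sub` when the ancestral targets were split near-symmetrically with
#' few new targets, and `biased_neo_sub` otherwise.
#'
#' @param p1,p2,orth lists of repeat pbs vectors for paralog 1, paralog 2
#'   and the ortholog.
#' @param p1_profile,p2_profile,orth_profile [zscore_and_maxnorm()]
#'   profiles (mean over repeats) used for the new-target fractions.
#' @param p1_in_del,p2_in_del optional repeat pbs lists of each paralog
#'   measured in the other's deletion background; used for the ortholog
#'   correlations when given.
#' @param conserved_r paralog-correlation cut-off for `conserved`
#'   (default 0.8).
#' @param a_lo,a_hi asymmetry bounds for `sub` / `neo` (defaults 0.1, 0.4).
#' @param n_lo,n_hi new-target-percent bounds for `sub` / `neo`
#'   (defaults 25, 50).
#' @return Object of class `fate_summary` with the correlations,
#'   `divergence_asymmetry`, `conserved_paralog`, `pct_new_P1`,
#'   `pct_new_P2` and `fate_label`.
#' @export
classify_fate <- function(p1, p2, orth = NULL,
                          p1_profile = NULL, p2_profile = NULL,
                          orth_profile = NULL,
                          p1_in_del = NULL, p2_in_del = NULL,
                          conserved_r = 0.8, a_lo = 0.1, a_hi = 0.4,
                          n_lo = 25, n_hi = 50) {
  c12 <- strain_correlation(p1, p2)$mean_r
  if (is.null(orth)) {
    return(structure(list(
      corr_P1_P2 = c12, corr_P1_orth = NA_real_, corr_P2_orth = NA_real_,
      divergence_asymmetry = NA_real_, conserved_paralog = NA_character_,
      pct_new_P1 = NA_real_, pct_new_P2 = NA_real_,
      used_deletion_background = FALSE,
      fate_label = if (c12 >= conserved_r) "conserved" else "diverged"),
      class = "fate_summary"))
  }
  use_del <- !is.null(p1_in_del) && !is.null(p2_in_del)
  c1o <- strain_correlation(if (use_del) p1_in_del else p1, orth)$mean_r
  c2o <- strain_correlation(if (use_del) p2_in_del else p2, orth)$mean_r
  asym <- abs(c1o - c2o)
  conserved_paralog <- if (c1o >= c2o) "P1" else "P2"

  pct1 <- pct2 <- NA_real_
  if (!is.null(p1_profile) && !is.null(orth_profile))
    pct1 <- suppressWarnings(new_target_fraction(p1_profile, orth_profile))
  if (!is.null(p2_profile) && !is.null(orth_profile))
    pct2 <- suppressWarnings(new_target_fraction(p2_profile, orth_profile))
  pct_less_conserved <- if (conserved_paralog == "P1") pct2 else pct1

  label <- if (c12 >= conserved_r) {
    "conserved"
  } else if (asym >= a_hi && !is.na(pct_less_conserved) &&
             pct_less_conserved >= n_hi) {
    "neo"
  } else if (asym <= a_lo && !is.na(pct1) && !is.na(pct2) &&
             pct1 <= n_lo && pct2 <= n_lo) {
    "sub"
  } else {
    "biased_neo_sub"
  }

  structure(list(corr_P1_P2 = c12, corr_P1_orth = c1o, corr_P2_orth = c2o,
                 divergence_asymmetry = asym,
                 conserved_paralog = conserved_paralog,
                 pct_new_P1 = pct1, pct_new_P2 = pct2,
                 used_deletion_background = use_del,
                 fate_label = label),
            class = "fate_summary")
}

#' @export
print.fate_summary <- function(x, ...) {
  cat(sprintf(paste0("fate_summary: %s\n  corr(P1,P2) = %.3f; corr with",
                     " ortholog: P1 %.3f, P2 %.3f (asymmetry %.3f)\n",
                     "  conserved paralog: %s; %% new targets: P1 %.1f,",
                     " P2 %.1f\n"),
              x$fate_label, x$corr_P1_P2, x$corr_P1_orth, x$corr_P2_orth,
              x$divergence_asymmetry, x$conserved_paralog,
              x$pct_new_P1, x$pct_new_P2))
  invisible(x)
}
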