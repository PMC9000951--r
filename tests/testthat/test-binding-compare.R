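test_that("strain correlation averages all repeat pairs", {
  set.seed(3)
  x <- setNames(rnorm(50), paste0("g", 1:50))
  y <- x + rnorm(50, sd = 0.8)
  res <- strain_correlation(list(x, y), list(x, y))
  # enumerate the four pairs by hand
  expected <- c(cor(x, x), cor(x, y), cor(y, x), cor(y, y))
  expect_equal(res$n_pairs, 4)
  expect_equal(res$mean_r, mean(expected))
  expect_equal(res$sd_r, sd(expected))
  # with r(x, y) = r the four-pair mean is (1 + r + r + 1) / 4
  expect_equal(res$mean_r, (2 + 2 * cor(x, y)) / 4)

  # the same data as a self-comparison drops the diagonal pairs
  self <- strain_correlation(list(x, y), list(x, y), same_strain = TRUE)
  expect_equal(self$n_pairs, 2)
  expect_equal(self$mean_r, cor(x, y))

  neg <- strain_correlation(list(x), list(-x))
  expect_equal(neg$mean_r, -1)
  expect_equal(neg$sd_r, 0)
  expect_equal(strain_correlation(list(x), list(x))$mean_r, 1)

  # symmetry in the arguments
  ab <- strain_correlation(list(x), list(y, -y))
  ba <- strain_correlation(list(y, -y), list(x))
  expect_equal(ab$mean_r, ba$mean_r)
  expect_equal(ab$sd_r, ba$sd_r)

  const <- setNames(rep(1, 50), names(x))
  expect_warning(expect_error(strain_correlation(list(const), list(const)),
                              "no valid"), "zero-variance")
})

test_that("robust slope adjustment matches the IRLS oracle and is exact on proportional data", {
  set.seed(4)
  wt <- setNames(c(sort(runif(50, 500, 6000), decreasing = TRUE),
                   runif(150, 0, 400)), paste0("g", 1:200))
  z <- (wt - mean(wt)) / sqrt(mean((wt - mean(wt))^2))

  # exact proportionality: slope recovered to machine precision,
  # log2 changes identically zero (pseudocount formula identity)
  ch <- adjust_deletion_profile(wt, 0.5 * wt, z)
  expect_equal(ch$slope, 0.5, tolerance = 1e-9)
  expect_true(all(abs(ch$log2_change) < 1e-9))
  expect_equal(length(significant_changes(ch)), 0)

  ident <- adjust_deletion_profile(wt, wt, z)
  expect_equal(ident$slope, 1, tolerance = 1e-9)

  # one strong target lost: the robust fit down-weights it
  mut <- 0.5 * wt
  lost <- names(wt)[3]
  mut[lost] <- 0
  ch2 <- adjust_deletion_profile(wt, mut, z)
  expect_equal(ch2$slope, 0.5, tolerance = 1e-6)
  oracle <- oracle_irls_slope(wt[ch2$fit_genes], mut[ch2$fit_genes])
  expect_equal(ch2$slope, oracle, tolerance = 1e-6)
  expect_equal(unname(ch2$log2_change[lost]),
               log2(700 / (wt[[lost]] + 700)))
  expect_true(lost %in% ch2$significant)

  # scale equivariance: scaling the mutant rescales the slope and
  # leaves the changes untouched
  ch3 <- adjust_deletion_profile(wt, 3 * mut, z)
  expect_equal(ch3$slope, 3 * ch2$slope, tolerance = 1e-6)
  expect_equal(ch3$log2_change, ch2$log2_change, tolerance = 1e-9)

  expect_error(adjust_deletion_profile(wt[1:30], 0.5 * wt[1:30], z[1:30]),
               "at least 50")
})

test_that("significant changes exceed the top-promoter mean by one sd", {
  set.seed(5)
  wt <- setNames(c(runif(50, 1000, 5000), runif(100, 0, 300)),
                 paste0("g", 1:150))
  z <- (wt - mean(wt)) / sqrt(mean((wt - mean(wt))^2))
  mut <- wt * 0.5
  weak <- "g120"
  mut[weak] <- wt[weak] * 0.5 / 16  # 4 log2 units down after adjustment
  ch <- adjust_deletion_profile(wt, mut, z)
  # the constructed threshold on the top-50 changes flags only that gene
  ref <- abs(ch$log2_change[ch$top_fit_genes])
  expect_true(abs(ch$log2_change[[weak]]) > mean(ref) + sd(ref))
  expect_equal(significant_changes(ch), weak)

  # |.| symmetry: negating all changes preserves the significant set
  ch_neg <- ch
  ch_neg$log2_change <- -ch$log2_change
  expect_equal(significant_changes(ch_neg), significant_changes(ch))
})

test_that("new-target fractions count paralog targets outside the ortholog set", {
  zp <- setNames(rep(0, 100), paste0("g", 1:100))
  zo <- zp
  zp[c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9", "g10")] <- 6
  zo[paste0("g", 1:6)] <- 6  # 4 of 10 paralog targets are new
  p <- profile_from_z(zp); o <- profile_from_z(zo)
  expect_equal(new_target_fraction(p, o), 40)

  o_all <- profile_from_z(zp)
  expect_equal(new_target_fraction(p, o_all), 0)
  zd <- setNames(rep(0, 100), paste0("g", 1:100))
  zd[paste0("g", 90:99)] <- 6
  expect_equal(new_target_fraction(p, profile_from_z(zd)), 100)

  empty <- profile_from_z(setNames(c(rep(0, 99), 1), paste0("g", 1:100)))
  expect_warning(res <- new_target_fraction(empty, o), "no strong targets")
  expect_true(is.nan(res))
})

test_that("fate classification recovers planted divergence scenarios", {
  # pure neo: P1 keeps the ancestral set, P2 binds only new targets
  sp <- scenario_spec(n_genes = 120, reads_per_repeat = 120000,
                      shared_target_fraction = 0, asymmetry = 1,
                      new_target_fraction_P2 = 1, seed = 21)
  sc <- make_paralog_scenario(sp, strains = c("P1", "P2", "orth"))
  pr <- define_promoters(sc$annotation)
  reps <- lapply(sc$tracks, function(tr)
    lapply(tr, function(t) pbs(normalize_coverage(t), pr)$pbs))
  prof <- lapply(names(sc$tracks), function(tf)
    zscore_and_maxnorm(pbs(mean_profile(qc_repeats(repeat_set(sc$tracks[[tf]]),
                                                   pr)), pr, tf)))
  names(prof) <- names(sc$tracks)
  fate <- classify_fate(reps$P1, reps$P2, reps$orth,
                        p1_profile = prof$P1, p2_profile = prof$P2,
                        orth_profile = prof$orth)
  expect_equal(fate$fate_label, "neo")
  expect_equal(fate$conserved_paralog, "P1")
  expect_equal(fate$pct_new_P2, 100)
  expect_gt(fate$divergence_asymmetry, 0.4)

  # even split of the ancestral targets, no new targets: sub
  sp2 <- scenario_spec(n_genes = 120, reads_per_repeat = 120000,
                       shared_target_fraction = 0, asymmetry = 0,
                       new_target_fraction_P2 = 0, seed = 22)
  sc2 <- make_paralog_scenario(sp2, strains = c("P1", "P2", "orth"))
  pr2 <- define_promoters(sc2$annotation)
  reps2 <- lapply(sc2$tracks, function(tr)
    lapply(tr, function(t) pbs(normalize_coverage(t), pr2)$pbs))
  prof2 <- lapply(names(sc2$tracks), function(tf)
    zscore_and_maxnorm(pbs(mean_profile(qc_repeats(repeat_set(sc2$tracks[[tf]]),
                                                   pr2)), pr2, tf)))
  names(prof2) <- names(sc2$tracks)
  fate2 <- classify_fate(reps2$P1, reps2$P2, reps2$orth,
                         p1_profile = prof2$P1, p2_profile = prof2$P2,
                         orth_profile = prof2$orth)
  expect_equal(fate2$fate_label, "sub")
  expect_lt(fate2$divergence_asymmetry, 0.1)

  # identical inputs are conserved with zero asymmetry
  fate3 <- classify_fate(reps$P1, reps$P1, reps$P1,
                         p1_profile = prof$P1, p2_profile = prof$P1,
                         orth_profile = prof$P1)
  expect_equal(fate3$fate_label, "conserved")
  expect_equal(fate3$divergence_asymmetry, 0, tolerance = 1e-6)

  # relabeling invariance: asymmetry unchanged, conserved paralog flips
  swapped <- classify_fate(reps$P2, reps$P1, reps$orth,
                           p1_profile = prof$P2, p2_profile = prof$P1,
                           orth_profile = prof$orth)
  expect_equal(swapped$divergence_asymmetry, fate$divergence_asymmetry)
  expect_equal(swapped$conserved_paralog, "P2")
  expect_equal(swapped$fate_label, "neo")

  # without an ortholog only the paralog correlation is classified
  noorth <- classify_fate(reps$P1, reps$P2)
  expect_equal(noorth$fate_label, "diverged")
  expect_true(is.na(noorth$corr_P1_orth))
})

test_that("deletion responses produce robustness or fragility signatures", {
  sp <- scenario_spec(n_genes = 120, reads_per_repeat = 120000,
                      shared_target_fraction = 0.5, asymmetry = 0,
                      seed = 31)
  pr_for <- function(sc) define_promoters(sc$annotation)
  reps_of <- function(sc, pr) lapply(sc$tracks, function(tr)
    lapply(tr, function(t) pbs(normalize_coverage(t), pr)$pbs))

  # competitive release: P1 gains P2-exclusive targets in the deletion,
  # so P1-after resembles P2 more than P1-before did
  scr <- make_paralog_scenario(sp, deletion_response = c(
    P1 = "competitive_release", P2 = "independent"),
    strains = c("P1", "P2", "P1_d2"))
  pr <- pr_for(scr)
  r <- reps_of(scr, pr)
  rf <- robustness_fragility(r$P1, r$P1_d2, r$P2)
  expect_gt(rf$r_after$mean_r, rf$r_before$mean_r)
  expect_equal(rf$verdict, "robust")

  # obligate-dimer collapse: P1 loses the shared targets
  scd <- make_paralog_scenario(sp, deletion_response = c(
    P1 = "dependent", P2 = "independent"),
    strains = c("P1", "P2", "P1_d2"))
  rd <- reps_of(scd, pr_for(scd))
  rf2 <- robustness_fragility(rd$P1, rd$P1_d2, rd$P2)
  expect_lt(rf2$r_after$mean_r, rf2$r_before$mean_r)
  expect_equal(rf2$verdict, "fragile")

  # unchanged deletion profile leaves the correlation unchanged
  rf3 <- robustness_fragility(rd$P1, rd$P1, rd$P2)
  expect_equal(rf3$r_after$mean_r, rf3$r_before$mean_r)
  expect_equal(rf3$verdict, "unchanged")

  # loss of specificity short-circuits the comparison
  rf4 <- robustness_fragility(rd$P1, rd$P1_d2, rd$P2,
                              loss_of_specificity = TRUE)
  expect_equal(rf4$verdict, "no_reliable_profile")
  expect_true(is.na(rf4$delta))
})
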