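test_that("global alignment matches the exhaustive DP oracle", {
  b62 <- paralobind:::get_subst_matrix("BLOSUM62")

  # identical sequences align without gaps at the diagonal score
  s <- "MKTAYIAKQR"
  al <- global_align(s, s)
  expect_equal(al$aligned_a, s)
  expect_equal(al$score,
               sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))

  # the classic textbook pair against the independent Gotoh oracle
  al2 <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(al2$score, oracle_align_score("HEAGAWGHEE", "PAWHEAE", b62))
  expect_equal(nchar(al2$aligned_a), nchar(al2$aligned_b))

  # property: score equals the oracle on random short peptides
  set.seed(61)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:12) {
    a <- paste(sample(aa, sample(4:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(4:12, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b, b62),
                 info = paste(a, b))
  }

  expect_error(global_align("", "PAW"), "nchar")
  expect_error(global_align("MKT", "PA3W"), "non-amino-acid")
})

test_that("conservation profiles smooth per-residue substitution scores", {
  # identical poly-A: constant at BLOSUM62(A, A) = 4
  polyA <- strrep("A", 60)
  pa <- conservation_profile(global_align(polyA, polyA))
  expect_equal(pa$score, rep(4, 60))

  # one central A->W substitution dips by (4 - (-3))/20 over 20 windows
  mutated <- paste0(strrep("A", 30), "W", strrep("A", 29))
  pm <- conservation_profile(global_align(polyA, mutated))
  expect_equal(sort(unique(round(pm$raw, 9))), c(-3, 4))
  interior <- pm$score[15:45]
  expect_equal(sort(unique(round(4 - interior, 9))), c(0, 7 / 20))
  expect_equal(sum(abs(interior - 4) > 1e-9), 20)

  # unrelated sequences score below the identity profile on average
  set.seed(71)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  r1 <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  r2 <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  unrelated <- conservation_profile(global_align(r1, r2))
  ident <- conservation_profile(global_align(r1, r1))
  expect_lt(mean(unrelated$score), mean(ident$score))

  # reference symmetry at identical aligned positions
  alAB <- global_align(r1, r2)
  pA <- conservation_profile(alAB, reference = "A")
  pB <- conservation_profile(alAB, reference = "B")
  gapless <- !grepl("-", alAB$aligned_a) && !grepl("-", alAB$aligned_b)
  if (gapless) expect_equal(pA$raw, pB$raw)
})

test_that("DBD residue classes follow the conservation and SR thresholds", {
  ann <- dbd_annotation("KRHD", "KRHE", conservation = c(10, 6, 4, 1))
  # conserved: score > 50% of max (5) -> first two positions
  expect_equal(as.character(ann$class),
               c("family_conserved", "family_conserved", "other", "other"))

  # equal SR scores never clear 150% of their mean
  ann2 <- dbd_annotation("KRHD", "KRHE", conservation = c(10, 6, 4, 1),
                         sr = c(100, 100, 100, 100))
  expect_false(any(ann2$class == "specificity_conferring"))

  # SR 300 vs mean 150: only position 1 is specificity-conferring, and
  # specificity takes precedence over family conservation
  ann3 <- dbd_annotation("KRHD", "KRHE", conservation = c(10, 6, 4, 1),
                         sr = c(300, 100, 100, 100))
  expect_equal(as.character(ann3$class)[1], "specificity_conferring")
  expect_equal(sum(ann3$class == "specificity_conferring"), 1)
})

test_that("substitution similarity uses the four biophysical classes", {
  expect_equal(substitution_similarity("K", "R"), "similar")    # both positive
  expect_equal(substitution_similarity("D", "K"), "dissimilar") # neg vs pos
  expect_equal(substitution_similarity("A", "A"), "identical")
  expect_equal(substitution_similarity("T", "Y"), "similar")    # hydrophilic
  expect_equal(substitution_similarity("W", "M"), "similar")    # hydrophobic
  expect_equal(substitution_similarity("G", "A"), "dissimilar") # Gly unassigned
  expect_equal(substitution_similarity("A", "-"), "dissimilar")
  # vectorized
  expect_equal(substitution_similarity(c("K", "D"), c("H", "E")),
               c("similar", "similar"))
  tab <- aa_class_table()
  expect_equal(length(tab), 19)
  expect_false("G" %in% names(tab))
})

test_that("DBD divergence fractions count substitutions per class", {
  ident <- dbd_annotation("KRHDE", "KRHDE", conservation = rep(10, 5),
                          sr = c(300, 100, 100, 100, 100))
  st <- dbd_divergence_stats(ident)
  expect_equal(st$frac_subs_all, 0)
  expect_equal(st$frac_subs_specificity, 0)

  # 2 substitutions among the 10 specificity positions -> 0.2
  a <- strrep("K", 40)
  b <- paste0("RR", strrep("K", 38))
  annA <- dbd_annotation(a, b, conservation = rep(10, 40),
                         sr = c(rep(300, 10), rep(0, 30)))
  expect_equal(sum(annA$class == "specificity_conferring"), 10)
  expect_equal(dbd_divergence_stats(annA)$frac_subs_specificity, 0.2)

  # constructed alignment with a known tally; gaps count as substitutions
  ann2 <- dbd_annotation("KD-AG", "RENAG", conservation = c(10, 10, 1, 1, 1),
                         sr = c(300, 300, 10, 10, 10))
  st2 <- dbd_divergence_stats(ann2)
  expect_equal(st2$frac_subs_all, 3 / 5)        # K>R, D>E, ->N
  expect_equal(st2$frac_subs_specificity, 1)    # both spec positions changed
  expect_equal(st2$n_similar, 2)                # K>R and D>E
  expect_equal(st2$n_dissimilar, 1)             # gap vs N

  expect_warning(res <- dbd_divergence_stats(
    dbd_annotation("KR", "KR", conservation = c(10, 1))),
    "no specificity")
  expect_true(is.na(res$frac_subs_specificity))
})

test_that("tree metrics calibrate to the pre-duplication species distance", {
  tm <- paralog_tree_metrics("((P1:0.2,P2:0.6):0.3,(CA:0.4,CB:0.6):0.1);",
                             "P1", "P2", "CA", "CB")
  expect_equal(tm$calibration_factor, 0.5)
  expect_equal(tm$D_P1, 0.4)
  expect_equal(tm$D_P2, 1.2)
  expect_equal(tm$delta_D, 0.8)
  expect_equal(tm$conserved_leaf, "P1")

  # calibration property: the mean calibration-leaf distance is one
  # after normalization, for an arbitrary tree
  set.seed(81)
  rt <- ape::rtree(8, tip.label = c("P1", "P2", "CA", "CB",
                                    paste0("o", 1:4)))
  tm2 <- paralog_tree_metrics(rt, "P1", "P2", "CA", "CB")
  d <- ape::dist.nodes(rt)
  lca <- ape::getMRCA(rt, match(c("CA", "CB"), rt$tip.label))
  norm_mean <- mean(d[lca, match(c("CA", "CB"), rt$tip.label)] /
                      tm2$calibration_factor)
  expect_equal(norm_mean, 1)

  # ultrametric symmetric tree: zero asymmetry
  tmu <- paralog_tree_metrics("((P1:0.3,P2:0.3):0.2,(CA:0.25,CB:0.25):0.25);",
                              "P1", "P2", "CA", "CB")
  expect_equal(tmu$delta_D, 0)

  # invariances: swapping calibration leaves or paralog leaves
  tswap <- paralog_tree_metrics("((P1:0.2,P2:0.6):0.3,(CA:0.4,CB:0.6):0.1);",
                                "P1", "P2", "CB", "CA")
  expect_equal(tswap$calibration_factor, tm$calibration_factor)
  pswap <- paralog_tree_metrics("((P1:0.2,P2:0.6):0.3,(CA:0.4,CB:0.6):0.1);",
                                "P2", "P1", "CA", "CB")
  expect_equal(pswap$delta_D, tm$delta_D)
  expect_equal(pswap$conserved_leaf, "P1")

  expect_error(paralog_tree_metrics("((P1:0.2,P2:0.6):0.3,(CA:0.4,CB:0.6):0.1);",
                                    "P1", "P2", "CA", "ZZ"), "not found")
  expect_error(paralog_tree_metrics("((P1:0,P2:0):0.3,(CA:0,CB:0):0.1);",
                                    "P1", "P2", "CA", "CB"),
               "zero calibration")
})

test_that("rate asymmetry on simulated families is recovered from the tree", {
  # paralogs evolved at rates 1 and 3 from their duplication node: the
  # calibrated distance ratio recovers the planted asymmetry
  nwk <- "((P1:0.05,P2:0.05):0.001,(CA:0.05,CB:0.05):0.001);"
  tmv <- paralog_tree_metrics(
    make_protein_family(nwk, rates = c(P1 = 1, P2 = 3),
                        dbd_interval = c(1, 10), seed = 91,
                        seq_length = 100)$true_tree,
    "P1", "P2", "CA", "CB")
  expect_equal(tmv$D_P2 / tmv$D_P1, 3, tolerance = 1e-9)

  # raw substitution counts against the direct ancestor (the root of a
  # two-leaf tree) at length 10,000
  fam <- make_protein_family("(P1:0.05,P2:0.05);",
                             rates = c(P1 = 1, P2 = 3),
                             dbd_interval = c(1, 50), seed = 91,
                             seq_length = 10050)
  root <- strsplit(fam$root_sequence, "")[[1]]
  mism <- vapply(c("P1", "P2"), function(lf) {
    s <- strsplit(as.character(fam$sequences[[lf]]), "")[[1]]
    sum(s[51:10050] != root[51:10050])
  }, numeric(1))
  expect_gt(mism[["P2"]] / mism[["P1"]], 2.5)
  expect_lt(mism[["P2"]] / mism[["P1"]], 3.5)
})
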