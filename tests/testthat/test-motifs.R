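delta_pwm <- function(bases, eps = 0) {
  # near-delta PWM over the given base string
  ch <- strsplit(bases, "")[[1]]
  m <- matrix(eps / 3, nrow = 4, ncol = length(ch),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) m[ch[j], j] <- 1 - eps
  m
}

test_that("PWM pairing minimizes correlation distance", {
  p1 <- delta_pwm("ACGTA", eps = 0.1)
  p2 <- delta_pwm("TTTTT", eps = 0.2)
  single <- choose_pwm_pair(list(p1), list(p2))
  expect_equal(single$i, 1)
  expect_equal(single$j, 1)

  # a duplicate of the other's PWM is the closest pair, distance 0
  res <- choose_pwm_pair(list(p1, p2), list(p2))
  expect_equal(res$i, 2)
  expect_equal(res$distance, 0, tolerance = 1e-12)

  # 2x2 candidates against a hand-enumerated argmin
  a1 <- delta_pwm("ACGTA", 0.05); a2 <- delta_pwm("GGGCC", 0.05)
  b1 <- delta_pwm("ACGTT", 0.05); b2 <- delta_pwm("CCCCC", 0.05)
  dist_hand <- function(x, y) {
    r <- -Inf
    for (off in (-(ncol(y) - 1)):(ncol(x) - 1)) {
      i0 <- max(1, 1 + off); i1 <- min(ncol(x), ncol(y) + off)
      if (i1 - i0 + 1 < 3) next
      r <- max(r, cor(as.vector(x[, i0:i1]),
                      as.vector(y[, (i0 - off):(i1 - off)])))
    }
    1 - r
  }
  d <- outer(1:2, 1:2, Vectorize(function(i, j)
    dist_hand(list(a1, a2)[[i]], list(b1, b2)[[j]])))
  best <- arrayInd(which.min(d), dim(d))
  res2 <- choose_pwm_pair(list(a1, a2), list(b1, b2))
  expect_equal(c(res2$i, res2$j), as.vector(best))
  expect_equal(res2$distance, min(d), tolerance = 1e-12)
})

test_that("PWM simplification keeps the five most informative positions", {
  # length-5 near-delta PWM: no N, pattern is the argmax string
  m5 <- delta_pwm("ACGTA")
  s5 <- simplify_pwm(m5)
  expect_equal(s5$pattern, "ACGTA")
  expect_equal(s5$informative_positions, 1:5)

  # length-7 with two uniform columns: exactly those become N
  m7 <- delta_pwm("ACGTACG", eps = 0.1)
  m7[, 3] <- 0.25; m7[, 6] <- 0.25
  s7 <- simplify_pwm(m7)
  expect_equal(substr(s7$pattern, 3, 3), "N")
  expect_equal(substr(s7$pattern, 6, 6), "N")
  expect_equal(sum(strsplit(s7$pattern, "")[[1]] != "N"), 5)

  # hand-computed information contents pick the right columns
  probs <- list(c(0.97, 0.01, 0.01, 0.01), c(0.7, 0.1, 0.1, 0.1),
                c(0.4, 0.2, 0.2, 0.2), c(0.85, 0.05, 0.05, 0.05),
                c(0.25, 0.25, 0.25, 0.25), c(0.9, 0.04, 0.03, 0.03),
                c(0.6, 0.2, 0.1, 0.1))
  m <- do.call(cbind, probs)
  rownames(m) <- c("A", "C", "G", "T")
  ic_hand <- vapply(probs, function(p) 2 + sum(p * log2(p)), numeric(1))
  s <- simplify_pwm(m)
  expect_equal(s$informative_positions, sort(order(-ic_hand)[1:5]))
  expect_equal(s$ic, ic_hand)

  expect_error(simplify_pwm(delta_pwm("ACG")), "at least 5")
  bad <- delta_pwm("ACGTA"); bad[1, 1] <- 0.5
  expect_error(simplify_pwm(bad), "sum to 1")
})

test_that("motif scanning finds planted occurrences and deduplicates palindromes", {
  sp <- small_scenario_spec(seed = 41)
  g <- make_genome(sp)
  pr <- define_promoters(g$annotation)
  occ <- scan_motif(g$genome, sp$motif, pr)
  expect_equal(nrow(occ), nrow(g$motifs))
  expect_true(all(occ$gene_id %in% g$annotation$gene_id))

  # absent motif
  none <- scan_motif(g$genome, "ACGTACGTACGTACG", pr)
  expect_equal(nrow(none), 0)

  # palindrome: plus and minus matches at one position collapse
  genome <- setNames(paste0(strrep("T", 30), "GAATTC", strrep("T", 30)),
                     "chrI")
  prom <- toy_promoters("g1", start = 0, end = 66)
  pal <- scan_motif(genome, "GAATTC", prom)
  expect_equal(nrow(pal), 1)
  expect_equal(pal$position, 30)

  # a match straddling the promoter boundary is rejected
  prom_short <- toy_promoters("g1", start = 0, end = 33)
  expect_equal(nrow(scan_motif(genome, "GAATTC", prom_short)), 0)
})

test_that("meta signal averages strand-oriented windows around occurrences", {
  occ1 <- data.frame(chrom = "chrI", position = 500, strand = "+",
                     gene_id = "g1")
  class(occ1) <- c("motif_occurrences", "data.frame")
  attr(occ1, "motif_length") <- 7L

  uni <- toy_track(rep(1, 1000), normalized = TRUE)
  m <- meta_signal(uni, occ1, window = 100)
  expect_equal(length(m), 201)
  expect_equal(as.numeric(m), rep(1, 201))

  v <- rep(0, 1000); v[504] <- 9  # 0-based 503 = center of the motif
  spike <- toy_track(v)
  m2 <- meta_signal(spike, occ1, window = 50)
  expect_equal(as.numeric(m2), c(rep(0, 50), 9, rep(0, 50)))

  # two occurrences with spikes at +10 and -10 average symmetrically
  occ2 <- rbind(occ1, transform(occ1, position = 700))
  class(occ2) <- c("motif_occurrences", "data.frame")
  attr(occ2, "motif_length") <- 7L
  v2 <- rep(0, 1000); v2[504 + 10] <- 4; v2[704 - 10] <- 4
  m3 <- meta_signal(toy_track(v2), occ2, window = 30)
  expect_equal(as.numeric(m3), rev(as.numeric(m3)))
  expect_equal(m3[[31 + 10]], 2)
  expect_equal(m3[[31 - 10]], 2)

  # minus-strand occurrences are orientation-flipped
  occm <- transform(occ1, strand = "-")
  class(occm) <- c("motif_occurrences", "data.frame")
  attr(occm, "motif_length") <- 7L
  v3 <- rep(0, 1000); v3[504 + 20] <- 5
  mp <- meta_signal(toy_track(v3), occ1, window = 30)
  mm <- meta_signal(toy_track(v3), occm, window = 30)
  expect_equal(as.numeric(mm), rev(as.numeric(mp)))

  # edge occurrences are dropped and reported
  occ_edge <- rbind(occ1, transform(occ1, position = 2))
  class(occ_edge) <- c("motif_occurrences", "data.frame")
  attr(occ_edge, "motif_length") <- 7L
  me <- meta_signal(uni, occ_edge, window = 100)
  expect_equal(attr(me, "n_dropped"), 1L)
  expect_error(meta_signal(uni, occ1[0, ]), "no motif occurrences")
})

test_that("percent of promoter signal near motifs is a windowed ratio", {
  prom <- toy_promoters("g1", start = 100, end = 800)
  occ <- data.frame(chrom = "chrI", position = 400 - 3, strand = "+",
                    gene_id = "g1")
  class(occ) <- c("motif_occurrences", "data.frame")
  attr(occ, "motif_length") <- 7L

  # all signal inside the +/-50 window around the occurrence center
  v <- rep(0, 1000); v[(400 - 20):(400 + 20)] <- 2
  expect_equal(pct_signal_near_motifs(toy_track(v), prom, occ), 100)

  # constructed half split: equal mass inside and outside the window
  v2 <- rep(0, 1000); v2[400] <- 6; v2[700] <- 6
  expect_equal(pct_signal_near_motifs(toy_track(v2), prom, occ), 50)

  # no occurrences inside the chosen subset genes
  v3 <- rep(1, 1000)
  occ_none <- occ[0, ]
  class(occ_none) <- c("motif_occurrences", "data.frame")
  attr(occ_none, "motif_length") <- 7L
  expect_equal(pct_signal_near_motifs(toy_track(v3), prom, occ_none,
                                      genes = "g1"), 0)

  # zero promoter signal is flagged undefined
  expect_warning(res <- pct_signal_near_motifs(toy_track(rep(0, 1000)),
                                               prom, occ), "no signal")
  expect_true(is.nan(res))

  # overlapping windows are counted once
  occ2 <- rbind(occ, transform(occ, position = 410 - 3))
  class(occ2) <- c("motif_occurrences", "data.frame")
  attr(occ2, "motif_length") <- 7L
  expect_equal(pct_signal_near_motifs(toy_track(v2), prom, occ2), 50)
})
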