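# Independent oracles: deliberately naive reimplementations used only to
# check the package's fast paths on small inputs.

# Gotoh affine-gap global alignment, score only; a gap of length L costs
# gap_open + L * gap_ext
oracle_align_score <- function(a, b, subst, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- subst[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# iteratively-reweighted least squares with bisquare weights and a
# MAD-about-zero scale, as in classic robust regression
oracle_irls_slope <- function(x, y, cc = 4.685, iters = 60) {
  w <- rep(1, length(x))
  slope <- NA_real_
  for (k in seq_len(iters)) {
    fit <- stats::lm(y ~ x, weights = w)
    slope <- unname(stats::coef(fit)[2])
    r <- stats::resid(fit)
    s <- max(stats::mad(r, center = 0), 1e-8)
    u <- r / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  slope
}

# canonical 7-mer index, computed by string/arithmetic means independent
# of the package's lookup table
oracle_kmer_universe <- local({
  u <- NULL
  function() {
    if (!is.null(u)) return(u)
    enc <- function(ch) {
      v <- match(ch, c("A", "C", "G", "T")) - 1
      sum(v * 4^(6:0))
    }
    combos <- expand.grid(rep(list(c("A", "C", "G", "T")), 7),
                          stringsAsFactors = FALSE)[, 7:1]
    codes <- apply(combos, 1, enc)
    rc_codes <- apply(combos, 1, function(ch)
      enc(rev(chartr("ACGT", "TGCA", ch))))
    u <<- sort(unique(pmin(codes, rc_codes)))
    u
  }
})

oracle_kmer_index <- function(kmer) {
  ch <- strsplit(kmer, "")[[1]]
  enc <- function(x) sum((match(x, c("A", "C", "G", "T")) - 1) * 4^(6:0))
  code <- min(enc(ch), enc(rev(chartr("ACGT", "TGCA", ch))))
  match(code, oracle_kmer_universe()) - 1L
}

# literal per-position reimplementation of the 7-mer scoring on a single
# chromosome
oracle_kmer_scores <- function(values, seq_chars, prom) {
  L <- length(values)
  sums <- numeric(8192); counts <- numeric(8192)
  in_prom <- function(p0) {  # 0-based position
    any(prom$start <= p0 & p0 < prom$end)
  }
  for (p in 11:(L - 10)) {
    if (!in_prom(p - 1)) next
    kmer <- paste(seq_chars[(p - 3):(p + 3)], collapse = "")
    if (grepl("[^ACGT]", kmer)) next
    f <- mean(values[(p - 10):(p + 10)]) - mean(values[(p - 3):(p + 3)])
    f <- max(f, 0)
    i <- oracle_kmer_index(kmer) + 1L
    sums[i] <- sums[i] + f
    counts[i] <- counts[i] + 1
  }
  ifelse(counts > 0, sums / counts, 0)
}
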