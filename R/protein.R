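#' Global protein alignment under BLOSUM62 with affine gaps
#'
#' Needleman-Wunsch global alignment; a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param seq_a,seq_b protein sequences (character strings, standard
#'   amino-acid alphabet).
#' @param matrix substitution matrix name (default `"BLOSUM62"`) or a
#'   numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1,
#'   the standard BLOSUM62 pairing).
#' @return Object of class `protein_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, and the substitution
#'   matrix used.
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  aa_ok <- "^[ACDEFGHIKLMNPQRSTVWYBZX*]+$"
  if (!grepl(aa_ok, toupper(seq_a)) || !grepl(aa_ok, toupper(seq_b)))
    stop("non-amino-acid character in input sequence")
  subst <- if (is.character(matrix)) get_subst_matrix(matrix) else matrix
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    substitutionMatrix = subst, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  structure(list(aligned_a = as.character(Biostrings::pattern(pa)),
                 aligned_b = as.character(Biostrings::subject(pa)),
                 score = Biostrings::score(pa),
                 matrix = subst, matrix_id = if (is.character(matrix)) matrix
                                             else "custom"),
            class = "protein_alignment")
}

get_subst_matrix <- function(name) {
  key <- paste0("subst_", name)
  if (!is.null(.pb_cache[[key]])) return(.pb_cache[[key]])
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  .pb_cache[[key]] <- get(name, envir = env)
  .pb_cache[[key]]
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment (%s, score %.0f):\n  %s\n  %s\n",
              x$matrix_id, x$score, x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Per-residue conservation profile of an aligned pair
#'
#' Each reference residue receives its pairwise substitution score
#' (residues aligned to a gap receive the matrix minimum), mapped back
#' onto the ungapped reference sequence and smoothed with a centered
#' `window`-residue moving average (truncated at the edges).
#'
#' @param alignment a [global_align()] result.
#' @param reference `"A"` or `"B"`: which sequence indexes the profile.
#' @param window moving-average width in residues (default 20).
#' @return Object of class `conservation_profile`: `score` (smoothed, one
#'   value per reference residue), `raw` (unsmoothed), `window`,
#'   `matrix_id`.
#' @export
conservation_profile <- function(alignment, reference = c("A", "B"),
                                 window = 20) {
  stopifnot(inherits(alignment, "protein_alignment"))
  reference <- match.arg(reference)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (reference == "B") { tmp <- a; a <- b; b <- tmp }
  subst <- alignment$matrix
  aa <- intersect(rownames(subst), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  min_score <- min(subst[aa, aa])
  ref_pos <- a != "-"
  raw <- vapply(which(ref_pos), function(i) {
    if (b[i] == "-") min_score else subst[a[i], b[i]]
  }, numeric(1))
  n <- length(raw)
  half_lo <- window %/% 2
  half_hi <- window - half_lo - 1L
  smooth <- vapply(seq_len(n), function(i) {
    mean(raw[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
  structure(list(score = smooth, raw = raw, window = window,
                 matrix_id = alignment$matrix_id),
            class = "conservation_profile")
}

#' Amino-acid biophysical classes
#'
#' Positively charged (K, R, H), negatively charged (D, E), hydrophilic
#' (T, S, N, Q, C, Y) and hydrophobic (A, W, V, I, L, P, F, M); glycine
#' belongs to none of the four classes and is treated as always
#' dissimilar to other residues.
#'
#' @return Named character vector mapping 19 amino acids to their class.
#' @export
aa_class_table <- function() {
  c(K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    T = "hydrophilic", S = "hydrophilic", N = "hydrophilic",
    Q = "hydrophilic", C = "hydrophilic", Y = "hydrophilic",
    A = "hydrophobic", W = "hydrophobic", V = "hydrophobic",
    I = "hydrophobic", L = "hydrophobic", P = "hydrophobic",
    F = "hydrophobic", M = "hydrophobic")
}

#' Similarity category of an amino-acid substitution
#'
#' `identical` if the residues are equal, `similar` if they share a
#' biophysical class, `dissimilar` otherwise. Pairings involving glycine
#' (unassigned) or a gap are dissimilar.
#'
#' @param aa1,aa2 single-letter amino acids (vectorized).
#' @return Character vector over
#'   `{"identical", "similar", "dissimilar"}`.
#' @export
substitution_similarity <- function(aa1, aa2) {
  tab <- aa_class_table()
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  out <- rep("dissimilar", length(aa1))
  same <- aa1 == aa2 & aa1 != "-"
  out[same] <- "identical"
  c1 <- tab[aa1]; c2 <- tab[aa2]
  sim <- !same & !is.na(c1) & !is.na(c2) & c1 == c2
  out[sim] <- "similar"
  out
}

#' Annotate an aligned DBD pair with residue classes
#'
#' Positions with conservation score above 50% of the maximum are
#' `family_conserved`; positions with a similarity-regression (SR) score
#' above 150% of the mean SR are `specificity_conferring` (this class
#' takes precedence where both rules fire, so the classes partition the
#' positions); everything else is `other`. Without SR scores (families
#' outside the SR analysis) only `family_conserved`/`other` are
#' assigned.
#'
#' @param seq_a,seq_b aligned (gapped) DBD sequences of equal length.
#' @param conservation per-position conservation scores.
#' @param sr optional per-position specificity (SR) scores.
#' @return Object of class `dbd_annotation` with `class` (factor per
#'   position), the inputs, and the thresholds used.
#' @export
dbd_annotation <- function(seq_a, seq_b, conservation, sr = NULL) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) == length(b), length(conservation) == length(a))
  if (!is.null(sr)) stopifnot(length(sr) == length(a))
  cons_thr <- 0.5 * max(conservation)
  conserved <- conservation > cons_thr
  if (!is.null(sr)) {
    sr_thr <- 1.5 * mean(sr)
    specific <- sr > sr_thr
  } else {
    sr_thr <- NA_real_
    specific <- rep(FALSE, length(a))
  }
  cls <- ifelse(specific, "specificity_conferring",
                ifelse(conserved, "family_conserved", "other"))
  structure(list(seq_a = a, seq_b = b, conservation = conservation,
                 sr = sr, class = factor(cls, levels = c(
                   "family_conserved", "specificity_conferring", "other")),
                 cons_threshold = cons_thr, sr_threshold = sr_thr),
            class = "dbd_annotation")
}

#' Substitution statistics of a DBD alignment
#'
#' Fraction of non-identical positions over the specificity-conferring
#' positions and over all aligned positions (gap columns count as
#' substitutions), plus similar/dissimilar counts among the
#' substitutions.
#'
#' @param annotation a [dbd_annotation()] result.
#' @return List with `frac_subs_specificity` (`NA` with a warning when no
#'   specificity positions exist), `frac_subs_all`, `n_similar`,
#'   `n_dissimilar`.
#' @export
dbd_divergence_stats <- function(annotation) {
  stopifnot(inherits(annotation, "dbd_annotation"))
  a <- annotation$seq_a; b <- annotation$seq_b
  subs <- a != b | a == "-" | b == "-"
  spec <- annotation$class == "specificity_conferring"
  frac_spec <- if (any(spec)) mean(subs[spec]) else {
    warning("no specificity-conferring positions; fraction undefined")
    NA_real_
  }
  simcat <- substitution_similarity(a[subs], b[subs])
  list(frac_subs_specificity = frac_spec,
       frac_subs_all = mean(subs),
       n_similar = sum(simcat == "similar"),
       n_dissimilar = sum(simcat == "dissimilar"))
}
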