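#' Simulate a protein family on a known tree with a slow DBD segment
#'
#' Evolves a random root sequence along a given tree by per-site
#' substitution (JTT exchangeabilities via [phangorn::simSeq()]), with
#' expected substitutions proportional to branch length times a
#' per-branch rate. The designated DNA-binding-domain segment evolves at
#' a reduced rate, mimicking the stronger purifying selection on DBDs.
#' The rate-scaled tree is the ground truth for distance-based
#' asymmetry analyses.
#'
#' @param tree an `ape` `phylo` object or a Newick string; branch
#'   lengths in expected substitutions per site (at rate 1).
#' @param rates branch rate multipliers: a scalar, a vector along
#'   `tree$edge` rows, or a named vector by tip label (terminal branches
#'   only; others default to 1).
#' @param dbd_interval integer `c(start, end)` of the DBD segment
#'   (1-based, inclusive) within the sequence.
#' @param seed integer seed.
#' @param seq_length total sequence length in residues.
#' @param dbd_rate_factor rate multiplier of the DBD segment (default
#'   0.2).
#' @return List with `sequences` (`AAStringSet`, one per leaf),
#'   `root_sequence`, `dbd_interval`, `true_tree` (rate-scaled `phylo`
#'   for the non-DBD part), `true_branch_distances` (expected root-to-
#'   leaf substitutions per non-DBD site) and `true_pairwise` (expected
#'   pairwise distances).
#' @export
make_protein_family <- function(tree, rates = 1, dbd_interval = c(201, 280),
                                seed = 1, seq_length = 500,
                                dbd_rate_factor = 0.2) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  stopifnot(length(dbd_interval) == 2, dbd_interval[1] >= 1,
            dbd_interval[2] <= seq_length,
            dbd_interval[2] >= dbd_interval[1])

  n_edge <- nrow(phy$edge)
  if (!is.null(names(rates))) {
    rv <- rep(1, n_edge)
    tip_edges <- match(seq_along(phy$tip.label), phy$edge[, 2])
    for (nm in names(rates)) {
      k <- which(phy$tip.label == nm)
      if (!length(k)) stop("rate given for unknown leaf: ", nm)
      rv[tip_edges[k]] <- rates[[nm]]
    }
  } else if (length(rates) == 1) {
    rv <- rep(rates, n_edge)
  } else if (length(rates) == n_edge) {
    rv <- as.numeric(rates)
  } else {
    stop("rates must be a scalar, named by tip, or one value per edge")
  }
  if (any(rv < 0)) stop("negative rate")

  scaled <- phy
  scaled$edge.length <- phy$edge.length * rv
  dbd_tree <- scaled
  dbd_tree$edge.length <- scaled$edge.length * dbd_rate_factor

  set.seed(substream_seed(seed, "protein"))
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  root <- sample(aa, seq_length, replace = TRUE)
  d0 <- dbd_interval[1]; d1 <- dbd_interval[2]
  dbd_sites <- seq(d0, d1)
  non_sites <- setdiff(seq_len(seq_length), dbd_sites)

  sim_segment <- function(tr, rootseq) {
    if (!length(rootseq)) return(NULL)
    s <- phangorn::simSeq(tr, l = length(rootseq), rootseq = rootseq,
                          type = "AA", model = "JTT")
    m <- as.character(s)  # tips x sites matrix of AA letters
    toupper(m)
  }
  m_non <- sim_segment(scaled, root[non_sites])
  m_dbd <- sim_segment(dbd_tree, root[dbd_sites])

  leaves <- phy$tip.label
  seqs <- vapply(leaves, function(lf) {
    full <- character(seq_length)
    if (!is.null(m_non)) full[non_sites] <- m_non[lf, ]
    if (!is.null(m_dbd)) full[dbd_sites] <- m_dbd[lf, ]
    paste(full, collapse = "")
  }, character(1))

  node_depths <- function(tr) {
    # path length from the root to every leaf
    d <- ape::dist.nodes(tr)
    rt <- length(tr$tip.label) + 1L
    setNames(d[rt, seq_along(tr$tip.label)], tr$tip.label)
  }
  list(sequences = Biostrings::AAStringSet(seqs),
       root_sequence = paste(root, collapse = ""),
       dbd_interval = dbd_interval,
       true_tree = scaled,
       true_branch_distances = node_depths(scaled),
       true_pairwise = ape::cophenetic.phylo(scaled))
}
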