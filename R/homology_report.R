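#' Extract region sequences from a cluster
#'
#' Minus-strand regions are reverse-complemented; `frame_offset` trims
#' leading bases so the returned sequence starts in frame 0.
#'
#' @param cluster A `gene_cluster`.
#' @param regions Region annotation data frame.
#' @return Named character vector of nucleotide sequences.
#' @export
region_sequences <- function(cluster, regions) {
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    s <- substring(cluster$seq, regions$start[i] + 1L, regions$end[i])
    if (regions$strand[i] == "-") s <- revcomp(s)
    fo <- regions$frame_offset[i]
    if (fo > 0) s <- substring(s, fo + 1L)
    s
  }, character(1))
  setNames(seqs, regions$name)
}

#' All-vs-all identity matrix over regions
#'
#' Pairwise global alignment between every pair of region sequences, at
#' the nucleotide level (scan scoring: match +5 / mismatch -4 / gap
#' open -10 / extend -0.5) or at the amino-acid level (BLOSUM62, gap
#' open -11 / extend -1, after in-frame translation). Identity is
#' `100 * identical columns / alignment length`, the alignment length
#' including gap columns.
#'
#' @param regions Region annotation data frame with unique names.
#' @param cluster A `gene_cluster`.
#' @param level `"nt"` or `"aa"`.
#' @return Symmetric percent matrix with diagonal exactly 100, region
#'   names as dimnames and attribute `level`.
#' @export
identity_matrix <- function(regions, cluster, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (anyDuplicated(regions$name))
    stop("duplicate region name: ", regions$name[duplicated(regions$name)][1])
  seqs <- region_sequences(cluster, regions)
  if (level == "aa") {
    seqs <- vapply(names(seqs), function(nm)
      translate_orf(seqs[[nm]], nm), character(1))
    sub <- aa_submat(); go <- AA_GAP_OPEN; ge <- AA_GAP_EXT; excl <- FALSE
  } else {
    sub <- nt_submat(); go <- NT_GAP_OPEN; ge <- NT_GAP_EXT; excl <- TRUE
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    pairs <- t(utils::combn(seq_len(n), 2L))
    ids <- pair_identities_cpp(unname(seqs), pairs, sub, go, ge, excl)
    for (p in seq_len(nrow(pairs)))
      m[pairs[p, 1], pairs[p, 2]] <- m[pairs[p, 2], pairs[p, 1]] <- ids[p]
  }
  attr(m, "level") <- level
  m
}

#' Rank the most similar region pairs
#'
#' Off-diagonal entries of an identity matrix ranked descending, each
#' unordered pair reported once; ties are ordered lexicographically by
#' label.
#'
#' @param m An [identity_matrix()].
#' @param k Number of pairs to return.
#' @return Data frame `a`, `b`, `identity`, ranked.
#' @export
top_homolog_pairs <- function(m, k = 5L) {
  stopifnot(k >= 1)
  labels <- rownames(m)
  n <- length(labels)
  if (n < 2) stop("need at least 2 regions")
  pairs <- t(utils::combn(seq_len(n), 2L))
  df <- data.frame(a = labels[pairs[, 1]], b = labels[pairs[, 2]],
                   identity = m[pairs], stringsAsFactors = FALSE)
  df <- df[order(-df$identity, df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  head(df, k)
}

#' Flag truncated domains within one domain class
#'
#' The reference length of the class is the median amino-acid length
#' (an order statistic, so a single extreme member cannot drag it); a
#' domain is flagged when `reference - length >= delta_min` residues.
#'
#' @param aa_lengths Named numeric vector of amino-acid lengths for all
#'   domains of one class (at least 2).
#' @param domain_class Class label carried through to the report.
#' @param delta_min Minimum deficit in residues to flag.
#' @return Data frame `name`, `domain_class`, `aa_length`,
#'   `reference_length`, `deficit`, `flagged`; empty (with a warning)
#'   when fewer than 2 domains are given.
#' @examples
#' flag_truncated(c(KR_1 = 450, KR_2 = 452, KR_3 = 400), delta_min = 40)
#' @export
flag_truncated <- function(aa_lengths, domain_class = "KR", delta_min = 40) {
  empty <- data.frame(name = character(), domain_class = character(),
                      aa_length = numeric(), reference_length = numeric(),
                      deficit = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  if (length(aa_lengths) < 2) {
    warning("fewer than 2 domains of class ", domain_class,
            ": no reference length exists")
    return(empty)
  }
  stopifnot(!is.null(names(aa_lengths)), all(nzchar(names(aa_lengths))))
  ref <- median(aa_lengths)
  deficit <- ref - aa_lengths
  data.frame(name = names(aa_lengths), domain_class = domain_class,
             aa_length = unname(aa_lengths), reference_length = ref,
             deficit = unname(deficit),
             flagged = unname(deficit >= delta_min),
             stringsAsFactors = FALSE, row.names = NULL)
}
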