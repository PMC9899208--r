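#' Codon-aware pairwise alignment of two coding sequences
#'
#' Aligns the translated amino-acid sequences globally (BLOSUM62,
#' gap open -11 / extend -1) and expands each amino-acid column back to
#' its source codon, so every gap in the returned nucleotide alignment has
#' a length divisible by 3 and the reading frame is preserved.
#'
#' @param nt_a,nt_b Coding nucleotide strings, length divisible by 3,
#'   translatable in frame 0 without internal stop codons.
#' @param label_a,label_b Sequence labels.
#' @return An `aligned_pair`: list with `label_a`, `label_b`, `cols_a`,
#'   `cols_b` (aligned nucleotide strings with `-` gaps) and
#'   `comparable_sites` (columns with no gap and no `N` in either row).
#' @export
codon_align_pair <- function(nt_a, nt_b, label_a = "a", label_b = "b") {
  aa_a <- translate_orf(nt_a, label_a)
  aa_b <- translate_orf(nt_b, label_b)
  aln <- nw_align_cpp(aa_a, aa_b, aa_submat(), AA_GAP_OPEN, AA_GAP_EXT)
  cols_a <- expand_codons(aln$aligned_a, nt_a)
  cols_b <- expand_codons(aln$aligned_b, nt_b)
  aligned_pair(cols_a, cols_b, label_a, label_b)
}

translate_orf <- function(nt, label = "sequence") {
  stopifnot(is.character(nt), length(nt) == 1)
  nt <- normalize_nt(nt, label)
  if (nchar(nt) %% 3 != 0)
    stop(label, ": length not divisible by 3")
  if (nchar(nt) == 0) stop(label, ": empty sequence")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  body <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("*", body, fixed = TRUE))
    stop(label, ": internal stop codon")
  aa
}

expand_codons <- function(aa_aligned, nt) {
  chars <- strsplit(aa_aligned, "", fixed = TRUE)[[1L]]
  codons <- character(length(chars))
  pos <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "-") {
      codons[k] <- "---"
    } else {
      codons[k] <- substr(nt, 3L * pos + 1L, 3L * pos + 3L)
      pos <- pos + 1L
    }
  }
  paste(codons, collapse = "")
}

#' Construct an aligned pair from pre-aligned rows
#'
#' @param cols_a,cols_b Equal-length aligned strings with `-` gaps.
#' @param label_a,label_b Sequence labels.
#' @return An `aligned_pair` object.
#' @export
aligned_pair <- function(cols_a, cols_b, label_a = "a", label_b = "b") {
  if (nchar(cols_a) != nchar(cols_b))
    stop("aligned rows differ in column count")
  ca <- strsplit(cols_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(cols_b, "", fixed = TRUE)[[1L]]
  comparable <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  structure(list(label_a = label_a, label_b = label_b,
                 cols_a = cols_a, cols_b = cols_b,
                 comparable_sites = sum(comparable)),
            class = "aligned_pair")
}

#' Raw mismatch proportion (p-distance) of an aligned pair
#'
#' Differing comparable sites over comparable sites, where a comparable
#' site is a column with no gap and no `N` in either row (pairwise
#' deletion).
#'
#' @param pair An `aligned_pair`.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  if (pair$comparable_sites == 0)
    stop("no comparable sites between ", pair$label_a, " and ", pair$label_b)
  ca <- strsplit(pair$cols_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(pair$cols_b, "", fixed = TRUE)[[1L]]
  comparable <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  sum(ca[comparable] != cb[comparable]) / sum(comparable)
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`, the expected substitutions per site
#' under the Jukes-Cantor model. Strictly increasing in `p`, with
#' `d >= p`. At `p >= 3/4` the model is saturated; this raises an error
#' unless `cap = TRUE`, in which case the distance is replaced by 5.0.
#'
#' @param p Mismatch proportion(s) in `[0, 0.75)`.
#' @param cap Replace saturated distances with 5.0 instead of erroring.
#' @return Distance(s) in substitutions/site.
#' @examples
#' jc_distance(0.3)  # -0.75 * log(0.6)
#' @export
jc_distance <- function(p, cap = FALSE) {
  stopifnot(is.numeric(p), all(p >= 0), all(p <= 1))
  sat <- p >= 0.75
  if (any(sat) && !cap)
    stop("saturated p-distance (p >= 0.75): Jukes-Cantor distance undefined")
  d <- ifelse(sat, 5.0, -0.75 * log(pmax(1 - (4 / 3) * p, .Machine$double.xmin)))
  pmax(d, 0)
}

#' Jukes-Cantor distance matrix for a set of coding sequences
#'
#' With `method = "codon"` every pair is aligned by [codon_align_pair()];
#' with `method = "aligned"` the inputs are rows of one alignment (equal
#' lengths; gaps `-` allowed) and each pair is compared by slicing the
#' given columns (pairwise deletion).
#'
#' @param seqs Named character vector of nucleotide sequences (n >= 2).
#' @param method `"codon"` or `"aligned"`.
#' @param cap Passed to [jc_distance()].
#' @return Symmetric distance matrix (substitutions/site) with the
#'   sequence names as dimnames.
#' @export
dist_jc <- function(seqs, method = c("codon", "aligned"), cap = FALSE) {
  method <- match.arg(method)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence label: ", names(seqs)[duplicated(names(seqs))][1])
  if (method == "aligned" && length(unique(nchar(seqs))) != 1)
    stop("method 'aligned' requires equal-length rows of one alignment")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pair <- if (method == "codon") {
        codon_align_pair(seqs[[i]], seqs[[j]], names(seqs)[i], names(seqs)[j])
      } else {
        aligned_pair(seqs[[i]], seqs[[j]], names(seqs)[i], names(seqs)[j])
      }
      p <- p_distance(pair)
      d <- tryCatch(jc_distance(p, cap = cap), error = function(e)
        stop("pair (", names(seqs)[i], ", ", names(seqs)[j], "): ",
             conditionMessage(e), call. = FALSE))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined (ties
#' broken toward the lowest label indices), branch lengths follow the
#' standard formulas with negative lengths clamped to zero, and distances
#' to the new node are `(d(i,k) + d(j,k) - d(i,j)) / 2`. The result is an
#' unrooted tree (trifurcating root node in the `phylo` encoding); on an
#' additive matrix it reproduces the generating tree exactly.
#'
#' @param D Symmetric distance matrix with zero diagonal, finite entries
#'   and unique row/column labels (n >= 2).
#' @return An [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must carry labels as dimnames")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (n < 2) stop("need at least 2 sequences")
  if (!all(is.finite(D))) stop("non-finite distances")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")

  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = rep(max(D[1, 2], 0) / 2, 2),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }

  ids <- seq_len(n)            # current node ids (tips 1..n, then internal)
  d <- D
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  next_id <- n + 1L
  n_internal <- 0L

  while (length(ids) > 3) {
    m <- length(ids)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_id <- next_id; next_id <- next_id + 1L; n_internal <- n_internal + 1L
    parent <- c(parent, new_id, new_id)
    child <- c(child, ids[i], ids[j])
    blen <- c(blen, max(li, 0), max(lj, 0))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    ids <- c(ids[keep], new_id)
  }

  # final three nodes joined at one internal vertex (three-point formulas)
  new_id <- next_id; n_internal <- n_internal + 1L
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  parent <- c(parent, new_id, new_id, new_id)
  child <- c(child, ids[1], ids[2], ids[3])
  blen <- c(blen, max(l1, 0), max(l2, 0), max(l3, 0))

  # renumber internal nodes so the last-created (central) node is n+1,
  # as the phylo convention expects for the root
  internal_old <- seq(n + 1L, n + n_internal)
  internal_new <- setNames(n + rev(seq_len(n_internal)), internal_old)
  remap <- function(v) ifelse(v > n, internal_new[as.character(v)], v)
  tree <- list(edge = cbind(as.integer(remap(parent)),
                            as.integer(remap(child))),
               edge.length = blen, tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Are two leaves a cherry (sister pair)?
#'
#' True iff the two leaves are adjacent to the same internal vertex of the
#' unrooted tree.
#'
#' @param tree An [ape::phylo] tree.
#' @param a,b Leaf labels.
#' @return Logical flag.
#' @export
is_sister_pair <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown leaf label: ", a)
  if (is.na(ib)) stop("unknown leaf label: ", b)
  if (ia == ib) stop("the two labels are identical")
  pa <- tree$edge[tree$edge[, 2] == ia, 1]
  pb <- tree$edge[tree$edge[, 2] == ib, 1]
  pa == pb
}

#' Does a single edge separate two leaf classes?
#'
#' True iff some edge of the unrooted tree induces exactly the bipartition
#' `class1 | class2` of the leaves.
#'
#' @param tree An [ape::phylo] tree.
#' @param label_map Named character vector (or factor) mapping every leaf
#'   label to one of exactly two classes.
#' @return Logical flag.
#' @export
split_consistent <- function(tree, label_map) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(label_map))
  if (length(missing)) stop("leaf missing from label_map: ", missing[1])
  classes <- as.character(label_map[tips])
  uc <- unique(classes)
  if (length(uc) != 2) stop("label_map must define exactly two non-empty classes")
  class1 <- which(classes == uc[1])
  ntip <- length(tips)
  # tip sets below each edge: tip edges give singletons, internal edges
  # give the clade of the child node
  tipsets <- lapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) ch else
      which(tips %in% ape::extract.clade(tree, ch)$tip.label)
  })
  target <- sort(class1)
  complement <- sort(setdiff(seq_len(ntip), class1))
  for (s in tipsets) {
    s <- sort(s)
    if (identical(s, target) || identical(s, complement)) return(TRUE)
  }
  FALSE
}
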