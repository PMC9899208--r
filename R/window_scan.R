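#' Parameters for the sliding-window duplication scan
#'
#' Defaults are the reference parameterization of the scan: 150-nt windows
#' advanced in 30-nt steps, duplicated regions defined as stretches of at
#' least 500 bp whose 5-window sliding mean of best intra-cluster identity
#' exceeds 80%.
#'
#' @param win_len Window (fragment) length in bp.
#' @param step Step between window starts in bp (`0 < step <= win_len`).
#' @param id_min Identity threshold in percent; the sliding mean must
#'   strictly exceed it.
#' @param run Number of adjacent windows averaged (centered sliding mean;
#'   truncated at the profile edges).
#' @param min_region Minimum span (bp) of a reported duplicated region.
#' @param min_separation Extra separation (bp) required between a window
#'   and an eligible partner beyond non-overlap. The default 0 admits any
#'   non-overlapping partner; adjacent windows share `win_len - step` bp of
#'   sequence, so `min_separation = win_len` is recommended for real scans
#'   when near-diagonal self-similarity should be ignored.
#' @param revcomp Also compare each window against the reverse complement
#'   of its partners (inverted repeats). Off by default.
#' @param fast Use exact ungapped (Hamming) identity instead of gapped
#'   global alignment. Fast and appropriate for substitution-dominated
#'   duplications.
#' @param exhaustive Align every eligible pair instead of only pairs
#'   sharing at least one k-mer. The k-mer prefilter cannot demote a
#'   near-threshold pair in practice; exhaustive mode exists to verify
#'   that on moderate inputs.
#' @param kmer Word size of the shared-k-mer prefilter.
#' @return A `scan_params` object.
#' @export
scan_params <- function(win_len = 150L, step = 30L, id_min = 80,
                        run = 5L, min_region = 500L, min_separation = 0L,
                        revcomp = FALSE, fast = FALSE, exhaustive = FALSE,
                        kmer = 12L) {
  win_len <- as.integer(win_len); step <- as.integer(step)
  run <- as.integer(run); min_region <- as.integer(min_region)
  min_separation <- as.integer(min_separation); kmer <- as.integer(kmer)
  stopifnot(win_len > 0, step > 0, step <= win_len,
            id_min > 0, id_min <= 100, run >= 1,
            min_region >= win_len, min_separation >= 0, kmer > 0)
  structure(list(win_len = win_len, step = step, id_min = id_min, run = run,
                 min_region = min_region, min_separation = min_separation,
                 revcomp = isTRUE(revcomp), fast = isTRUE(fast),
                 exhaustive = isTRUE(exhaustive), kmer = kmer),
            class = "scan_params")
}

#' Segment a cluster into scan windows
#'
#' Windows start at `0, step, 2*step, ...`; only full-length windows are
#' kept, so a cluster shorter than `win_len` yields zero windows and the
#' window count is `floor((L - win_len)/step) + 1` otherwise.
#'
#' @param cluster A `gene_cluster`.
#' @param params A [scan_params()] object.
#' @return Data frame with columns `index` (1-based ordinal), `start`,
#'   `end` (0-based half-open bp).
#' @export
segment_windows <- function(cluster, params = scan_params()) {
  L <- cluster$length
  n <- if (L >= params$win_len) (L - params$win_len) %/% params$step + 1L else 0L
  idx <- seq_len(n)
  data.frame(index = idx, start = (idx - 1L) * params$step,
             end = (idx - 1L) * params$step + params$win_len)
}

window_seqs <- function(cluster, windows) {
  substring(cluster$seq, windows$start + 1L, windows$end)
}

#' Percent identity of two fragments under global alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gaps, scored
#' match +5 / mismatch -4 / gap open -10 / gap extend -0.5. Identity is
#' `100 * identical aligned columns / alignment length` (gap columns count
#' in the denominator, never as identities); `N` never counts as a match.
#' Under this scoring, substitution-only pairs of equal length align
#' gap-free, so the result then equals the Hamming-based identity.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Percent identity in `[0, 100]`; symmetric in its arguments.
#' @examples
#' fragment_identity("ACGTACGT", "ACGTACGT")  # 100
#' @export
fragment_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("empty fragment")
  a <- normalize_nt(a, "fragment a")
  b <- normalize_nt(b, "fragment b")
  pair_identities_cpp(c(a, b), matrix(c(1L, 2L), 1L), nt_submat(),
                      NT_GAP_OPEN, NT_GAP_EXT, TRUE)[[1L]]
}

# Candidate partner pairs for the scan: i < j, non-overlapping genomic
# intervals with at least `min_separation` extra bp between them, and
# (unless exhaustive) sharing at least one k-mer.
scan_candidate_pairs <- function(seqs, windows, params) {
  n <- nrow(windows)
  if (n < 2) return(matrix(integer(0), 0, 2))
  min_gap <- params$win_len + params$min_separation
  if (params$exhaustive) {
    pr <- which(outer(windows$start, windows$start,
                      function(a, b) b - a >= min_gap), arr.ind = TRUE)
    pairs <- cbind(pr[, 1], pr[, 2])
  } else {
    k <- params$kmer
    km <- lapply(seqs, function(s) {
      if (nchar(s) < k) return(character(0))
      unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    })
    buckets <- split(rep(seq_len(n), lengths(km)), unlist(km))
    pairs_list <- lapply(buckets, function(v) {
      if (length(v) < 2) return(NULL)
      v <- sort(v)
      t(utils::combn(v, 2L))
    })
    pairs <- do.call(rbind, pairs_list)
    if (is.null(pairs) || nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
    pairs <- unique(pairs)
    keep <- windows$start[pairs[, 2]] - windows$start[pairs[, 1]] >= min_gap
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Best intra-cluster identity per window
#'
#' For every scan window, aligns it against all eligible partner windows
#' (non-overlapping genomic intervals, optionally separated by
#' `min_separation` extra bp) and keeps the highest percent identity.
#' Windows with no eligible partner (or with more than 50% `N`) report
#' identity 0 and no partner. Ties are broken toward the lowest partner
#' index.
#'
#' By default pairs are pre-screened with a shared-k-mer filter before
#' alignment; set `exhaustive = TRUE` in the params to align every
#' eligible pair, and `fast = TRUE` to replace gapped alignment with exact
#' ungapped identity.
#'
#' @param cluster A `gene_cluster`.
#' @param params A [scan_params()] object.
#' @return An `identity_profile`: list with `windows` (data frame),
#'   `best_identity` (percent per window), `best_partner` (window index or
#'   `NA`), and `params`.
#' @export
max_identity_profile <- function(cluster, params = scan_params()) {
  windows <- segment_windows(cluster, params)
  n <- nrow(windows)
  best <- rep(0, n)
  partner <- rep(NA_integer_, n)
  if (n >= 2) {
    seqs <- window_seqs(cluster, windows)
    nfrac <- vapply(seqs, function(s)
      sum(strsplit(s, "", fixed = TRUE)[[1L]] == "N"), 0L,
      USE.NAMES = FALSE) / params$win_len
    masked <- nfrac > 0.5
    pairs <- scan_candidate_pairs(seqs, windows, params)
    if (nrow(pairs)) {
      pairs <- pairs[!masked[pairs[, 1]] & !masked[pairs[, 2]], ,
                     drop = FALSE]
    }
    if (nrow(pairs)) {
      ids <- if (params$fast) {
        hamming_identities_cpp(seqs, pairs, TRUE)
      } else {
        pair_identities_cpp(seqs, pairs, nt_submat(),
                            NT_GAP_OPEN, NT_GAP_EXT, TRUE)
      }
      if (params$revcomp) {
        rc <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
        both <- c(seqs, rc)
        rcpairs <- cbind(pairs[, 1], pairs[, 2] + n)
        rids <- if (params$fast) {
          hamming_identities_cpp(both, rcpairs, TRUE)
        } else {
          pair_identities_cpp(both, rcpairs, nt_submat(),
                              NT_GAP_OPEN, NT_GAP_EXT, TRUE)
        }
        ids <- pmax(ids, rids)
      }
      # pairs are sorted so each window sees its partners in ascending
      # index order; strict > therefore keeps the lowest-index maximizer
      for (p in seq_along(ids)) {
        i <- pairs[p, 1]; j <- pairs[p, 2]; v <- ids[p]
        if (v > best[i]) { best[i] <- v; partner[i] <- j }
        if (v > best[j]) { best[j] <- v; partner[j] <- i }
      }
    }
    best[masked] <- 0
    partner[masked] <- NA_integer_
  }
  structure(list(windows = windows, best_identity = best,
                 best_partner = partner, params = params,
                 cluster_id = cluster$id, cluster_length = cluster$length),
            class = "identity_profile")
}

#' @export
print.identity_profile <- function(x, ...) {
  cat(sprintf("<identity_profile> %s: %d windows, max best identity %.1f%%\n",
              x$cluster_id, nrow(x$windows),
              if (length(x$best_identity)) max(x$best_identity) else NA))
  invisible(x)
}

# Centered sliding mean over `run` adjacent values, truncated at the edges
# (the mean is over the available neighbors).
sliding_mean <- function(x, run) {
  n <- length(x)
  h_lo <- (run - 1L) %/% 2L
  h_hi <- run %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h_lo):min(n, i + h_hi)]), 0)
}

#' Call duplicated regions from an identity profile
#'
#' Marks windows whose centered `run`-window sliding mean of best identity
#' strictly exceeds `id_min`, takes maximal runs of marked windows, unions
#' each run's window intervals into a region (merging regions whose
#' intervals overlap, since windows overlap at `step < win_len`), and
#' retains regions spanning at least `min_region` bp. Reported regions are
#' disjoint and sorted.
#'
#' @param profile An `identity_profile` from [max_identity_profile()].
#' @param params A [scan_params()] object (defaults to the profile's own).
#' @return Data frame with columns `start`, `end`, `mean_identity`
#'   (mean best identity over member windows), `n_windows`.
#' @export
call_duplicated_regions <- function(profile, params = profile$params) {
  empty <- data.frame(start = integer(), end = integer(),
                      mean_identity = numeric(), n_windows = integer())
  n <- nrow(profile$windows)
  if (n == 0) return(empty)
  sm <- sliding_mean(profile$best_identity, params$run)
  marked <- sm > params$id_min
  if (!any(marked)) return(empty)
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  regions <- data.frame(
    start = profile$windows$start[starts[keep]],
    end = profile$windows$end[ends[keep]],
    mean_identity = vapply(keep, function(k)
      mean(profile$best_identity[starts[k]:ends[k]]), 0),
    n_windows = ends[keep] - starts[keep] + 1L)
  # merge overlapping intervals (adjacent runs can still overlap in bp)
  if (nrow(regions) > 1) {
    merged <- regions[1, , drop = FALSE]
    for (i in 2:nrow(regions)) {
      last <- nrow(merged)
      if (regions$start[i] < merged$end[last]) {
        w1 <- merged$n_windows[last]; w2 <- regions$n_windows[i]
        merged$mean_identity[last] <-
          (merged$mean_identity[last] * w1 + regions$mean_identity[i] * w2) /
          (w1 + w2)
        merged$n_windows[last] <- w1 + w2
        merged$end[last] <- max(merged$end[last], regions$end[i])
      } else {
        merged <- rbind(merged, regions[i, ])
      }
    }
    regions <- merged
  }
  regions <- regions[regions$end - regions$start >= params$min_region, ,
                     drop = FALSE]
  rownames(regions) <- NULL
  regions
}
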