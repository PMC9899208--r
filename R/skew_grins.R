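#' GC skew of a sequence
#'
#' `(#G - #C) / (#G + #C)` over the whole string. `N` is ignored in the
#' counts; when the sequence contains no G or C the skew is undefined and
#' `NA` is returned.
#'
#' @param seq Nucleotide string.
#' @return Skew in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' gc_skew("GGGC")  # (3 - 1) / (3 + 1) = 0.5
#' @export
gc_skew <- function(seq) {
  base_skew(seq, "G", "C")
}

#' TA skew of a sequence
#'
#' `(#T - #A) / (#T + #A)`; `NA` when the sequence contains no T or A.
#'
#' @inheritParams gc_skew
#' @return Skew in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' ta_skew("AAAT")  # (1 - 3) / (1 + 3) = -0.5
#' @export
ta_skew <- function(seq) {
  base_skew(seq, "T", "A")
}

base_skew <- function(seq, plus, minus) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  p <- sum(chars == plus)
  m <- sum(chars == minus)
  if (p + m == 0) return(NA_real_)
  (p - m) / (p + m)
}

#' Per-window GC and TA skew profile
#'
#' Computes both skews for every scan window, on the identical window grid
#' as [max_identity_profile()]. Windows with a zero denominator carry `NA`
#' (undefined) for that skew.
#'
#' @param cluster A `gene_cluster`.
#' @param params A [scan_params()] object.
#' @return A `skew_profile` data frame: `index`, `start`, `end`,
#'   `gc_skew`, `ta_skew`.
#' @export
skew_profile <- function(cluster, params = scan_params()) {
  windows <- segment_windows(cluster, params)
  if (nrow(windows) == 0) {
    out <- cbind(windows, gc_skew = numeric(0), ta_skew = numeric(0))
    class(out) <- c("skew_profile", "data.frame")
    return(out)
  }
  seqs <- Biostrings::DNAStringSet(window_seqs(cluster, windows))
  counts <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  gc_den <- counts[, "G"] + counts[, "C"]
  ta_den <- counts[, "T"] + counts[, "A"]
  out <- cbind(windows,
               gc_skew = ifelse(gc_den > 0,
                                (counts[, "G"] - counts[, "C"]) / gc_den,
                                NA_real_),
               ta_skew = ifelse(ta_den > 0,
                                (counts[, "T"] - counts[, "A"]) / ta_den,
                                NA_real_))
  class(out) <- c("skew_profile", "data.frame")
  out
}

#' Promote duplicated regions to GRINS calls
#'
#' For each duplicated region, averages the absolute per-window GC and TA
#' skews over the windows fully contained in the region (windows whose
#' skew is undefined are excluded from the mean, not imputed). A region
#' passes when both mean absolute skews strictly exceed `skew_min`
#' (`rule = "both"`, the default) or when either does (`rule = "either"`).
#' All candidate regions are returned with their pass flag; filtering to
#' passing calls is left to the caller.
#'
#' @param dups Duplicated regions from [call_duplicated_regions()].
#' @param skews A [skew_profile()] on the same window grid.
#' @param skew_min Mean-absolute-skew threshold (dimensionless).
#' @param rule `"both"` or `"either"`.
#' @return Data frame: the region columns plus `mean_abs_gc`,
#'   `mean_abs_ta`, `passes`.
#' @export
call_grins <- function(dups, skews, skew_min = 0.15,
                       rule = c("both", "either")) {
  rule <- match.arg(rule)
  stopifnot(skew_min >= 0)
  out <- dups
  out$mean_abs_gc <- rep(NA_real_, NROW(dups))
  out$mean_abs_ta <- rep(NA_real_, NROW(dups))
  out$passes <- logical(NROW(dups))
  if (NROW(dups) == 0) return(out)
  for (i in seq_len(nrow(dups))) {
    member <- skews$start >= dups$start[i] & skews$end <= dups$end[i]
    gc <- skews$gc_skew[member]
    ta <- skews$ta_skew[member]
    gc_ok <- !is.na(gc)
    ta_ok <- !is.na(ta)
    if (!any(gc_ok) && !any(ta_ok)) {
      warning("region [", dups$start[i], ",", dups$end[i],
              ") has no windows with defined skew; marked failing")
      next
    }
    mg <- if (any(gc_ok)) mean(abs(gc[gc_ok])) else NA_real_
    mt <- if (any(ta_ok)) mean(abs(ta[ta_ok])) else NA_real_
    out$mean_abs_gc[i] <- mg
    out$mean_abs_ta[i] <- mt
    gc_pass <- !is.na(mg) && mg > skew_min
    ta_pass <- !is.na(mt) && mt > skew_min
    out$passes[i] <- if (rule == "both") gc_pass && ta_pass
                     else gc_pass || ta_pass
  }
  out
}
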