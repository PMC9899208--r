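# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. All stochastic operations in the package route through this,
# so nothing perturbs (or depends on) the global random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uppercase, RNA->DNA, and map non-ACGTN IUPAC codes to N (with a warning).
# Errors when the residue composition looks like protein.
normalize_nt <- function(seq, what = "sequence") {
  seq <- chartr("u", "t", seq)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    if (mean(bad) > 0.10) {
      stop(what, " does not look like nucleotide: ",
           round(100 * mean(bad)), "% of characters outside {A,C,G,T,N} ",
           "(amino-acid alphabet detected?)")
    }
    warning(sum(bad), " non-ACGTN IUPAC character(s) in ", what,
            " mapped to N")
    chars[bad] <- "N"
    seq <- paste(chars, collapse = "")
  }
  seq
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# EDNAFULL-like nucleotide scoring over {A,C,G,T,N}: match +5, mismatch -4,
# N scores -4 against everything (including N) so masked bases never pair.
nt_submat <- function() {
  if (is.null(.pkg_cache$nt_submat)) {
    ab <- c("A", "C", "G", "T", "N")
    m <- matrix(-4, 5, 5, dimnames = list(ab, ab))
    diag(m) <- 5
    m["N", "N"] <- -4
    .pkg_cache$nt_submat <- m
  }
  .pkg_cache$nt_submat
}

aa_submat <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

NT_GAP_OPEN <- 10
NT_GAP_EXT <- 0.5
AA_GAP_OPEN <- 11
AA_GAP_EXT <- 1

# Jaccard overlap of two half-open intervals (used in tests and reports).
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (union <= 0) return(0)
  inter / union
}
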