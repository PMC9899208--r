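#' Configuration for the synthetic-cluster generator
#'
#' Defaults emulate a streptomycete cis-AT PKS at desk scale: 8 modules of
#' 900 bp (300 codons) separated and flanked by 150-bp spacers, at 72% GC
#' (typical of *Streptomyces* genomes).
#'
#' @param seed Integer seed; every generator operation is a pure function
#'   of its inputs and this seed.
#' @param n_modules Number of module ORFs.
#' @param module_len Module length in bp (>= 300, divisible by 3).
#' @param intermodule_len Spacer length in bp (spacers flank and separate
#'   the modules).
#' @param gc_content Target GC proportion in (0, 1).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L, n_modules = 8L, module_len = 900L,
                             intermodule_len = 150L, gc_content = 0.72) {
  n_modules <- as.integer(n_modules)
  module_len <- as.integer(module_len)
  intermodule_len <- as.integer(intermodule_len)
  stopifnot(n_modules >= 1, module_len >= 300, module_len %% 3 == 0,
            intermodule_len >= 0, gc_content > 0, gc_content < 1)
  structure(list(seed = as.integer(seed), n_modules = n_modules,
                 module_len = module_len, intermodule_len = intermodule_len,
                 gc_content = gc_content),
            class = "generator_config")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Sense-codon sampling distribution at a target GC: independent-base codon
# probabilities with the three stop codons removed and renormalized.
sense_codon_probs <- function(gc) {
  p <- base_probs(gc)
  grid <- expand.grid(third = BASES, second = BASES, first = BASES,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$first, grid$second, grid$third)
  prob <- p[grid$first] * p[grid$second] * p[grid$third]
  keep <- !(codons %in% STOP_CODONS)
  prob <- prob[keep] / sum(prob[keep])
  setNames(prob, codons[keep])
}

random_orf <- function(len, gc) {
  cp <- sense_codon_probs(gc)
  if (any(!is.finite(cp)) || sum(cp > 0) == 0)
    stop("infeasible GC content for stop-free codons")
  paste(sample(names(cp), len %/% 3L, replace = TRUE, prob = cp),
        collapse = "")
}

random_spacer <- function(len, gc) {
  if (len == 0) return("")
  p <- base_probs(gc)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic PKS-like cluster with known truth
#'
#' The cluster alternates stop-free module ORFs (random sense codons at
#' the target GC) with random intergenic spacers:
#' `spacer | module_1 | spacer | ... | module_k | spacer`, giving length
#' `k * module_len + (k+1) * intermodule_len`. Module boundaries are
#' annotated; the truth object accumulates planted duplications and
#' skewed intervals from the `plant_*` operations.
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_truth`: list with `cluster` (a `gene_cluster`),
#'   `regions` (module annotations), `planted_dups`, `planted_skews`
#'   (empty data frames initially), `true_tree` (`NULL`) and `config`.
#' @export
generate_cluster <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    parts <- character(2L * cfg$n_modules + 1L)
    starts <- integer(cfg$n_modules)
    pos <- 0L
    k <- 0L
    for (i in seq_len(cfg$n_modules)) {
      sp <- random_spacer(cfg$intermodule_len, cfg$gc_content)
      k <- k + 1L; parts[k] <- sp; pos <- pos + nchar(sp)
      starts[i] <- pos
      orf <- random_orf(cfg$module_len, cfg$gc_content)
      k <- k + 1L; parts[k] <- orf; pos <- pos + nchar(orf)
    }
    parts[k + 1L] <- random_spacer(cfg$intermodule_len, cfg$gc_content)
    seq <- paste(parts, collapse = "")
  })
  cluster <- gene_cluster(sprintf("synthetic_cluster_seed%d", cfg$seed), seq)
  regions <- data.frame(
    name = sprintf("module_%d", seq_len(cfg$n_modules)),
    kind = "module", domain_class = "none",
    start = starts, end = starts + cfg$module_len,
    strand = "+", frame_offset = 0L, stringsAsFactors = FALSE)
  structure(list(
    cluster = cluster,
    regions = region_annotations(regions, cluster$length),
    planted_dups = data.frame(src_start = integer(), src_end = integer(),
                              dest_start = integer(), dest_end = integer(),
                              target_identity = numeric()),
    planted_skews = data.frame(start = integer(), end = integer(),
                               gc_target = numeric(), ta_target = numeric()),
    true_tree = NULL, config = cfg), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d bp, %d modules, %d planted ",
                     "duplication(s), %d planted skewed interval(s)\n"),
              x$cluster$length, nrow(x$regions), nrow(x$planted_dups),
              nrow(x$planted_skews)))
  invisible(x)
}

replace_interval <- function(seq, start, end, replacement) {
  stopifnot(nchar(replacement) == end - start)
  paste0(substring(seq, 1L, start), replacement,
         substring(seq, end + 1L, nchar(seq)))
}

# substitute each position with probability `rate`, always to a different
# base (uniform over the 3 alternatives); N positions are left untouched
mutate_always_change <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(chars)) < rate & chars %in% BASES
  if (any(hit)) {
    idx <- which(hit)
    alt <- vapply(chars[idx], function(b)
      sample(setdiff(BASES, b), 1L), character(1), USE.NAMES = FALSE)
    chars[idx] <- alt
  }
  paste(chars, collapse = "")
}

#' Plant a diverged duplication in a synthetic cluster
#'
#' Copies the source interval, substitutes each site with probability
#' `sub_rate` (always to a different base, uniform over the three
#' alternatives, so the expected identity between source and copy is
#' exactly `100 * (1 - sub_rate)`), and writes the copy over the
#' destination interval.
#'
#' @param truth A `synthetic_truth`.
#' @param source Length-2 vector `c(start, end)`, 0-based half-open.
#' @param dest_start Destination start (the copy occupies
#'   `[dest_start, dest_start + length)` and must not overlap the source).
#' @param sub_rate Per-site substitution probability (< 0.5).
#' @param seed Integer seed.
#' @return The updated `synthetic_truth`.
#' @export
plant_duplication <- function(truth, source, dest_start, sub_rate, seed) {
  stopifnot(inherits(truth, "synthetic_truth"), length(source) == 2,
            sub_rate >= 0, sub_rate < 0.5)
  L <- truth$cluster$length
  src <- as.integer(source); dest_start <- as.integer(dest_start)
  len <- src[2] - src[1]
  stopifnot(src[1] >= 0, src[2] > src[1], src[2] <= L)
  dest <- c(dest_start, dest_start + len)
  if (dest[1] < 0 || dest[2] > L) stop("destination outside cluster bounds")
  if (dest[1] < src[2] && src[1] < dest[2])
    stop("source and destination intervals overlap")
  copy <- substring(truth$cluster$seq, src[1] + 1L, src[2])
  copy <- with_seed(seed, mutate_always_change(copy, sub_rate))
  truth$cluster$seq <- replace_interval(truth$cluster$seq, dest[1], dest[2],
                                        copy)
  truth$planted_dups <- rbind(truth$planted_dups, data.frame(
    src_start = src[1], src_end = src[2],
    dest_start = dest[1], dest_end = dest[2],
    target_identity = 100 * (1 - sub_rate)))
  truth
}

#' Plant a nucleotide-skewed interval
#'
#' Resequences the interval i.i.d. with base probabilities solving
#' `(pG - pC)/(pG + pC) = gc_target` and `(pT - pA)/(pT + pA) = ta_target`
#' at the configured GC content. Codon/ORF structure inside the interval
#' is not preserved.
#'
#' @param truth A `synthetic_truth`.
#' @param interval Length-2 vector `c(start, end)`, 0-based half-open.
#' @param gc_target,ta_target Target skews, strictly inside (-1, 1).
#' @param seed Integer seed.
#' @param gc_content GC proportion of the resequenced interval; defaults
#'   to the generator's.
#' @return The updated `synthetic_truth`.
#' @export
plant_skew <- function(truth, interval, gc_target, ta_target, seed,
                       gc_content = truth$config$gc_content) {
  stopifnot(inherits(truth, "synthetic_truth"), length(interval) == 2)
  if (abs(gc_target) >= 1 || abs(ta_target) >= 1)
    stop("infeasible skew target: |target| must be < 1 ",
         "(the boundary requires a zero base probability)")
  iv <- as.integer(interval)
  stopifnot(iv[1] >= 0, iv[2] > iv[1], iv[2] <= truth$cluster$length)
  S <- gc_content; W <- 1 - gc_content
  p <- c(A = W * (1 - ta_target) / 2, C = S * (1 - gc_target) / 2,
         G = S * (1 + gc_target) / 2, T = W * (1 + ta_target) / 2)
  if (any(p <= 0)) stop("infeasible skew target combination")
  new_seq <- with_seed(seed,
    paste(sample(BASES, iv[2] - iv[1], replace = TRUE, prob = p),
          collapse = ""))
  truth$cluster$seq <- replace_interval(truth$cluster$seq, iv[1], iv[2],
                                        new_seq)
  truth$planted_skews <- rbind(truth$planted_skews, data.frame(
    start = iv[1], end = iv[2], gc_target = gc_target,
    ta_target = ta_target))
  truth
}

#' Evolve a root sequence along a tree under the Jukes-Cantor model
#'
#' Each site evolves independently along each branch: for branch length
#' `d` (substitutions/site, scaled by `rate_scale`), a site differs from
#' its parent with probability `p = (3/4)(1 - exp(-4 d / 3))`, and a
#' substituted site takes one of the other three bases uniformly.
#'
#' @param root_orf Root nucleotide sequence.
#' @param tree An [ape::phylo] tree with branch lengths (substitutions per
#'   site) and unique leaf labels.
#' @param rate_scale Multiplier applied to all branch lengths.
#' @param seed Integer seed.
#' @return Named character vector of leaf sequences.
#' @export
evolve_on_tree <- function(root_orf, tree, rate_scale = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  root_orf <- normalize_nt(root_orf, "root sequence")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  with_seed(seed, {
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- root_orf
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      d <- lens[e] * rate_scale
      p <- 0.75 * (1 - exp(-4 * d / 3))
      seqs[[child]] <- mutate_always_change(seqs[[parent]], p)
    }
    setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
  })
}
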