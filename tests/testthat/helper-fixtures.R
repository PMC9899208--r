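# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

NT <- c("A", "C", "G", "T")

rand_nt <- function(n, probs = rep(0.25, 4)) {
  paste(sample(NT, n, replace = TRUE, prob = probs), collapse = "")
}

# substitute exactly k positions, each to a different base
substitute_k <- function(x, k) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  idx <- sample(length(chars), k)
  for (i in idx) chars[i] <- sample(setdiff(NT, chars[i]), 1L)
  paste(chars, collapse = "")
}

# independent identity oracle for gap-free pairs of equal length
hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  100 * sum(ca == cb & ca != "N") / length(ca)
}

# random stop-free ORF (uniform sense codons)
rand_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(NT, NT, NT), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# ~10-kb synthetic cluster with one skewed tandem duplicate (module 3
# skewed, then copied immediately after itself) and one neutral tandem
# duplicate (module 8). Truth intervals are the source|copy unions.
flagship_truth <- function(seed = 7) {
  tr <- generate_cluster(generator_config(seed = seed, n_modules = 10,
                                          module_len = 900,
                                          intermodule_len = 100))
  m <- tr$regions
  tr <- plant_skew(tr, c(m$start[3], m$end[3]), 0.3, 0.3, seed = seed + 100)
  tr <- plant_duplication(tr, c(m$start[3], m$end[3]), m$end[3], 0.05,
                          seed = seed + 200)
  tr <- plant_duplication(tr, c(m$start[8], m$end[8]), m$end[8], 0.05,
                          seed = seed + 300)
  tr$skewed_union <- c(m$start[3], m$end[3] + 900)
  tr$neutral_union <- c(m$start[8], m$end[8] + 900)
  tr
}

jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / ((a[2] - a[1]) + (b[2] - b[1]) - inter)
}

# unrooted split sets as sorted "a|b" strings, for topology comparison
split_set <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    a <- sort(labs[p])
    b <- sort(setdiff(tips, a))
    if (length(a) < 2 || length(b) < 2) next
    key <- if (a[1] < b[1]) paste(paste(a, collapse = ","),
                                  paste(b, collapse = ","), sep = "|")
           else paste(paste(b, collapse = ","), paste(a, collapse = ","),
                      sep = "|")
    out <- c(out, key)
  }
  sort(unique(out))
}

# fixed 6-leaf tree with a recent m3/m6 duplication and all internal
# branches >= 0.05
six_leaf_tree <- function() {
  ape::read.tree(text = paste0(
    "((m1:0.15,m2:0.15):0.08,((m3:0.03,m6:0.03):0.12,",
    "(m4:0.1,m5:0.1):0.06):0.05);"))
}

write_tsv_regions_file <- function(df, path) {
  write_regions(df, path)
  path
}
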