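test_that("codon-aware alignment preserves reading frame", {
  set.seed(51)
  a <- rand_orf(100)
  pair <- codon_align_pair(a, a)
  expect_identical(pair$cols_a, a)
  expect_identical(pair$comparable_sites, 300L)

  # one inserted codon -> exactly one gap of length 3
  b <- paste0(substr(a, 1, 150), "GCA", substr(a, 151, 300))
  pair <- codon_align_pair(a, b)
  gaps <- regmatches(pair$cols_a, gregexpr("-+", pair$cols_a))[[1L]]
  expect_identical(gaps, "---")

  expect_error(codon_align_pair(paste0(a, "A"), a), "divisible by 3")
  stopped <- paste0(substr(a, 1, 30), "TAA", substr(a, 34, 300))
  expect_error(codon_align_pair(stopped, a), "internal stop")
})

test_that("codon alignment gaps always have length divisible by 3", {
  set.seed(52)
  for (i in 1:10) {
    a <- rand_orf(60)
    # delete 1-3 whole codons and substitute a few bases
    ncod <- sample(1:3, 1)
    at <- sample(10:45, 1)
    b <- paste0(substr(a, 1, 3 * at), substr(a, 3 * (at + ncod) + 1, 180))
    b <- substitute_k(b, 4)
    ok <- tryCatch({grinscan:::translate_orf(b); TRUE},
                   error = function(e) FALSE)
    if (!ok) next  # substitution created an internal stop; skip draw
    pair <- codon_align_pair(a, b)
    gaps <- unlist(regmatches(pair$cols_a, gregexpr("-+", pair$cols_a)))
    gaps <- c(gaps, unlist(regmatches(pair$cols_b,
                                      gregexpr("-+", pair$cols_b))))
    expect_true(all(nchar(gaps) %% 3 == 0))
  }
})

test_that("p-distance counts differing comparable sites", {
  pair <- aligned_pair("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(p_distance(pair), 0)
  pair <- aligned_pair("AAAAAAAAAAAA", "AAATTTAAAAAA")  # 3 of 12 differ
  expect_equal(p_distance(pair), 0.25)
  pair <- aligned_pair("AAAA", "TTTT")
  expect_equal(p_distance(pair), 1)
  # gaps and N excluded from the comparable set
  pair <- aligned_pair("AA-NAA", "AAGCAT")
  expect_identical(pair$comparable_sites, 4L)
  expect_equal(p_distance(pair), 0.25)
  # symmetric in its rows
  set.seed(53)
  a <- rand_nt(60)
  b <- substitute_k(a, 9)
  expect_equal(p_distance(aligned_pair(a, b)), p_distance(aligned_pair(b, a)))
})

test_that("Jukes-Cantor correction matches the closed form and its
          domain behaviour", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.3), -0.75 * log(0.6), tolerance = 1e-12)
  expect_error(jc_distance(0.75), "saturated")
  expect_equal(jc_distance(0.8, cap = TRUE), 5.0)
  grid <- seq(0, 0.74, length.out = 100)
  d <- jc_distance(grid)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= grid))
})

test_that("distances agree with the reference JC implementation", {
  set.seed(54)
  seqs <- c(s1 = rand_nt(300))
  seqs["s2"] <- substitute_k(seqs[["s1"]], 30)
  seqs["s3"] <- substitute_k(seqs[["s1"]], 60)
  D <- dist_jc(seqs, method = "aligned")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(ref[rownames(D), colnames(D)]),
               tolerance = 1e-9)
})

test_that("neighbor-joining solves the small closed-form cases", {
  D <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(D)
  expect_identical(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.5, 0.5))

  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(D)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))

  # additive 4-leaf matrix from ((A:1,B:2):1,(C:3,D:1))
  tgen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D <- ape::cophenetic.phylo(tgen)
  t4 <- nj_tree(D)
  expect_identical(split_set(t4), split_set(tgen))
  path <- ape::cophenetic.phylo(t4)[rownames(D), colnames(D)]
  expect_lt(max(abs(path - D)), 1e-9)
})

test_that("neighbor-joining is exact on random additive matrices and
          agrees with the reference implementation", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- gen$edge.length + 0.05
    D <- ape::cophenetic.phylo(gen)
    mine <- nj_tree(D)
    expect_identical(split_set(mine), split_set(gen))
    path <- ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
    expect_lt(max(abs(path - D)), 1e-9)
    ref <- ape::nj(D)
    expect_identical(split_set(mine), split_set(ref))
  }
})

test_that("neighbor-joining output is invariant under label permutation", {
  set.seed(56)
  gen <- ape::rtree(8)
  D <- ape::cophenetic.phylo(gen)
  perm <- sample(nrow(D))
  expect_identical(split_set(nj_tree(D)),
                   split_set(nj_tree(D[perm, perm])))
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(D), "symmetric")
  D <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(D), "finite")
})

test_that("cherry and split queries read the unrooted topology", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_sister_pair(tree, "A", "B"))
  expect_true(is_sister_pair(tree, "C", "D"))
  expect_false(is_sister_pair(tree, "A", "C"))
  expect_error(is_sister_pair(tree, "A", "Z"), "unknown leaf")

  classes <- c(A = "x", B = "x", C = "y", D = "y")
  expect_true(split_consistent(tree, classes))
  classes <- c(A = "x", B = "y", C = "x", D = "y")
  expect_false(split_consistent(tree, classes))
  expect_error(split_consistent(tree, c(A = "x", B = "y", C = "x")),
               "missing")

  # interleaved 8-leaf case
  t8 <- ape::read.tree(
    text = "(((A1:1,A2:1):1,(A3:1,A4:1):1):1,((B1:1,B2:1):1,(B3:1,B4:1):1):1);")
  cl <- setNames(substr(t8$tip.label, 1, 1), t8$tip.label)
  expect_true(split_consistent(t8, cl))
})

test_that("a planted recent duplication is recovered as a sister pair", {
  set.seed(57)
  seqs <- evolve_on_tree(rand_orf(500), six_leaf_tree(), seed = 58)
  res <- run_phylo_pipeline(seqs, aligned = TRUE, sisters = c("m3", "m6"))
  expect_true(res$sisters)
})

test_that("two module families evolved from distinct ancestors split
          cleanly", {
  # two clades of four, long stem between them
  t2fam <- ape::read.tree(text = paste0(
    "(((a1:0.05,a2:0.05):0.05,(a3:0.05,a4:0.05):0.05):0.4,",
    "((p1:0.05,p2:0.05):0.05,(p3:0.05,p4:0.05):0.05):0.4);"))
  seqs <- evolve_on_tree(rand_orf(500), t2fam, seed = 59)
  classes <- setNames(substr(names(seqs), 1, 1), names(seqs))
  res <- run_phylo_pipeline(seqs, aligned = TRUE, classes = classes)
  expect_true(res$split)
})
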