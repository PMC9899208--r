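test_that("window segmentation retains only full windows", {
  p <- scan_params()
  counts <- vapply(c(149, 150, 209, 4350), function(L) {
    set.seed(L)
    nrow(segment_windows(gene_cluster("c", rand_nt(L)), p))
  }, 0L)
  expect_identical(counts, c(0L, 1L, 2L, 141L))
  # starts advance by `step` and match the closed-form count
  set.seed(21)
  w <- segment_windows(gene_cluster("c", rand_nt(500)), p)
  expect_identical(w$start, seq(0L, 330L, by = 30L))
  expect_identical(w$end, w$start + 150L)
  for (L in c(150, 151, 179, 180, 300, 1000)) {
    set.seed(L)
    n <- nrow(segment_windows(gene_cluster("c", rand_nt(L)), p))
    expect_identical(n, as.integer((L - 150) %/% 30 + 1))
  }
})

test_that("fragment identity matches constructed oracles", {
  set.seed(22)
  a <- rand_nt(150)
  expect_equal(fragment_identity(a, a), 100)

  b <- substitute_k(a, 15)
  expect_equal(fragment_identity(a, b), 90)

  ins <- paste0(substr(a, 1, 75), "A", substr(a, 76, 150))
  expect_equal(fragment_identity(a, ins), 100 * 150 / 151, tolerance = 1e-9)

  expect_error(fragment_identity("", a), "empty")
})

test_that("fragment identity is symmetric and equals the Hamming oracle on
          substitution-only pairs", {
  set.seed(23)
  for (i in 1:25) {
    a <- rand_nt(150)
    b <- substitute_k(a, sample(0:20, 1))
    expect_equal(fragment_identity(a, b), fragment_identity(b, a))
    # equals the Hamming oracle whenever the gap-free alignment is optimal
    # (decided by the independent reference aligner)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5,
                                                    mismatch = -4,
                                                    baseOnly = TRUE)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global"))
    mm <- round(150 * (1 - hamming_identity(a, b) / 100))
    if (ref == 5 * (150 - mm) - 4 * mm)
      expect_equal(fragment_identity(a, b), hamming_identity(a, b))
  }
  # gapped pairs stay symmetric too
  for (i in 1:10) {
    a <- rand_nt(150)
    b <- paste0(substr(a, 1, 50), substr(a, 61, 150), rand_nt(10))
    expect_equal(fragment_identity(a, b), fragment_identity(b, a))
  }
})

test_that("alignment scores agree with the reference aligner", {
  set.seed(24)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- rand_nt(sample(80:160, 1))
    b <- rand_nt(sample(80:160, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    mine <- grinscan:::nw_align_cpp(a, b, grinscan:::nt_submat(), 10, 0.5)
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("N bases never count as matches", {
  a <- strrep("N", 150)
  expect_equal(fragment_identity(a, a), 0)
  b <- paste0(strrep("ACGT", 30), strrep("N", 30))
  expect_lt(fragment_identity(b, b), 100)
})

test_that("an exact tandem copy gives identity 100 for all partnered windows", {
  set.seed(25)
  x <- rand_nt(1500)
  cl <- gene_cluster("tandem", paste0(x, x))
  prof <- max_identity_profile(cl, scan_params())
  # windows with an exact image one period away (not straddling the
  # junction) must report 100% against that image
  imaged <- prof$windows$start <= 1350 | prof$windows$start >= 1500
  expect_true(all(prof$best_identity[imaged] == 100))
  shift <- abs(prof$windows$start[prof$best_partner[imaged]] -
                 prof$windows$start[imaged])
  expect_true(all(shift == 1500))
})

test_that("random sequence stays below the duplication threshold", {
  set.seed(26)
  cl <- gene_cluster("rand", rand_nt(3000))
  prof <- max_identity_profile(cl, scan_params(exhaustive = TRUE))
  expect_lt(max(prof$best_identity), 80)
  # prefilter mode can only lower reported identities, never raise them
  pre <- max_identity_profile(cl, scan_params())
  expect_true(all(pre$best_identity <= prof$best_identity + 1e-9))
})

test_that("a single-window cluster has no partner", {
  set.seed(27)
  prof <- max_identity_profile(gene_cluster("c", rand_nt(150)), scan_params())
  expect_equal(prof$best_identity, 0)
  expect_true(is.na(prof$best_partner))
})

test_that("duplicated-region calling follows the sliding-mean rule", {
  p <- scan_params()
  set.seed(28)
  cl <- gene_cluster("c", rand_nt(2000))
  prof <- max_identity_profile(cl, p)

  prof$best_identity <- rep(100, length(prof$best_identity))
  regs <- call_duplicated_regions(prof, p)
  expect_identical(nrow(regs), 1L)
  expect_identical(regs$start, 0L)
  expect_identical(regs$end, max(prof$windows$end))

  prof$best_identity <- rep(79, length(prof$best_identity))
  expect_identical(nrow(call_duplicated_regions(prof, p)), 0L)
})

test_that("a planted diverged duplicate is recovered against truth", {
  tr <- generate_cluster(generator_config(seed = 31, n_modules = 10,
                                          module_len = 900,
                                          intermodule_len = 100))
  m <- tr$regions
  # tandem copy at ~90% identity -> a single merged region
  tr <- plant_duplication(tr, c(m$start[4], m$end[4]), m$end[4], 0.10,
                          seed = 32)
  truth <- c(m$start[4], m$end[4] + 900)
  prof <- max_identity_profile(tr$cluster, scan_params())
  regs <- call_duplicated_regions(prof, scan_params())
  # the called bases recover the planted source|copy union
  expect_gte(jaccard(c(min(regs$start), max(regs$end)), truth), 0.8)
  expect_true(all(regs$start >= truth[1] - 150 & regs$end <= truth[2] + 150))
  expect_true(all(abs(regs$mean_identity - 90) < 3))

  # post-hoc re-check of the region rule on every region
  sm <- grinscan:::sliding_mean(prof$best_identity, 5)
  for (r in seq_len(nrow(regs))) {
    member <- prof$windows$start >= regs$start[r] &
      prof$windows$end <= regs$end[r]
    expect_gt(mean(sm[member] > 80), 0.9)
    expect_gte(regs$end[r] - regs$start[r], 500)
  }
})

test_that("distant copies are reported symmetrically at source and copy", {
  tr <- generate_cluster(generator_config(seed = 33, n_modules = 10,
                                          module_len = 900,
                                          intermodule_len = 100))
  m <- tr$regions
  tr <- plant_duplication(tr, c(m$start[3], m$end[3]), m$start[7], 0.05,
                          seed = 34)
  regs <- call_duplicated_regions(max_identity_profile(tr$cluster,
                                                       scan_params()),
                                  scan_params())
  expect_identical(nrow(regs), 2L)
  expect_gte(jaccard(c(regs$start[1], regs$end[1]),
                     c(m$start[3], m$end[3])), 0.8)
  expect_gte(jaccard(c(regs$start[2], regs$end[2]),
                     c(m$start[7], m$end[7])), 0.8)
  # regions never overlap
  expect_true(all(regs$start[-1] >= regs$end[-nrow(regs)]))
})

test_that("lowering the identity threshold never removes called bases", {
  tr <- flagship_truth(seed = 35)
  prof <- max_identity_profile(tr$cluster, scan_params())
  covered <- function(id_min) {
    p <- scan_params(id_min = id_min)
    regs <- call_duplicated_regions(prof, p)
    if (!nrow(regs)) return(integer(0))
    unlist(mapply(seq, regs$start, regs$end - 1L, SIMPLIFY = FALSE))
  }
  hi <- covered(85)
  lo <- covered(70)
  expect_true(all(hi %in% lo))
})
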