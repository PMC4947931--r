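test_that("FASTA round trip normalises case and preserves content", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgTacg", ">s2", "ACGTACG", ">s3", "acgtacg"), fa)
  pt <- data.frame(id = c("s1", "s2", "s3"), population = "p1")
  rd <- read_fasta_alignment(fa, pt)
  expect_equal(length(rd$alignment$ids), 3)
  expect_equal(n_sites(rd$alignment), 7)
  expect_true(all(rd$alignment$mat %in% c("A", "C", "G", "T")))
  # write-then-read identity
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(rd$alignment, fa2)
  rd2 <- read_fasta_alignment(fa2)
  expect_identical(rd$alignment$mat, rd2$alignment$mat)
})

test_that("input validation errors name the offending records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGT"), fa)
  expect_error(read_fasta_alignment(fa, data.frame(id = "s1",
                                                   population = "p")),
               "s2")
  expect_error(dna_alignment(c(a = "ACG", b = "ACGT")), "ragged")
  expect_error(dna_alignment(setNames(c("ACG", "ACG"), c("x", "x"))),
               "duplicate")
})

test_that("concatenation adds lengths, preserves order, is associative", {
  n <- 4
  a <- random_alignment(n, 1141, seed = 11)
  b <- random_alignment(n, 714, seed = 12)
  ab <- concatenate_alignments(a, b)
  expect_equal(n_sites(ab), 1855)
  expect_identical(ab$mat[, 1:1141], a$mat)
  expect_identical(unname(ab$mat[, 1142:1855]), unname(b$mat))
  # identity with empty fragment
  expect_identical(concatenate_alignments(a, dna_alignment(a$mat[, 0])), a)
  # associativity on three fragments
  cc <- random_alignment(n, 50, seed = 13)
  lhs <- concatenate_alignments(concatenate_alignments(a, b), cc)
  rhs <- concatenate_alignments(a, concatenate_alignments(b, cc))
  expect_identical(lhs$mat, rhs$mat)
  # id mismatch reported with the symmetric difference
  d <- random_alignment(n, 10, seed = 14)
  d$ids[1] <- rownames(d$mat)[1] <- "zz"
  expect_error(concatenate_alignments(a, d), "zz")
})

test_that("haplotype collapsing counts and round-trips", {
  tf <- toy_alignment()
  ht <- collapse_haplotypes(tf$aln, tf$pm)
  expect_equal(length(ht$sequences), 2)
  expect_equal(unname(ht$counts), matrix(c(3L, 2L, 0L, 1L), 2, 2))
  expect_equal(sum(ht$counts), ht$n)
  # degenerate cases
  same <- dna_alignment(setNames(rep("ACGT", 5), paste0("s", 1:5)))
  expect_equal(length(collapse_haplotypes(same)$sequences), 1)
  dist <- random_alignment(6, 40, seed = 3)
  expect_equal(length(collapse_haplotypes(dist)$sequences), 6)
  # collapse -> expand reproduces the sequence multiset
  back <- expand_haplotypes(ht)
  expect_equal(sort(unname(apply(back$mat, 1, paste, collapse = ""))),
               sort(unname(apply(tf$aln$mat, 1, paste, collapse = ""))))
})

test_that("site classification matches hand enumeration", {
  aln0 <- dna_alignment(setNames(rep("ACGT", 4), paste0("s", 1:4)))
  expect_equal(unname(attr(classify_sites(aln0), "counts")["variable"]), 0)
  # {ACG, ACG, ATG, GTG}: site1 variable non-PI (A/G singleton),
  # site2 variable + PI (C<->T transition), site3 invariant
  aln <- dna_alignment(c(s1 = "ACG", s2 = "ACG", s3 = "ATG", s4 = "GTG"))
  ss <- classify_sites(aln)
  expect_equal(ss$variable, c(TRUE, TRUE, FALSE))
  expect_equal(ss$parsimony_informative, c(FALSE, TRUE, FALSE))
  expect_equal(ss$subst_type[1:2], c("transition", "transition"))
  cnt <- attr(ss, "counts")
  expect_equal(unname(cnt["variable"] + cnt["invariant"] + cnt["indel_only"]),
               unname(cnt["k"]))
})

test_that("site classification invariants hold on random alignments", {
  for (seed in 1:5) {
    aln <- random_alignment(8, 60, seed = seed,
                            bases = c("A", "C", "G", "T", "N", "-"))
    ss <- classify_sites(aln)
    expect_true(all(ss$variable[ss$parsimony_informative]))
    cnt <- attr(ss, "counts")
    expect_equal(unname(cnt["variable"] + cnt["invariant"] +
                          cnt["indel_only"]), 60)
    # concatenated variable sites = union of fragment variable sites
    a <- dna_alignment(aln$mat[, 1:30]); b <- dna_alignment(aln$mat[, 31:60])
    va <- classify_sites(a)$variable; vb <- classify_sites(b)$variable
    expect_equal(classify_sites(aln)$variable, c(va, vb))
  }
})

test_that("pairwise differences use pairwise deletion", {
  aln <- dna_alignment(c(x = "ACG", y = "ATG", z = "ACG"))
  D <- pairwise_differences(aln)
  expect_equal(unname(D["x", "y"]), 1)
  expect_equal(unname(D["x", "z"]), 0)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # N columns excluded per pair
  aln2 <- dna_alignment(c(x = "ANG", y = "ATG"))
  expect_equal(unname(pairwise_differences(aln2)[1, 2]), 0)
  pd <- pairwise_differences(aln2, effective_length = TRUE)
  expect_equal(unname(pd$sites[1, 2]), 2)
})

test_that("haplotype export annotates frequencies and round-trips", {
  tf <- toy_alignment()
  ht <- collapse_haplotypes(tf$aln, tf$pm)
  fa <- withr::local_tempfile(fileext = ".fasta")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_haplotypes(ht, fa, csv)
  lines <- readLines(fa)
  expect_true(any(grepl("n=3", lines)))
  counts <- read.csv(csv, row.names = 1)
  expect_equal(sum(counts), 6)
})
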