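test_that("score transform follows 2^(0.1 s)", {
  tr <- pssm_transform(matrix(c(0, 10, -10), nrow = 1))
  expect_equal(as.numeric(tr), c(1, 2, 0.5))
  expect_true(all(pssm_transform(matrix(seq(-400L, 399L), ncol = 5)) > 0))
})

test_that("frequency matrix rows are stochastic", {
  tr <- matrix(c(1, 1, 1, 1, 1, 2, 1, 1, 1, 1), nrow = 2, byrow = TRUE)
  fm <- tr / rowSums(tr)
  expect_equal(fm[1, ], rep(0.2, 5))
  expect_equal(fm[2, ], c(1 / 3, 1 / 6, 1 / 6, 1 / 6, 1 / 6))
  set.seed(1)
  p <- pssm(matrix(sample(-9:9, 50, replace = TRUE), ncol = 5), strrep("ACGU", 2L) |> paste0("AC"))
  expect_equal(rowSums(frequency_matrix(p)), rep(1, 10), tolerance = 1e-9)
})

test_that("consensus takes the nucleotide argmax; gap never wins; ties go to A<C<G<U", {
  expect_equal(consensus_sequence(matrix(c(0.7, 0.1, 0.1, 0.05, 0.05), nrow = 1)), "A")
  # 4-way tie among nucleotides while the gap column dominates
  expect_equal(consensus_sequence(matrix(c(0.1, 0.1, 0.1, 0.1, 0.6), nrow = 1)), "A")
  # pairwise tie cases follow lowest-alphabet-index
  expect_equal(consensus_sequence(matrix(c(0.3, 0.3, 0.2, 0.2, 0), nrow = 1)), "A")
  expect_equal(consensus_sequence(matrix(c(0.1, 0.2, 0.35, 0.35, 0), nrow = 1)), "G")
  # one-hot frequency matrix reproduces its sequence
  oh <- diag(4)[match(strsplit("GACU", "")[[1]], c("A", "C", "G", "U")), ]
  expect_equal(consensus_sequence(cbind(oh, 0)), "GACU")
})

test_that("consensus composition and entropy match hand values and a generic oracle", {
  cc <- consensus_composition("ACGU")
  expect_equal(unname(cc$nccs), rep(0.25, 4))
  expect_equal(cc$ecs, log(4))

  cc <- consensus_composition("AAAA")
  expect_equal(unname(cc$nccs), c(1, 0, 0, 0))
  expect_equal(cc$ecs, 0)

  cc <- consensus_composition("AACG")
  expect_equal(unname(cc$nccs), c(0.5, 0.25, 0.25, 0))
  expect_equal(cc$ecs, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(cc$ecs, 1.039721, tolerance = 1e-6)
})

test_that("frequency-matrix entropy matches closed forms", {
  expect_equal(profile_entropy(matrix(0.2, nrow = 3, ncol = 5)), log(5))
  oh <- cbind(diag(4), 0)
  expect_equal(profile_entropy(oh), 0)
  fm <- rbind(c(0.5, 0.5, 0, 0, 0), rep(0.2, 5))
  expect_equal(profile_entropy(fm), (log(2) + log(5)) / 2)
  expect_equal(profile_entropy(fm), 1.151293, tolerance = 1e-6)
})

test_that("consensus k-mers are windowed relative frequencies in lexicographic order", {
  d <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(d["AA"]), 1)
  expect_equal(sum(d), 1)
  expect_equal(unname(kmer_frequencies("AAAA", 3)["AAA"]), 1)

  d <- kmer_frequencies("ACGU", 2)
  expect_equal(unname(d[c("AC", "CG", "GU")]), rep(1 / 3, 3))

  d2 <- kmer_frequencies("ACAC", 2)
  expect_equal(unname(d2[c("AC", "CA")]), c(2 / 3, 1 / 3))
  t2 <- kmer_frequencies("ACAC", 3)
  expect_equal(unname(t2[c("ACA", "CAC")]), c(0.5, 0.5))

  expect_equal(names(kmer_frequencies("ACGU", 2))[1:5], c("AA", "AC", "AG", "AU", "CA"))
  expect_error(kmer_frequencies("AC", 3), "too short")
})

test_that("profile block has 87 features in the frozen named order", {
  nm <- profile_feature_names()
  expect_length(nm, 87)
  expect_equal(nm[1:6], c("psi.NCCS_A", "psi.NCCS_C", "psi.NCCS_G", "psi.NCCS_U", "psi.Ecs", "psi.Efm"))
  expect_equal(nm[7], "psi.di_AA")
  expect_equal(nm[23], "psi.tri_AAA")
  expect_equal(nm[87], "psi.GC")

  pf <- profile_features(pseudo_pssm("ACGUACGU"))
  expect_length(pf, 87)
  expect_named(pf, nm)
  expect_equal(unname(pf["psi.Ecs"]), log(4))
  expect_equal(unname(pf["psi.GC"]), 0.5)
})

test_that("near-one-hot profiles give uniform composition and vanishing entropy", {
  # huge score contrast makes the frequency matrix effectively one-hot
  chars <- strsplit("ACGU", "")[[1]]
  scores <- matrix(-800L, nrow = 4, ncol = 5)
  scores[cbind(1:4, 1:4)] <- 0L
  p <- pssm(scores, "ACGU")
  pf <- profile_features(p)
  expect_equal(unname(pf[paste0("psi.NCCS_", c("A", "C", "G", "U"))]), rep(0.25, 4))
  expect_equal(unname(pf["psi.Ecs"]), log(4))
  expect_lt(unname(pf["psi.Efm"]), 1e-10)
})

test_that("profile features are invariant to a constant score shift", {
  set.seed(11)
  scores <- matrix(sample(-8:8, 60, replace = TRUE), ncol = 5)
  s <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
  a <- profile_features(pssm(scores, s))
  b <- profile_features(pssm(scores + 7L, s))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("gc content counts G and C only", {
  expect_equal(gc_fraction_of <- profile_features(pseudo_pssm("GGCC"))[["psi.GC"]], 1)
  expect_equal(profile_features(pseudo_pssm("AAUU"))[["psi.GC"]], 0)
  expect_equal(profile_features(pseudo_pssm("GACU"))[["psi.GC"]], 0.5)
})
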