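# Codon statistics: alignment, four-fold site identification, 4dTv, and
# amino-acid distances.

test_that("identical CDS align without gaps", {
  cds <- "ATGGCTACGGTACTTTAA"
  aln <- align_pair_codon_aware(cds, cds)
  expect_identical(aln$aln_a, cds)
  expect_identical(aln$aln_b, cds)
})

test_that("equal-length synonymous pair aligns gapless over 9 columns", {
  aln <- align_pair_codon_aware("ATGGGTTAA", "ATGGGATAA")
  expect_equal(nchar(aln$aln_a), 9L)
  expect_false(grepl("-", aln$aln_a, fixed = TRUE))
  expect_false(grepl("-", aln$aln_b, fixed = TRUE))
})

test_that("a deleted internal codon yields exactly one 3-column gap run", {
  cds_a <- "ATGGGTTGGAAACCGTAA"           # M G W K P *
  cds_b <- "ATGGGTAAACCGTAA"              # M G K P *   (W codon deleted)
  aln <- align_pair_codon_aware(cds_a, cds_b)
  expect_equal(nchar(aln$aln_a), 18L)
  runs <- regmatches(aln$aln_b, gregexpr("-+", aln$aln_b))[[1]]
  expect_identical(runs, "---")
  expect_false(grepl("-", aln$aln_a, fixed = TRUE))
})

test_that("alignment scores match exhaustive path enumeration on short inputs", {
  # independent oracle: enumerate every monotone alignment path and score it
  mat <- get(data("BLOSUM62", package = "Biostrings",
                  envir = environment()))
  cases <- list(c("MGWKP", "MGKP"), c("MGW", "MW"), c("MAW", "MVVW"),
                c("CCHG", "CHG"), c("MGWKP", "MP"))
  for (cs in cases) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(cs[1]), Biostrings::AAString(cs[2]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    expect_equal(Biostrings::score(pa),
                 bf_align_score(cs[1], cs[2], mat), label = paste(cs,
                                                                  collapse = "/"))
  }
})

test_that("internal stop codons are aligned as residues, not errors", {
  aln <- align_pair_codon_aware("ATGTGAGGTTAA", "ATGTGAGGATAA")
  expect_equal(nchar(aln$aln_a), 12L)
  expect_error(align_pair_codon_aware("", "ATG"), "empty")
})

test_that("four-fold site identification follows the codon-table rules", {
  one <- function(ca, cb)
    identify_fourfold_sites(codon_pair_alignment(ca, cb))
  expect_equal(one("GGT", "GGC"), 3L)             # Gly family
  expect_length(one("ATG", "ATG"), 0L)            # Met is not four-fold
  expect_length(one("AGA", "AGG"), 0L)            # AGR Arg is two-fold
  expect_length(one("GGT", "GCT"), 0L)            # first-two mismatch
  expect_length(one("GG-", "GGT"), 0L)            # gap excluded
  expect_length(one("GGN", "GGT"), 0L)            # ambiguity excluded
})

test_that("four-fold identification agrees with the genetic-code oracle on all sense-codon pairs", {
  codons <- sense_codons()
  expect_length(codons, 61L)
  ff <- vapply(codons, bf_is_fourfold, logical(1))
  # oracle sanity: exactly 8 four-fold families x 4 codons
  expect_equal(sum(ff), 32L)
  for (ca in codons) {
    hits <- vapply(codons, function(cb) {
      length(identify_fourfold_sites(codon_pair_alignment(ca, cb))) > 0L
    }, logical(1))
    want <- ff[[ca]] & ff & substr(codons, 1, 2) == substr(ca, 1, 2)
    expect_identical(unname(hits), unname(want), label = ca)
  }
})

test_that("substitution classification separates transitions and transversions", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("A", "T"), "transversion")
  expect_identical(classify_substitution("C", "C"), "identical")
  expect_identical(
    classify_substitution(c("A", "G", "C"), c("C", "A", "T")),
    c("transversion", "transition", "transition"))
  expect_error(classify_substitution("N", "A"), "ambiguous")
})

test_that("4dTv of the hand-counted toy alignment is 2/4", {
  aln <- codon_pair_alignment("GGTCTAGCCACGTTTATG", "GGACTGGCGACGTTCATG")
  r <- compute_4dtv(aln)
  expect_equal(r$n_4d_sites, 4L)
  expect_equal(r$n_transversions, 2L)
  expect_equal(r$n_transitions, 1L)
  expect_equal(r$fourdtv, 0.5)
})

test_that("4dTv is 0 for identical sequences and undefined without 4d sites", {
  r <- compute_4dtv(codon_pair_alignment("GGTGGC", "GGTGGC"))
  expect_equal(r$fourdtv, 0)
  r0 <- compute_4dtv(codon_pair_alignment("ATGTGG", "ATGTGG"))
  expect_false(r0$defined)
  expect_true(is.na(r0$fourdtv))
})

test_that("4dTv is symmetric in the pair", {
  anc <- random_cds(500, seed = 11)
  aln <- evolved_pair_alignment(anc, tau = 0.2, seed = 21)
  swapped <- codon_pair_alignment(aln$aln_b, aln$aln_a)
  a <- compute_4dtv(aln); b <- compute_4dtv(swapped)
  expect_equal(a$fourdtv, b$fourdtv)
  expect_equal(a$n_4d_sites, b$n_4d_sites)
  expect_equal(a$n_transversions, b$n_transversions)
  expect_equal(a$n_transitions, b$n_transitions)
})

test_that("simulated 4dTv hits its Monte-Carlo expectation at tau(0.27)", {
  anc <- random_cds(360000, seed = 8)
  aln <- evolved_pair_alignment(anc, tau = tau_for_target_4dtv(0.27),
                                seed = 81)
  r <- compute_4dtv(aln)
  expect_gte(r$n_4d_sites, 50000L)
  se <- sqrt(0.27 * 0.73 / r$n_4d_sites)
  expect_lt(abs(r$fourdtv - 0.27), 3 * se)
})

test_that("mean 4dTv is monotone non-decreasing in tau", {
  taus <- c(0.02, 0.1, 0.2)
  means <- vapply(seq_along(taus), function(ti) {
    vals <- vapply(1:100, function(i) {
      anc <- random_cds(100, seed = 1000 * ti + i)
      compute_4dtv(evolved_pair_alignment(anc, taus[ti],
                                          seed = 5000 * ti + i))$fourdtv
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the corrected 4dTv option applies -log(1 - 2Q)/2", {
  aln <- codon_pair_alignment("GGTCTAGCCACGTTTATG", "GGACTGGCGACGTTCATG")
  r <- compute_4dtv(aln, correct = TRUE)
  expect_false(r$defined)  # Q = 0.5 saturates the correction
  anc <- random_cds(2000, seed = 3)
  aln2 <- evolved_pair_alignment(anc, 0.1, seed = 13)
  raw <- compute_4dtv(aln2)
  cor <- compute_4dtv(aln2, correct = TRUE)
  expect_equal(cor$fourdtv, -0.5 * log(1 - 2 * raw$fourdtv))
})

test_that("amino-acid distances follow the Poisson closed form", {
  r <- compute_aa_distance("MGWKP", "MGWKP")
  expect_equal(r$p_distance, 0)
  expect_equal(r$poisson_corrected, 0)
  r2 <- compute_aa_distance("MGWKPAAAQQ", "MGWKPAAAQH")
  expect_equal(r2$p_distance, 0.1)
  expect_equal(r2$poisson_corrected, 0.10536, tolerance = 1e-4)
  # saturated distance is flagged
  r3 <- compute_aa_distance("AG", "GA")
  expect_true(is.na(r3$poisson_corrected))
  # all-gap alignment undefined
  r4 <- compute_aa_distance("--", "AA")
  expect_false(r4$defined)
  # gapped columns are excluded from the denominator
  r5 <- compute_aa_distance("MG-W", "MGAW")
  expect_equal(r5$n_sites, 3L)
  expect_equal(r5$p_distance, 0)
})

test_that("pairs_4dtv drives alignment and 4dTv over a pair table", {
  gs <- build_genome_set(small_wgd_config(n_genes = 6, codons = 40,
                                          seed = 4))
  pv <- pairs_4dtv(all_cds(gs), gs$hits[, c("qid", "sid")])
  expect_equal(nrow(pv), nrow(gs$truth))
  expect_true(all(pv$fourdtv >= 0 & pv$fourdtv <= 1, na.rm = TRUE))
  expect_true(all(pv$n_transversions + pv$n_transitions <= pv$n_4d_sites))
  expect_error(pairs_4dtv(all_cds(gs),
                          data.frame(qid = "nope", sid = "nada")),
               "not in CDS")
})
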