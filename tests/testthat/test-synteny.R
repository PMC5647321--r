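# Synteny: hit loading, collinear chaining, block aggregation.

make_anchors <- function(ra, rb, chrom_a = "c1", chrom_b = "c2",
                         score = 50) {
  data.frame(gene_a = sprintf("a%d", seq_along(ra)),
             gene_b = sprintf("b%d", seq_along(rb)),
             chrom_a = rep(chrom_a, length(ra)),
             chrom_b = rep(chrom_b, length(ra)),
             rank_a = ra, rank_b = rb,
             score = rep(score, length(ra)),
             stringsAsFactors = FALSE)
}

test_that("load_hits attaches coordinate-sorted ranks and deduplicates", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "h1", "h2", "h3"),
    chrom = rep(c("cA", "cB"), each = 3),
    start = c(100, 900, 500, 10, 20, 30),
    end = c(150, 950, 550, 15, 25, 35),
    strand = "+", stringsAsFactors = FALSE)
  hits <- data.frame(qid = c("g1", "g3", "g2", "g1"),
                     sid = c("h1", "h2", "h3", "h1"),
                     pident = c(90, 80, 70, 95))
  a <- load_hits(hits, genes)
  expect_equal(nrow(a), 3L)  # duplicate (g1,h1) collapsed
  expect_equal(a$score[a$gene_a == "g1"], 95)  # highest score kept
  # g2 starts last on cA -> rank 2; g3 in the middle -> rank 1
  expect_equal(a$rank_a[a$gene_a == "g2"], 2)
  expect_equal(a$rank_a[a$gene_a == "g3"], 1)
  expect_equal(a$rank_b[a$gene_b == "h3"], 2)
  expect_error(load_hits(data.frame(qid = "gX", sid = "h1"), genes),
               "gX")
})

test_that("perfect collinearity chains into a single block", {
  a <- make_anchors(1:5, 1:5)
  bl <- chain_anchors(a, chain_params(min_anchors = 3))
  expect_length(bl, 1L)
  expect_equal(nrow(bl[[1]]$anchors), 5L)
  expect_equal(bl[[1]]$orientation, "same")
  expect_equal(bl[[1]]$block_score, 50)  # 5 anchors x 10, no gaps
})

test_that("strictly decreasing rank_b chains as one inverted block", {
  a <- make_anchors(1:5, c(9, 7, 6, 4, 2))
  bl <- chain_anchors(a, chain_params(min_anchors = 3))
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$orientation, "inverted")
  expect_equal(nrow(bl[[1]]$anchors), 5L)
})

test_that("an off-diagonal outlier is excluded by the gap limit", {
  a <- make_anchors(1:5, c(1, 2, 3, 10, 4))
  bl <- chain_anchors(a, chain_params(max_gap = 3, min_anchors = 3))
  expect_length(bl, 1L)
  got <- bl[[1]]$anchors
  expect_setequal(got$gene_a, c("a1", "a2", "a3", "a5"))
  expect_false("a4" %in% got$gene_a)  # the (4,10) anchor
  # score: 4 anchors x 10 minus one skipped gene in genome a
  expect_equal(bl[[1]]$block_score, 39)
})

test_that("first reported chain attains the exhaustive optimum on random instances", {
  params <- chain_params(max_gap = 5, min_anchors = 2, gap_penalty = 1,
                         anchor_score = 10)
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(5:10, 1)
    ra <- sample(0:14, n)
    rb <- sample(0:14, n)
    a <- make_anchors(ra, rb)
    bf <- bf_best_chain_score(ra, rb, params)
    bl <- chain_anchors(a, params)
    if (length(bl) == 0L) {
      expect_true(bf <= 2 * params$anchor_score, label = paste("rep", rep))
    } else {
      expect_equal(bl[[1]]$block_score, bf, label = paste("rep", rep))
    }
  }
})

test_that("chaining is anti-symmetric under swapping the two genomes", {
  swap <- function(a)
    data.frame(gene_a = a$gene_b, gene_b = a$gene_a,
               chrom_a = a$chrom_b, chrom_b = a$chrom_a,
               rank_a = a$rank_b, rank_b = a$rank_a,
               score = a$score, stringsAsFactors = FALSE)
  keyset <- function(blocks, rev = FALSE)
    sort(unlist(lapply(blocks, function(b)
      if (rev) paste(b$anchors$gene_b, b$anchors$gene_a)
      else paste(b$anchors$gene_a, b$anchors$gene_b))))
  p <- chain_params(min_anchors = 2)

  # structured instances (tie-free optima): exact anchor-set equality
  a1 <- make_anchors(c(0:5, 10:14), c(0:5, 18:14))
  expect_identical(keyset(chain_anchors(a1, p)),
                   keyset(chain_anchors(swap(a1), p), rev = TRUE))
  gs <- build_genome_set(small_wgd_config(n_genes = 24, codons = 10,
                                          loss = 0.2, gpc = 24, seed = 13))
  a2 <- load_hits(gs$hits, all_genes(gs))
  expect_identical(keyset(chain_anchors(a2, p)),
                   keyset(chain_anchors(swap(a2), p), rev = TRUE))

  # random instances may contain equal-scoring alternative optima, between
  # which the deterministic tie-break is orientation-dependent; the optimal
  # (first) chain score is still anti-symmetric
  set.seed(77)
  for (rep in 1:10) {
    a <- make_anchors(sample(0:19, 12), sample(0:19, 12))
    b1 <- chain_anchors(a, p)
    b2 <- chain_anchors(swap(a), p)
    expect_equal(length(b1) > 0L, length(b2) > 0L,
                 label = paste("rep", rep))
    if (length(b1) && length(b2))
      expect_equal(b1[[1]]$block_score, b2[[1]]$block_score,
                   label = paste("rep", rep))
  }
})

test_that("loss-free WGD output gives one block per chromosome pair with all genes", {
  gs <- build_genome_set(small_wgd_config(n_genes = 60, codons = 10,
                                          loss = 0, gpc = 12, seed = 6))
  anchors <- load_hits(gs$hits, all_genes(gs))
  blocks <- synteny_blocks(anchors, chain_params())
  expect_length(blocks, 5L)  # 60 genes / 12 per chromosome
  expect_true(all(vapply(blocks, function(b) nrow(b$anchors),
                         integer(1)) == 12L))
  pairs <- unique(paste(vapply(blocks, `[[`, character(1), "chrom_a"),
                        vapply(blocks, `[[`, character(1), "chrom_b")))
  expect_length(pairs, 5L)
})

test_that("true anchors survive the addition of random decoy hits", {
  gs <- build_genome_set(small_wgd_config(n_genes = 100, codons = 10,
                                          loss = 0, gpc = 20, seed = 12,
                                          decoy_hits = TRUE))
  expect_gt(nrow(gs$hits), nrow(gs$truth))
  anchors <- load_hits(gs$hits, all_genes(gs))
  blocks <- synteny_blocks(anchors, chain_params())
  in_blocks <- unlist(lapply(blocks, function(b)
    paste(b$anchors$gene_a, b$anchors$gene_b)))
  truth_keys <- paste(gs$truth$gene_a, gs$truth$gene_b)
  recovered <- mean(truth_keys %in% in_blocks |
                      paste(gs$truth$gene_b, gs$truth$gene_a) %in% in_blocks)
  expect_gte(recovered, 0.95)
})

test_that("block 4dTv aggregates per-pair values by median", {
  b <- chain_anchors(make_anchors(1:3, 1:3),
                     chain_params(min_anchors = 2))[[1]]
  pv <- data.frame(id_a = paste0("a", 1:3), id_b = paste0("b", 1:3),
                   fourdtv = c(0.1, 0.2, 0.3))
  expect_equal(block_4dtv(b, pv)$block_4dtv, 0.2)
  # symmetric lookup
  pv_rev <- data.frame(id_a = pv$id_b, id_b = pv$id_a,
                       fourdtv = pv$fourdtv)
  expect_equal(block_4dtv(b, pv_rev)$block_4dtv, 0.2)
  # single defined value
  expect_equal(block_4dtv(b, pv[2, ])$block_4dtv, 0.2)
  # even-count median interpolates
  b4 <- chain_anchors(make_anchors(1:4, 1:4),
                      chain_params(min_anchors = 2))[[1]]
  pv4 <- data.frame(id_a = paste0("a", 1:4), id_b = paste0("b", 1:4),
                    fourdtv = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(block_4dtv(b4, pv4)$block_4dtv, 0.25)
  # mean aggregation by flag
  expect_equal(block_4dtv(b4, pv4, agg = "mean")$block_4dtv, 0.25)
  # no defined values: flagged NA
  pv_na <- transform(pv, fourdtv = NA_real_)
  expect_true(is.na(block_4dtv(b, pv_na)$block_4dtv))
})

test_that("chain_anchors rejects multi-chromosome input and empty input is empty", {
  a <- rbind(make_anchors(1:3, 1:3),
             make_anchors(1:3, 1:3, chrom_a = "c9"))
  expect_error(chain_anchors(a, chain_params()), "single chromosome pair")
  expect_length(chain_anchors(make_anchors(integer(0), integer(0)),
                              chain_params()), 0L)
})
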