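# Collinear anchor chaining: turn pairwise homology hits into syntenic
# blocks by dynamic programming over gene-order ranks, then aggregate
# per-pair 4dTv into block-level values.

#' Chaining parameters
#'
#' @param max_gap Maximum number of intervening (skipped) genes allowed
#'   between consecutive anchors, per genome (>= 1).
#' @param min_anchors Minimum anchors for a reported block (>= 2).
#' @param gap_penalty Score deduction per skipped gene per genome.
#' @param anchor_score Score reward per anchor in a chain.
#' @return Object of class `chain_params`.
#' @export
chain_params <- function(max_gap = 10L, min_anchors = 5L, gap_penalty = 1,
                         anchor_score = 10) {
  .check_number(max_gap, "max_gap", lower = 1)
  .check_number(min_anchors, "min_anchors", lower = 2)
  .check_number(gap_penalty, "gap_penalty", lower = 0)
  .check_number(anchor_score, "anchor_score", lower = 0, strict = TRUE)
  structure(list(max_gap = as.integer(max_gap),
                 min_anchors = as.integer(min_anchors),
                 gap_penalty = gap_penalty, anchor_score = anchor_score),
            class = "chain_params")
}

# 0-based gene-order rank within each chromosome, by coordinate sort.
.gene_ranks <- function(genes) {
  genes$rank <- stats::ave(genes$start, genes$chrom,
                           FUN = function(s) rank(s, ties.method = "first")) - 1L
  genes
}

#' Load homology hits as rank-coordinate anchors
#'
#' Resolves each hit's query and subject ids against two gene tables and
#' attaches gene-order ranks (0-based coordinate-sorted index within the
#' chromosome). Anchors use rank coordinates, not base pairs, so gap sizes
#' count skipped genes. Duplicate (query, subject) rows keep the highest
#' score.
#'
#' @param hits Hit table (TSV path or data frame) with columns `qid`, `sid`
#'   and optionally `pident` (used as the anchor score; defaults to 0).
#' @param genes_a,genes_b Gene tables (GFF3 path or data frame) for the query
#'   and subject genome. May be the same object for self-comparison.
#' @return Data frame of anchors: `gene_a, gene_b, chrom_a, chrom_b, rank_a,
#'   rank_b, score`.
#' @export
load_hits <- function(hits, genes_a, genes_b = genes_a) {
  hits <- .as_hit_table(hits)
  ga <- .gene_ranks(.as_gene_table(genes_a))
  gb <- .gene_ranks(.as_gene_table(genes_b))
  ia <- match(hits$qid, ga$gene_id)
  ib <- match(hits$sid, gb$gene_id)
  if (anyNA(ia))
    stop("hit id not in gene annotation: ", hits$qid[which(is.na(ia))[1L]],
         call. = FALSE)
  if (anyNA(ib))
    stop("hit id not in gene annotation: ", hits$sid[which(is.na(ib))[1L]],
         call. = FALSE)
  anchors <- data.frame(
    gene_a = hits$qid, gene_b = hits$sid,
    chrom_a = ga$chrom[ia], chrom_b = gb$chrom[ib],
    rank_a = ga$rank[ia], rank_b = gb$rank[ib],
    score = if ("pident" %in% names(hits)) hits$pident else 0,
    stringsAsFactors = FALSE)
  # duplicate (a,b) hits: keep the highest score
  anchors <- anchors[order(anchors$gene_a, anchors$gene_b,
                           -anchors$score), ]
  anchors <- anchors[!duplicated(anchors[c("gene_a", "gene_b")]), ]
  rownames(anchors) <- NULL
  anchors
}

# Best chain by DP over anchors with ranks (ra, rb), both strictly
# increasing, per-genome gaps <= max_gap. Returns NULL or a list with
# idx (row indices into the input), score, start_ra, len.
.best_chain_dp <- function(ra, rb, params) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  score <- rep(params$anchor_score, n)
  pred <- rep(0L, n)
  start_ra <- ra
  len <- rep(1L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j] - 1L
      db <- rb[i] - rb[j] - 1L
      if (da < 0L || db < 0L || ra[i] == ra[j] || rb[i] == rb[j]) next
      if (da > params$max_gap || db > params$max_gap) next
      cand <- score[j] + params$anchor_score - params$gap_penalty * (da + db)
      better <- cand > score[i] ||
        (cand == score[i] &&
           (start_ra[j] < start_ra[i] ||
              (start_ra[j] == start_ra[i] && len[j] + 1L > len[i])))
      if (better) {
        score[i] <- cand
        pred[i] <- j
        start_ra[i] <- start_ra[j]
        len[i] <- len[j] + 1L
      }
    }
  }
  best <- which(score == max(score))
  if (length(best) > 1L) {
    best <- best[order(start_ra[best], -len[best], ra[best])][1L]
  }
  idx <- integer(0)
  i <- best
  while (i > 0L) { idx <- c(i, idx); i <- pred[i] }
  list(idx = ord[idx], score = score[best], start_ra = start_ra[best],
       len = len[best])
}

#' Chain anchors of one chromosome pair into syntenic blocks
#'
#' Dynamic-programming chaining in the DAGchainer spirit: a chain scores
#' `sum(anchor_score) - sum(gap_penalty * skipped genes)` and must advance
#' gene-order ranks strictly in both genomes, in either the same or the
#' inverted orientation, with at most `max_gap` skipped genes per genome
#' between consecutive anchors. Maximal-scoring non-overlapping chains are
#' extracted greedily (best chain, remove its anchors, repeat); chains
#' shorter than `min_anchors` are dropped. Tandem duplicate anchors (one gene
#' in several hits) collapse to the best-scoring anchor first. Ties between
#' chains break toward the same orientation, then the earlier `rank_a` start,
#' then the longer chain.
#'
#' @param anchors Anchor data frame from [load_hits()]; all rows must belong
#'   to one (chrom_a, chrom_b) pair -- use [synteny_blocks()] to partition a
#'   genome-wide anchor set.
#' @param params A [chain_params()] object.
#' @return List of `syntenic_block` objects, each a list with `anchors`
#'   (ordered data frame), `orientation` (`"same"`/`"inverted"`), `chrom_a`,
#'   `chrom_b`, `block_score`, `block_4dtv` (`NA` until [block_4dtv()]).
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  stopifnot(inherits(params, "chain_params"))
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  if (length(unique(anchors$chrom_a)) > 1L ||
      length(unique(anchors$chrom_b)) > 1L)
    stop("chain_anchors() expects anchors of a single chromosome pair",
         call. = FALSE)
  # collapse tandem duplicates: best score per gene on each side
  anchors <- anchors[order(-anchors$score, anchors$rank_a, anchors$rank_b), ]
  anchors <- anchors[!duplicated(anchors$gene_a), ]
  anchors <- anchors[!duplicated(anchors$gene_b), ]
  anchors <- anchors[order(anchors$rank_a, anchors$rank_b), ]
  rownames(anchors) <- NULL
  blocks <- list()
  pool <- anchors
  while (nrow(pool) > 0L) {
    fwd <- .best_chain_dp(pool$rank_a, pool$rank_b, params)
    rev <- .best_chain_dp(pool$rank_a, -pool$rank_b, params)
    pick_fwd <- fwd$score > rev$score ||
      (fwd$score == rev$score &&
         (fwd$start_ra < rev$start_ra ||
            (fwd$start_ra == rev$start_ra && fwd$len >= rev$len)))
    ch <- if (pick_fwd) fwd else rev
    orientation <- if (pick_fwd) "same" else "inverted"
    rows <- pool[ch$idx, , drop = FALSE]
    rows <- rows[order(rows$rank_a), ]
    rownames(rows) <- NULL
    if (nrow(rows) >= params$min_anchors) {
      blocks[[length(blocks) + 1L]] <- structure(
        list(anchors = rows, orientation = orientation,
             chrom_a = rows$chrom_a[1L], chrom_b = rows$chrom_b[1L],
             block_score = ch$score, block_4dtv = NA_real_),
        class = "syntenic_block")
    }
    pool <- pool[-ch$idx, , drop = FALSE]
  }
  blocks
}

#' @export
print.syntenic_block <- function(x, ...) {
  cat(sprintf("Syntenic block %s ~ %s (%s): %d anchors, score %.1f, 4dTv %s\n",
              x$chrom_a, x$chrom_b, x$orientation, nrow(x$anchors),
              x$block_score,
              if (is.na(x$block_4dtv)) "NA" else format(x$block_4dtv,
                                                        digits = 4)))
  invisible(x)
}

#' Chain a genome-wide anchor set
#'
#' Partitions anchors by (chrom_a, chrom_b) and runs [chain_anchors()] on
#' each partition, assembling blocks with stable identifiers.
#'
#' @inheritParams chain_anchors
#' @return List of `syntenic_block` objects with a `block_id` element added,
#'   ordered by chromosome pair and start rank.
#' @export
synteny_blocks <- function(anchors, params = chain_params()) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  blocks <- list()
  for (k in sort(unique(key))) {
    bs <- chain_anchors(anchors[key == k, , drop = FALSE], params)
    blocks <- c(blocks, bs)
  }
  for (i in seq_along(blocks))
    blocks[[i]]$block_id <- sprintf("B%04d", i)
  blocks
}

#' Aggregate per-pair 4dTv values to the block level
#'
#' Sets each block's `block_4dtv` to the median (default) or mean of the
#' defined per-pair values over the block's anchors. Blocks with no defined
#' pair value keep `NA` and are excluded from dating.
#'
#' @param blocks A `syntenic_block` or list of them.
#' @param pair_values Data frame with the paired gene ids in the first two
#'   columns and a `fourdtv` column (as from [pairs_4dtv()]); lookup is
#'   symmetric in the pair.
#' @param agg `"median"` (default) or `"mean"`.
#' @return The block(s) with `block_4dtv` filled in.
#' @export
block_4dtv <- function(blocks, pair_values, agg = c("median", "mean")) {
  agg <- match.arg(agg)
  single <- inherits(blocks, "syntenic_block")
  if (single) blocks <- list(blocks)
  ids_a <- as.character(pair_values[[1L]])
  ids_b <- as.character(pair_values[[2L]])
  val <- pair_values$fourdtv
  lut <- new.env(parent = emptyenv())
  for (i in seq_along(val)) {
    assign(paste(ids_a[i], ids_b[i], sep = "\r"), val[i], envir = lut)
    assign(paste(ids_b[i], ids_a[i], sep = "\r"), val[i], envir = lut)
  }
  fun <- if (agg == "median") stats::median else mean
  blocks <- lapply(blocks, function(b) {
    keys <- paste(b$anchors$gene_a, b$anchors$gene_b, sep = "\r")
    v <- vapply(keys, function(k)
      if (exists(k, envir = lut)) get(k, envir = lut) else NA_real_,
      numeric(1), USE.NAMES = FALSE)
    v <- v[!is.na(v)]
    b$block_4dtv <- if (length(v)) fun(v) else NA_real_
    b
  })
  if (single) blocks[[1L]] else blocks
}

#' Flat summary table of syntenic blocks
#'
#' @param blocks List of `syntenic_block` objects.
#' @return Data frame: `block_id, chrom_a, chrom_b, orientation, n_anchors,
#'   block_score, block_4dtv`.
#' @export
blocks_table <- function(blocks) {
  if (length(blocks) == 0L)
    return(data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), block_score = numeric(0),
                      block_4dtv = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(blocks, function(b)
    data.frame(block_id = b$block_id %||% NA_character_,
               chrom_a = b$chrom_a, chrom_b = b$chrom_b,
               orientation = b$orientation, n_anchors = nrow(b$anchors),
               block_score = b$block_score, block_4dtv = b$block_4dtv,
               stringsAsFactors = FALSE)))
}

#' Per-anchor table of syntenic blocks
#'
#' @param blocks List of `syntenic_block` objects.
#' @return Data frame of all anchors with their `block_id`.
#' @export
block_anchors_table <- function(blocks) {
  if (length(blocks) == 0L)
    return(data.frame(block_id = character(0), gene_a = character(0),
                      gene_b = character(0), rank_a = integer(0),
                      rank_b = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(blocks, function(b) {
    cbind(data.frame(block_id = b$block_id %||% NA_character_,
                     stringsAsFactors = FALSE),
          b$anchors[, c("gene_a", "gene_b", "rank_a", "rank_b")])
  }))
}
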