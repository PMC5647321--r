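# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle is derived directly from first principles (genetic-code
# table, exhaustive enumeration, closed forms) and never calls the code path
# it checks.

sense_codons <- function() {
  bases <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all[Biostrings::GENETIC_CODE[all] != "*"]
}

# Oracle: is this codon in a four-fold degenerate family? Enumerated from the
# genetic-code table: all four third-position variants must be sense codons
# encoding the same amino acid.
bf_is_fourfold <- function(codon) {
  fam <- paste0(substr(codon, 1, 2), c("T", "C", "A", "G"))
  aa <- Biostrings::GENETIC_CODE[fam]
  all(aa != "*") && length(unique(aa)) == 1L
}

# Oracle: random in-frame CDS of n codons (sense codons only).
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Oracle: exhaustive maximum chain score over all ordered anchor subsets of
# size >= 2 (same or inverted orientation), honouring max_gap per genome.
bf_best_chain_score <- function(ra, rb, params) {
  n <- length(ra)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 2L) next
    idx <- idx[order(ra[idx])]
    da <- diff(ra[idx])
    db <- diff(rb[idx])
    if (any(da <= 0L)) next
    ok_same <- all(db > 0L) && all(da - 1L <= params$max_gap) &&
      all(db - 1L <= params$max_gap)
    ok_inv <- all(db < 0L) && all(da - 1L <= params$max_gap) &&
      all(-db - 1L <= params$max_gap)
    if (!ok_same && !ok_inv) next
    gaps <- sum(da - 1L) + sum(abs(db) - 1L)
    s <- length(idx) * params$anchor_score - params$gap_penalty * gaps
    if (s > best) best <- s
  }
  best
}

# Oracle: exact hypergeometric upper tail by direct summation of binomial
# coefficients.
bf_hyper_tail <- function(k, n, K, N) {
  i <- seq(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Oracle: exhaustive global affine-gap alignment score by enumerating every
# monotone alignment path of two short sequences and scoring each path with
# the gap rule "each maximal gap run of length L costs open + L * ext".
bf_align_score <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, cols) {
    if (i > length(a) && j > length(b)) {
      score <- 0
      gap_len_a <- gap_len_b <- 0L
      for (cc in cols) {
        if (cc[1] == "-") {
          gap_len_a <- gap_len_a + 1L
        } else if (gap_len_a > 0L) {
          score <- score - open - ext * gap_len_a; gap_len_a <- 0L
        }
        if (cc[2] == "-") {
          gap_len_b <- gap_len_b + 1L
        } else if (gap_len_b > 0L) {
          score <- score - open - ext * gap_len_b; gap_len_b <- 0L
        }
        if (cc[1] != "-" && cc[2] != "-")
          score <- score + mat[cc[1], cc[2]]
      }
      if (gap_len_a > 0L) score <- score - open - ext * gap_len_a
      if (gap_len_b > 0L) score <- score - open - ext * gap_len_b
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1L, j + 1L, c(cols, list(c(a[i], b[j]))))
    if (i <= length(a))
      rec(i + 1L, j, c(cols, list(c(a[i], "-"))))
    if (j <= length(b))
      rec(i, j + 1L, c(cols, list(c("-", b[j]))))
  }
  rec(1L, 1L, list())
  best
}

# Build an ungapped codon pair alignment from an ancestor evolved down two
# lineages (tau/2 each), bypassing the aligner.
evolved_pair_alignment <- function(anc, tau, kappa = 2, seed = 1) {
  a <- evolve_k2p(anc, tau / 2, kappa = kappa, seed = seed)
  b <- evolve_k2p(anc, tau / 2, kappa = kappa, seed = seed + 1000003L)
  codon_pair_alignment(a, b)
}

# Small single-WGD simulation config used by several tests.
small_wgd_config <- function(n_genes = 30, codons = 30, tau4dtv = 0.042,
                             loss = 0, seed = 7, gpc = 10, ...) {
  sim_config(n_genes = n_genes, codons_per_gene = codons,
             events = list(list(kind = "wgd",
                                tau = tau_for_target_4dtv(tau4dtv))),
             loss_prob = loss, seed = seed, genes_per_chromosome = gpc, ...)
}

# The canonical three-level scenario: two outgroup speciations plus a
# triplicating WGD.
three_level_config <- function(n_genes = 48, codons = 60, loss = 0.1,
                               seed = 3, gpc = 12) {
  sim_config(n_genes = n_genes, codons_per_gene = codons,
             events = allohexaploid_events(),
             loss_prob = loss, seed = seed, genes_per_chromosome = gpc)
}
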