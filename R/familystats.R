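# Gene-family statistics: hypergeometric domain over-representation,
# expansion profiles from amino-acid p-distances, and qPCR delta-delta-Ct
# fold changes.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of drawing at least `k` domain-positive genes when
#' `n` genes are drawn without replacement from a universe of `N` genes of
#' which `K` carry the domain:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' One-sided (over-representation) only. Computed via the exact
#' log-space hypergeometric tail of \code{stats::phyper}.
#'
#' @param k Focal genes carrying the domain (vectorised).
#' @param n Focal genome gene count (draw size).
#' @param K Domain-positive genes in the universe.
#' @param N Universe gene count.
#' @return Upper-tail p-value(s) in (0, 1].
#' @export
hypergeometric_enrichment <- function(k, n, K, N) {
  if (any(is.na(c(k, n, K, N))) || any(c(k, n, K, N) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(n > N) || any(K > N))
    stop("impossible table: n and K must not exceed N", call. = FALSE)
  if (any(k > K) || any(k > n))
    stop("impossible table: k must not exceed min(n, K)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Domain over-representation scan for a focal genome
#'
#' Counts, per domain accession, the genes carrying the domain in the focal
#' genome versus a multi-genome background, and tests over-representation
#' with [hypergeometric_enrichment()]. A gene counts once per domain
#' regardless of repeated annotation rows. Two universe conventions are
#' offered: `"union"` (default) draws the focal genome's genes from the union
#' of all genomes including the focal one; `"others"` treats the non-focal
#' genomes alone as the sampling universe.
#'
#' @param annotations Data frame (or TSV path) with columns `gene_id`,
#'   `genome_id`, `domain_accession`. Every gene of every genome must appear
#'   (genes without domains may carry an empty accession).
#' @param focal_genome Genome id tested for over-representation.
#' @param domains Optional character vector restricting the scan.
#' @param background `"union"` or `"others"`.
#' @param adjust If `TRUE`, add Benjamini-Hochberg adjusted p-values.
#' @return Data frame: `domain, k, n, K, N, p` (and `p_adj` if requested),
#'   ordered by `p`.
#' @export
domain_enrichment <- function(annotations, focal_genome, domains = NULL,
                              background = c("union", "others"),
                              adjust = FALSE) {
  background <- match.arg(background)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- .read_tsv(annotations)
  need <- c("gene_id", "genome_id", "domain_accession")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns gene_id, genome_id, domain_accession",
         call. = FALSE)
  if (!focal_genome %in% annotations$genome_id)
    stop("focal genome not present: ", focal_genome, call. = FALSE)
  ann <- annotations[!is.na(annotations$domain_accession) &
                       annotations$domain_accession != "", , drop = FALSE]
  focal <- annotations$genome_id == focal_genome
  n <- length(unique(annotations$gene_id[focal]))
  in_universe <- if (background == "union") rep(TRUE, nrow(annotations))
                 else !focal
  N <- length(unique(annotations$gene_id[in_universe]))
  if (is.null(domains))
    domains <- sort(unique(ann$domain_accession[ann$genome_id ==
                                                  focal_genome]))
  rows <- lapply(domains, function(dom) {
    with_dom <- ann$domain_accession == dom
    k <- length(unique(ann$gene_id[with_dom & ann$genome_id == focal_genome]))
    uni_dom <- if (background == "union") with_dom
               else with_dom & ann$genome_id != focal_genome
    K <- length(unique(ann$gene_id[uni_dom]))
    # under the background-only universe k can exceed K; the tail is then
    # evaluated at the largest attainable overlap
    p <- hypergeometric_enrichment(min(k, K, n), n, K, N)
    data.frame(domain = dom, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise amino-acid p-distances within a gene family
#'
#' Globally aligns every pair of family members (BLOSUM62, affine gaps) and
#' computes the p-distance over gap-free columns.
#'
#' @param proteins Named character vector of protein sequences (>= 2).
#' @param ... Alignment parameters passed through to
#'   \code{Biostrings::pairwiseAlignment}.
#' @return Data frame: `id_a, id_b, p_distance`.
#' @export
family_pdistances <- function(proteins, ...) {
  if (length(proteins) < 2L)
    stop("a family needs at least 2 members", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("m", seq_along(proteins))
  mat <- .score_matrix("BLOSUM62")
  idx <- utils::combn(length(proteins), 2L)
  rows <- apply(idx, 2L, function(ij) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[ij[1L]]]),
      Biostrings::AAString(proteins[[ij[2L]]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, ...)
    d <- compute_aa_distance(as.character(Biostrings::pattern(pa)),
                             as.character(Biostrings::subject(pa)))
    data.frame(id_a = names(proteins)[ij[1L]],
               id_b = names(proteins)[ij[2L]],
               p_distance = d$p_distance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expansion profile of a gene family
#'
#' Histogram of within-family pairwise amino-acid p-distances and the
#' fraction of pairs below a low-divergence threshold. A recently expanded
#' family (e.g. after polyploidization) shows an excess of near-zero
#' distances.
#'
#' @param proteins Named character vector of family member proteins (>= 2);
#'   alternatively supply precomputed `distances`.
#' @param distances Numeric vector of pairwise p-distances in [0, 1].
#' @param bin_width Histogram bin width (default 0.02).
#' @param low_threshold Distance below which a pair counts as low-divergence
#'   (default 0.05).
#' @param family_id Optional label.
#' @return Object of class `expansion_profile`: list with `family_id`,
#'   `distances`, `breaks`, `counts`, `bin_width`,
#'   `low_divergence_fraction`.
#' @export
expansion_profile <- function(proteins = NULL, distances = NULL,
                              bin_width = 0.02, low_threshold = 0.05,
                              family_id = NULL) {
  if (is.null(distances)) {
    if (is.null(proteins))
      stop("supply `proteins` or `distances`", call. = FALSE)
    distances <- family_pdistances(proteins)$p_distance
  }
  distances <- distances[!is.na(distances)]
  if (length(distances) < 1L)
    stop("a family needs at least 2 members (1 pairwise distance)",
         call. = FALSE)
  if (any(distances < 0 | distances > 1))
    stop("p-distances must lie in [0, 1]", call. = FALSE)
  breaks <- seq(0, max(1e-12, ceiling(max(distances) / bin_width)) *
                  bin_width + bin_width, by = bin_width)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE,
                      right = FALSE)
  structure(list(family_id = family_id, distances = distances,
                 breaks = h$breaks, counts = h$counts,
                 bin_width = bin_width,
                 low_divergence_fraction = mean(distances < low_threshold)),
            class = "expansion_profile")
}

#' @export
print.expansion_profile <- function(x, ...) {
  cat(sprintf("Expansion profile%s: %d pairs, %.1f%% below low-divergence threshold\n",
              if (is.null(x$family_id)) "" else paste0(" [", x$family_id, "]"),
              length(x$distances), 100 * x$low_divergence_fraction))
  invisible(x)
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Fold change of a target gene relative to a reference (internal control)
#' gene between a treatment and a control condition:
#' \eqn{2^{-\Delta\Delta C_T}} with
#' \eqn{\Delta\Delta C_T = (C_T^{target} - C_T^{ref})_{treat} -
#' (C_T^{target} - C_T^{ref})_{control}}.
#'
#' @param target_ct,reference_ct Treatment cycle thresholds of target and
#'   reference gene (vectorised).
#' @param control_target_ct,control_reference_ct Control-condition cycle
#'   thresholds.
#' @return Fold change(s); 1 when treatment and control measurements match.
#' @export
fold_change_ddct <- function(target_ct, reference_ct,
                             control_target_ct, control_reference_ct) {
  all_ct <- c(target_ct, reference_ct, control_target_ct,
              control_reference_ct)
  if (any(!is.finite(all_ct)) || any(all_ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  ddct <- (target_ct - reference_ct) -
    (control_target_ct - control_reference_ct)
  2^(-ddct)
}
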