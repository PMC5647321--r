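# Codon-level pair statistics: protein-guided codon alignment, four-fold
# degenerate site identification, the 4dTv statistic, and amino-acid
# p-distances.

# Codon families whose third position is fully degenerate under the standard
# genetic code, keyed by the first two codon positions.
.FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Construct a codon pair alignment
#'
#' A codon pair alignment holds two gap-containing CDS strings of equal
#' aligned length, in frame: gaps occur only in multiples of three, so the
#' alignment can be read codon by codon. Usually produced by
#' [align_pair_codon_aware()]; this constructor validates hand-built ones.
#'
#' @param aln_a,aln_b Aligned nucleotide strings (gaps as `-`), equal length
#'   divisible by 3; ungapped characters over A/C/G/T/N.
#' @param id_a,id_b Gene identifiers.
#' @return Object of class `codon_pair_alignment`.
#' @export
codon_pair_alignment <- function(aln_a, aln_b, id_a = "a", id_b = "b") {
  aln_a <- toupper(as.character(aln_a))
  aln_b <- toupper(as.character(aln_b))
  if (nchar(aln_a) != nchar(aln_b))
    stop("aligned lengths differ", call. = FALSE)
  if (nchar(aln_a) %% 3L != 0L)
    stop("aligned length must be divisible by 3", call. = FALSE)
  if (grepl("[^ACGTN-]", aln_a) || grepl("[^ACGTN-]", aln_b))
    stop("alignment characters must be A/C/G/T/N or '-'", call. = FALSE)
  structure(list(id_a = id_a, id_b = id_b, aln_a = aln_a, aln_b = aln_b),
            class = "codon_pair_alignment")
}

#' @export
print.codon_pair_alignment <- function(x, ...) {
  cat(sprintf("Codon pair alignment %s / %s: %d columns (%d codons)\n",
              x$id_a, x$id_b, nchar(x$aln_a), nchar(x$aln_a) %/% 3L))
  invisible(x)
}

# Split an aligned in-frame string into codon triplets.
.codons_of <- function(aln) {
  n <- nchar(aln)
  substring(aln, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Cached lookups: codon -> amino acid (standard code, stops as "*"), and the
# protein scoring matrices shipped with Biostrings.
.codonstats_cache <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.codonstats_cache$code)) {
    code <- Biostrings::GENETIC_CODE
    .codonstats_cache$code <- stats::setNames(as.character(code),
                                              names(code))
  }
  .codonstats_cache$code
}

.score_matrix <- function(name) {
  if (is.null(.codonstats_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .codonstats_cache[[name]] <- get(name, envir = e)
  }
  .codonstats_cache[[name]]
}

# Translate an in-frame CDS; codons containing ambiguity become "X".
.translate_cds <- function(cds) {
  aa <- .codon_table()[.codons_of(cds)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Protein-guided codon-aware pairwise alignment
#'
#' Translates both CDS under the standard genetic code (internal stop codons
#' become the `*` residue and are aligned like any other), aligns the proteins
#' globally (Needleman-Wunsch with a substitution matrix and affine gaps via
#' \pkg{Biostrings}), and back-translates the protein alignment to a codon
#' alignment, so gaps always appear in multiples of three.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`); a trailing
#'   incomplete codon is trimmed.
#' @param id_a,id_b Identifiers carried into the result.
#' @param substitution_matrix Protein scoring matrix name (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties in matrix units
#'   (defaults 11 and 1).
#' @return A [codon_pair_alignment()].
#' @export
align_pair_codon_aware <- function(cds_a, cds_b, id_a = "a", id_b = "b",
                                   substitution_matrix = "BLOSUM62",
                                   gap_opening = 11, gap_extension = 1) {
  cds_a <- toupper(as.character(cds_a))
  cds_b <- toupper(as.character(cds_b))
  cds_a <- substr(cds_a, 1L, nchar(cds_a) - nchar(cds_a) %% 3L)
  cds_b <- substr(cds_b, 1L, nchar(cds_b) - nchar(cds_b) %% 3L)
  if (nchar(cds_a) == 0L || nchar(cds_b) == 0L)
    stop("empty sequence", call. = FALSE)
  prot_a <- .translate_cds(cds_a)
  prot_b <- .translate_cds(cds_b)
  mat <- .score_matrix(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  res_a <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  res_b <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  cod_a <- .codons_of(cds_a)
  cod_b <- .codons_of(cds_b)
  ia <- ib <- 0L
  out_a <- out_b <- character(length(res_a))
  for (i in seq_along(res_a)) {
    if (res_a[i] == "-") out_a[i] <- "---"
    else { ia <- ia + 1L; out_a[i] <- cod_a[ia] }
    if (res_b[i] == "-") out_b[i] <- "---"
    else { ib <- ib + 1L; out_b[i] <- cod_b[ib] }
  }
  codon_pair_alignment(paste(out_a, collapse = ""),
                       paste(out_b, collapse = ""), id_a, id_b)
}

#' Identify four-fold degenerate sites in a codon pair alignment
#'
#' A third-position column is counted as a four-fold degenerate site iff
#' (i) neither codon of the pair contains a gap or ambiguity, (ii) both
#' codons belong to a four-fold degenerate family (CTN, GTN, TCN, CCN, ACN,
#' GCN, CGN, GGN), and (iii) the first two codon positions are identical
#' between the two genes. Condition (iii) is the conservative convention:
#' it avoids third positions whose degeneracy class could differ between the
#' pair.
#'
#' @param aln A [codon_pair_alignment()].
#' @return Integer vector of 1-based alignment column indices (third codon
#'   positions); possibly empty.
#' @export
identify_fourfold_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  ca <- .codons_of(aln$aln_a)
  cb <- .codons_of(aln$aln_b)
  clean <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  pa <- substr(ca, 1L, 2L)
  keep <- clean & pa == substr(cb, 1L, 2L) & pa %in% .FOURFOLD_PREFIXES
  3L * which(keep)
}

#' Classify a nucleotide substitution
#'
#' @param base_a,base_b Single bases in A/C/G/T (vectorised).
#' @return Character vector over `"identical"`, `"transition"` (A<->G,
#'   C<->T), `"transversion"`.
#' @export
classify_substitution <- function(base_a, base_b) {
  base_a <- toupper(base_a); base_b <- toupper(base_b)
  ok <- c("A", "C", "G", "T")
  if (!all(base_a %in% ok) || !all(base_b %in% ok))
    stop("ambiguous base: caller must filter to A/C/G/T", call. = FALSE)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ifelse(base_a == base_b, "identical",
         ifelse(purine[base_a] == purine[base_b], "transition",
                "transversion"))
}

#' Compute the 4dTv statistic of a codon pair alignment
#'
#' 4dTv is the fraction of four-fold degenerate sites (per
#' [identify_fourfold_sites()]) whose third-position pair differs by a
#' transversion. The raw proportion is reported by default; `correct = TRUE`
#' applies the two-state saturation correction \eqn{-\log(1 - 2Q)/2} instead.
#'
#' @param aln A [codon_pair_alignment()].
#' @param correct Apply the multiple-hit correction (default `FALSE`).
#' @return Object of class `fourdtv_result`: list with `n_4d_sites`,
#'   `n_transversions`, `n_transitions`, `fourdtv` (`NA` and `defined =
#'   FALSE` when no four-fold site exists, or when the corrected value would
#'   be saturated).
#' @export
compute_4dtv <- function(aln, correct = FALSE) {
  sites <- identify_fourfold_sites(aln)
  n <- length(sites)
  if (n == 0L) {
    res <- list(id_a = aln$id_a, id_b = aln$id_b, n_4d_sites = 0L,
                n_transversions = 0L, n_transitions = 0L,
                fourdtv = NA_real_, defined = FALSE)
    return(structure(res, class = "fourdtv_result"))
  }
  ba <- substring(aln$aln_a, sites, sites)
  bb <- substring(aln$aln_b, sites, sites)
  cls <- classify_substitution(ba, bb)
  n_tv <- sum(cls == "transversion")
  n_ts <- sum(cls == "transition")
  q <- n_tv / n
  value <- q
  defined <- TRUE
  if (correct) {
    if (q >= 0.5) { value <- NA_real_; defined <- FALSE }
    else value <- -0.5 * log(1 - 2 * q)
  }
  structure(list(id_a = aln$id_a, id_b = aln$id_b, n_4d_sites = n,
                 n_transversions = n_tv, n_transitions = n_ts,
                 fourdtv = value, defined = defined),
            class = "fourdtv_result")
}

#' @export
print.fourdtv_result <- function(x, ...) {
  cat(sprintf("4dTv(%s, %s): %s  [%d transversions / %d four-fold sites]\n",
              x$id_a, x$id_b,
              if (x$defined) format(x$fourdtv, digits = 4) else "undefined",
              x$n_transversions, x$n_4d_sites))
  invisible(x)
}

#' Amino-acid distance of an aligned protein pair
#'
#' p-distance over gap-free columns, with the Poisson correction
#' \eqn{-\log(1 - p)}.
#'
#' @param protein_aln_a,protein_aln_b Aligned protein strings of equal length
#'   (gaps as `-`).
#' @return List with `p_distance`, `poisson_corrected` (`NA` when p = 1),
#'   `n_sites`, `defined` (`FALSE` when no gap-free column exists).
#' @export
compute_aa_distance <- function(protein_aln_a, protein_aln_b) {
  a <- strsplit(toupper(as.character(protein_aln_a)), "")[[1]]
  b <- strsplit(toupper(as.character(protein_aln_b)), "")[[1]]
  if (length(a) != length(b)) stop("aligned lengths differ", call. = FALSE)
  keep <- a != "-" & b != "-"
  n <- sum(keep)
  if (n == 0L)
    return(list(p_distance = NA_real_, poisson_corrected = NA_real_,
                n_sites = 0L, defined = FALSE))
  p <- mean(a[keep] != b[keep])
  list(p_distance = p,
       poisson_corrected = if (p < 1) -log(1 - p) else NA_real_,
       n_sites = n, defined = TRUE)
}

# Protein alignment strings from a codon alignment (gap codon -> "-").
.protein_alignment <- function(aln) {
  tr <- function(s) {
    cods <- .codons_of(s)
    out <- character(length(cods))
    gap <- cods == "---"
    out[gap] <- "-"
    if (any(!gap)) {
      prot <- .translate_cds(paste(cods[!gap], collapse = ""))
      out[!gap] <- strsplit(prot, "")[[1]]
    }
    paste(out, collapse = "")
  }
  list(a = tr(aln$aln_a), b = tr(aln$aln_b))
}

#' Per-pair 4dTv table for a list of gene pairs
#'
#' Drives [align_pair_codon_aware()] and [compute_4dtv()] over a pair list
#' (e.g. a homology hit table) against a pooled CDS set, also reporting the
#' protein p-distance of each aligned pair.
#'
#' @param cds Named character vector of CDS, a `DNAStringSet`, or a FASTA
#'   path.
#' @param pairs Data frame with the first two columns naming the paired genes
#'   (e.g. `qid`/`sid` or `id_a`/`id_b`), or a TSV path.
#' @param correct Passed to [compute_4dtv()].
#' @param ... Passed to [align_pair_codon_aware()].
#' @return Data frame with columns `id_a, id_b, n_4d_sites, n_transversions,
#'   n_transitions, fourdtv, p_distance`.
#' @export
pairs_4dtv <- function(cds, pairs, correct = FALSE, ...) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- read_cds_fasta(cds)
  if (methods::is(cds, "DNAStringSet")) cds <- as.character(cds)
  if (is.character(pairs) && length(pairs) == 1L) pairs <- .read_tsv(pairs)
  ids_a <- as.character(pairs[[1L]])
  ids_b <- as.character(pairs[[2L]])
  missing <- setdiff(unique(c(ids_a, ids_b)), names(cds))
  if (length(missing))
    stop("gene id(s) not in CDS set: ", paste(utils::head(missing, 5),
                                              collapse = ", "), call. = FALSE)
  n <- length(ids_a)
  out <- data.frame(id_a = ids_a, id_b = ids_b,
                    n_4d_sites = integer(n), n_transversions = integer(n),
                    n_transitions = integer(n), fourdtv = NA_real_,
                    p_distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    aln <- align_pair_codon_aware(cds[[ids_a[i]]], cds[[ids_b[i]]],
                                  id_a = ids_a[i], id_b = ids_b[i], ...)
    r <- compute_4dtv(aln, correct = correct)
    out$n_4d_sites[i] <- r$n_4d_sites
    out$n_transversions[i] <- r$n_transversions
    out$n_transitions[i] <- r$n_transitions
    out$fourdtv[i] <- r$fourdtv
    pr <- .protein_alignment(aln)
    out$p_distance[i] <- compute_aa_distance(pr$a, pr$b)$p_distance
  }
  out
}
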