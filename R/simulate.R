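# Synthetic allopolyploid genome simulator.
#
# Generates CDS sets, gene coordinates, homology hit tables and a ground-truth
# divergence table for an allopolyploid scenario: a focal genome carrying one
# or more whole-genome duplications (WGD), plus outgroup genomes split off at
# deeper speciation events. Sequence divergence follows a Kimura two-parameter
# process parameterised directly in transversion-rate time (beta*tau), so the
# expected transversion fraction between two copies separated by total
# divergence tau is Q(tau) = (1 - exp(-4*tau)) / 2 -- the quantity the 4dTv
# statistic estimates at four-fold degenerate sites.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all, .STOP_CODONS)
}

#' Simulation configuration for a synthetic allopolyploid genome set
#'
#' Bundles and validates all parameters of the genome simulator. Divergence is
#' expressed in transversion-rate time units (beta*tau): an event with
#' divergence parameter `tau` separates gene copies whose expected four-fold
#' transversion fraction is \eqn{Q(\tau) = (1 - e^{-4\tau})/2}. Events must be
#' listed deepest (largest tau) first; calendar time never enters the
#' simulator.
#'
#' @param n_genes Number of ancestral genes (>= 1).
#' @param codons_per_gene Gene length in codons, including the start and stop
#'   codon (>= 10).
#' @param events List of events, each a list with `kind` (`"wgd"` or
#'   `"speciation"`) and `tau` (total pairwise divergence of the copies the
#'   event separates, in beta*tau units). A `"wgd"` event may carry `copies`
#'   (default 2); `copies = 3` models a hexaploid whose three subgenomes share
#'   one divergence level. Taus must be strictly positive and strictly
#'   decreasing (deeper events first).
#' @param kappa Transition/transversion rate ratio (kappa = alpha/beta > 0).
#' @param loss_prob Per-copy post-duplication retention failure probability in
#'   [0, 1): after a WGD each resulting copy is independently lost with this
#'   probability, so a retained paralog pair occurs with probability
#'   (1 - loss_prob)^2.
#' @param seed Integer root RNG seed; per-gene substreams are derived by stable
#'   hashing of gene identifiers, so outputs are byte-reproducible and
#'   independent of processing order.
#' @param genes_per_chromosome Genes laid out per ancestral chromosome;
#'   controls the collinear block structure downstream synteny chaining sees.
#' @param decoy_hits If `TRUE`, the emitted hit table additionally contains
#'   uniform-random decoy hits between unrelated genes.
#' @param decoy_frac Decoy hit count as a fraction of true hit count.
#'
#' @return An object of class `sim_config`.
#' @seealso [build_genome_set()], [tau_for_target_4dtv()],
#'   [allohexaploid_events()]
#' @export
sim_config <- function(n_genes, codons_per_gene, events, kappa = 2,
                       loss_prob = 0, seed = 1L, genes_per_chromosome = 25L,
                       decoy_hits = FALSE, decoy_frac = 0.05) {
  .check_number(n_genes, "n_genes", lower = 1)
  if (!is.numeric(codons_per_gene) || length(codons_per_gene) != 1L ||
      is.na(codons_per_gene) || codons_per_gene < 10)
    stop("invalid config: `codons_per_gene` must be >= 10", call. = FALSE)
  .check_number(kappa, "kappa", lower = 0, strict = TRUE)
  .check_number(loss_prob, "loss_prob", lower = 0)
  if (loss_prob >= 1) stop("`loss_prob` must be < 1", call. = FALSE)
  .check_number(genes_per_chromosome, "genes_per_chromosome", lower = 1)
  if (!is.list(events) || length(events) == 0L)
    stop("`events` must be a non-empty list", call. = FALSE)
  events <- lapply(events, function(ev) {
    if (is.null(ev$kind) || !ev$kind %in% c("wgd", "speciation"))
      stop("event `kind` must be \"wgd\" or \"speciation\"", call. = FALSE)
    .check_number(ev$tau, "tau", lower = 0, strict = TRUE)
    if (ev$kind == "wgd") {
      ev$copies <- as.integer(ev$copies %||% 2L)
      if (ev$copies < 2L) stop("wgd `copies` must be >= 2", call. = FALSE)
    } else {
      ev$copies <- NULL
    }
    ev
  })
  taus <- vapply(events, `[[`, numeric(1), "tau")
  if (length(taus) > 1L && any(diff(taus) >= 0))
    stop("event taus must be strictly decreasing (deepest event first)",
         call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         events = events, kappa = kappa, loss_prob = loss_prob,
         seed = as.integer(seed),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         decoy_hits = isTRUE(decoy_hits), decoy_frac = decoy_frac),
    class = "sim_config")
}

#' Event list for an allohexaploid with two outgroups
#'
#' Convenience constructor for the canonical scenario this package targets:
#' two diploid outgroup lineages split at deep speciation events, and a focal
#' hexaploid whose three subgenomes derive from one shallow
#' polyploidization/hybridization event (all three pairwise subgenome
#' divergences at a single level). Event taus are set from target 4dTv values
#' via [tau_for_target_4dtv()].
#'
#' @param paralog_4dtv Target 4dTv of the within-genome (subgenome) paralog
#'   peak.
#' @param ortholog_4dtv Target 4dTv values of the ortholog peaks to each
#'   outgroup, deepest first.
#' @param copies Number of subgenome copies produced by the polyploidization
#'   event.
#' @return An event list suitable for [sim_config()].
#' @export
allohexaploid_events <- function(paralog_4dtv = 0.042,
                                 ortholog_4dtv = c(0.27, 0.16),
                                 copies = 3L) {
  ortholog_4dtv <- sort(ortholog_4dtv, decreasing = TRUE)
  if (length(ortholog_4dtv) && min(ortholog_4dtv) <= paralog_4dtv)
    stop("ortholog peaks must be deeper than the paralog peak", call. = FALSE)
  ev <- lapply(ortholog_4dtv, function(x)
    list(kind = "speciation", tau = tau_for_target_4dtv(x)))
  c(ev, list(list(kind = "wgd", tau = tau_for_target_4dtv(paralog_4dtv),
                  copies = as.integer(copies))))
}

#' Divergence parameter for a target 4dTv value
#'
#' Inverts the saturation curve \eqn{Q(\tau) = (1 - e^{-4\tau})/2} of the
#' two-state transversion class process, returning the total pairwise
#' divergence tau (in beta*tau units) at which the expected transversion
#' fraction at neutral sites equals `x`. Lets simulations be parameterised by
#' observed 4dTv peak positions.
#'
#' @param x Target 4dTv in [0, 0.5); the statistic saturates at 0.5.
#' @return tau = -log(1 - 2x) / 4 (vectorised).
#' @examples
#' tau_for_target_4dtv(0.042)  # ~0.021936
#' @export
tau_for_target_4dtv <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x >= 0.5))
    stop("target 4dTv must lie in [0, 0.5): the statistic saturates at 0.5",
         call. = FALSE)
  -log(1 - 2 * x) / 4
}

#' Simulate ancestral protein-coding genes
#'
#' Draws `n_genes` random CDS of `codons_per_gene` codons each: an ATG start,
#' internal codons sampled uniformly from the 61 sense codons, and a terminal
#' stop codon. Each gene uses an RNG substream derived from the root seed and
#' its identifier, so the set is deterministic and order-independent.
#'
#' @param config A [sim_config()] object.
#' @return Named character vector of CDS (names are gene ids `g0001`, ...).
#' @export
simulate_ancestral_genes <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  sense <- .sense_codons()
  width <- max(4L, nchar(as.character(config$n_genes)))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(config$n_genes))
  cds <- vapply(ids, function(id) {
    with_seed(stream_seed(config$seed, paste0(id, ":anc")), {
      internal <- sample(sense, config$codons_per_gene - 2L, replace = TRUE)
      paste0("ATG", paste(internal, collapse = ""),
             sample(.STOP_CODONS, 1L))
    })
  }, character(1))
  names(cds) <- ids
  cds
}

#' Evolve a nucleotide sequence under a Kimura two-parameter process
#'
#' Applies site-independent substitutions with transition rate kappa*beta and
#' two transversion rates beta each, run for a duration such that beta*t =
#' `tau`. The expected fraction of transversion differences between input and
#' output is \eqn{Q(\tau) = (1 - e^{-4\tau})/2}; because the transversion
#' class process is a symmetric two-state chain, this expectation is additive
#' along branches regardless of the starting sequence. Protein-coding validity
#' is not enforced: evolved sequences may contain internal stop codons, which
#' downstream codon statistics handle.
#'
#' @param seq A nucleotide sequence over A/C/G/T (character scalar or
#'   [Biostrings::DNAString]).
#' @param tau Total divergence in beta*tau units (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param seed Optional integer seed; if given, the caller's RNG state is left
#'   untouched.
#' @return The evolved sequence as a character scalar.
#' @export
evolve_k2p <- function(seq, tau, kappa = 2, seed = NULL) {
  .check_number(tau, "tau", lower = 0)
  .check_number(kappa, "kappa", lower = 0, strict = TRUE)
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  if (length(s) == 0L) stop("empty sequence")
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence must be over {A,C,G,T}")
  if (tau == 0) return(paste(s, collapse = ""))
  run <- function() {
    e4 <- exp(-4 * tau)
    p_tv <- 0.25 * (1 - e4)  # each of the two transversion targets
    p_ts <- 0.25 + 0.25 * e4 - 0.5 * exp(-2 * (kappa + 1) * tau)
    p_same <- 1 - p_ts - 2 * p_tv
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    u <- stats::runif(length(s))
    out <- s
    i <- u >= p_same & u < p_same + p_ts
    out[i] <- ts_map[s[i]]
    i <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
    out[i] <- tv1[s[i]]
    i <- u >= p_same + p_ts + p_tv
    out[i] <- tv2[s[i]]
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Evolve helper used by build_genome_set: branch seeds are derived from the
# root seed, gene id and a branch key, so every branch has its own stream.
.evolve_branch <- function(seq, tau, config, gene, key) {
  if (tau <= 0) return(seq)
  evolve_k2p(seq, tau, kappa = config$kappa,
             seed = stream_seed(config$seed, paste(gene, key, sep = "|")))
}

#' Build a complete synthetic genome set
#'
#' Runs the event tree over every ancestral gene: speciation events split off
#' outgroup genomes that then evolve to the present; WGD events replicate every
#' focal gene lineage into `copies` subgenome copies, each independently
#' retained with probability 1 - `loss_prob`. Gene order within chromosomes is
#' preserved in every copy (dropped genes removed), so true homologs form
#' perfectly collinear runs. The emitted hit table lists every true homolog
#' pair with gene coordinates, emulating an all-vs-all protein search result
#' (optionally with random decoy hits); the truth table records each pair's
#' relation, true divergence and expected 4dTv.
#'
#' @param config A [sim_config()] with at least one WGD event.
#' @return An object of class `genome_set`: a list with elements
#'   `genomes` (per genome: `cds` named character vector and `genes`
#'   data frame with `gene_id`, `chrom`, `start`, `end`, `strand`),
#'   `hits` (data frame with columns `qid, sid, pident, length, qchrom,
#'   qstart, qend, schrom, sstart, send`), `truth` (data frame with
#'   `gene_a, gene_b, relation, true_tau, expected_4dtv`), and `config`.
#' @export
build_genome_set <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  if (!any(vapply(config$events, `[[`, character(1), "kind") == "wgd"))
    stop("config must contain at least one wgd event")
  anc <- simulate_ancestral_genes(config)
  events <- config$events
  depths <- vapply(events, `[[`, numeric(1), "tau") / 2
  n_out <- 0L
  out_names <- character(0)
  for (ev in events) if (ev$kind == "speciation") {
    n_out <- n_out + 1L
    out_names <- c(out_names, paste0("out", n_out))
  }
  genome_names <- c("focal", out_names)

  # tips[[genome]] is a list of per-gene tip lists:
  # list(gene, sub, seq, path); path[i] = branch label taken at event i.
  tip_rows <- list()
  for (gi in seq_along(anc)) {
    gene <- names(anc)[gi]
    lineages <- list(list(sub = "", seq = anc[[gene]],
                          path = character(length(events))))
    og_idx <- 0L
    prev_depth <- depths[1L]
    for (i in seq_along(events)) {
      ev <- events[[i]]
      d <- depths[i]
      seg <- prev_depth - d
      if (seg > 0) {
        lineages <- lapply(lineages, function(ln) {
          ln$seq <- .evolve_branch(ln$seq, seg, config, gene,
                                   paste0("F", ln$sub, ":seg", i))
          ln
        })
      }
      if (ev$kind == "speciation") {
        og_idx <- og_idx + 1L
        gname <- paste0("out", og_idx)
        for (ln in lineages) {
          path <- ln$path
          path[i] <- "O"
          seq_tip <- .evolve_branch(ln$seq, d, config, gene,
                                    paste0(gname, ln$sub, ":tip"))
          tip_rows[[length(tip_rows) + 1L]] <-
            list(gene = gene, genome = gname, sub = ln$sub,
                 seq = seq_tip, path = path)
        }
        lineages <- lapply(lineages, function(ln) {
          ln$path[i] <- "F"
          ln
        })
      } else {  # wgd
        new <- list()
        for (ln in lineages) {
          for (j in seq_len(ev$copies)) {
            sub <- paste0(ln$sub, LETTERS[j])
            lost <- config$loss_prob > 0 &&
              with_seed(stream_seed(config$seed,
                                    paste(gene, "loss", i, sub, sep = "|")),
                        stats::runif(1)) < config$loss_prob
            if (lost) next
            path <- ln$path
            path[i] <- LETTERS[j]
            new[[length(new) + 1L]] <- list(sub = sub, seq = ln$seq,
                                            path = path)
          }
        }
        lineages <- new
        if (length(lineages) == 0L) break  # gene fully lost in focal genome
      }
      prev_depth <- d
    }
    for (ln in lineages) {
      seq_tip <- .evolve_branch(ln$seq, prev_depth, config, gene,
                                paste0("F", ln$sub, ":tip"))
      tip_rows[[length(tip_rows) + 1L]] <-
        list(gene = gene, genome = "focal", sub = ln$sub,
             seq = seq_tip, path = ln$path)
    }
  }

  if (!any(vapply(tip_rows, `[[`, character(1), "genome") == "focal"))
    stop("zero retained genes after loss in the focal genome")

  tips <- data.frame(
    gene = vapply(tip_rows, `[[`, character(1), "gene"),
    genome = vapply(tip_rows, `[[`, character(1), "genome"),
    sub = vapply(tip_rows, `[[`, character(1), "sub"),
    stringsAsFactors = FALSE)
  tips$gene_id <- paste0(tips$gene, "_", tips$genome,
                         ifelse(tips$sub == "", "", paste0("_", tips$sub)))
  tips$seq <- vapply(tip_rows, `[[`, character(1), "seq")
  gene_len <- 3L * config$codons_per_gene

  # chromosome layout: ancestral chromosome index by gene rank, copied per
  # genome/subgenome; positions re-packed after losses.
  anc_idx <- match(tips$gene, names(anc))
  anc_chrom <- (anc_idx - 1L) %/% config$genes_per_chromosome + 1L
  tips$chrom <- paste0(tips$genome, "_chr", anc_chrom,
                       ifelse(tips$sub == "", "", paste0("_", tips$sub)))
  ord <- order(tips$genome, tips$chrom, anc_idx)
  tips <- tips[ord, ]
  tip_paths <- lapply(tip_rows, `[[`, "path")[ord]
  pos <- stats::ave(seq_len(nrow(tips)), tips$chrom, FUN = seq_along)
  tips$start <- (pos - 1L) * 2000L + 1L
  tips$end <- tips$start + gene_len - 1L

  genomes <- lapply(genome_names, function(gn) {
    tt <- tips[tips$genome == gn, , drop = FALSE]
    cds <- tt$seq
    names(cds) <- tt$gene_id
    genes <- data.frame(gene_id = tt$gene_id, chrom = tt$chrom,
                        start = tt$start, end = tt$end, strand = "+",
                        stringsAsFactors = FALSE)
    list(cds = cds, genes = genes)
  })
  names(genomes) <- genome_names

  # truth: all tip pairs of the same ancestral gene; divergence event is the
  # first (deepest) event where the two paths differ.
  truth <- list()
  taus <- vapply(events, `[[`, numeric(1), "tau")
  for (gene in unique(tips$gene)) {
    idx <- which(tips$gene == gene)
    if (length(idx) < 2L) next
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1L), length(idx))) {
        a <- idx[ii]; b <- idx[jj]
        pa <- tip_paths[[a]]; pb <- tip_paths[[b]]
        div <- which(pa != pb & pa != "" & pb != "")[1L]
        if (is.na(div)) next
        truth[[length(truth) + 1L]] <- data.frame(
          gene_a = tips$gene_id[a], gene_b = tips$gene_id[b],
          relation = if (tips$genome[a] == tips$genome[b]) "paralog"
                     else "ortholog",
          true_tau = taus[div], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  truth$expected_4dtv <- 0.5 * (1 - exp(-4 * truth$true_tau))

  lookup <- tips[match(c(truth$gene_a, truth$gene_b), tips$gene_id), ]
  n <- nrow(truth)
  hits <- data.frame(
    qid = truth$gene_a, sid = truth$gene_b,
    pident = round(100 * exp(-truth$true_tau), 2),
    length = gene_len,
    qchrom = lookup$chrom[seq_len(n)],
    qstart = lookup$start[seq_len(n)], qend = lookup$end[seq_len(n)],
    schrom = lookup$chrom[n + seq_len(n)],
    sstart = lookup$start[n + seq_len(n)], send = lookup$end[n + seq_len(n)],
    stringsAsFactors = FALSE)

  if (config$decoy_hits && n > 0L) {
    n_decoy <- max(1L, round(config$decoy_frac * n))
    decoys <- with_seed(stream_seed(config$seed, "decoys"), {
      ia <- sample(nrow(tips), n_decoy, replace = TRUE)
      ib <- sample(nrow(tips), n_decoy, replace = TRUE)
      keep <- tips$gene[ia] != tips$gene[ib]  # unrelated genes only
      data.frame(
        qid = tips$gene_id[ia[keep]], sid = tips$gene_id[ib[keep]],
        pident = round(stats::runif(sum(keep), 30, 60), 2),
        length = gene_len,
        qchrom = tips$chrom[ia[keep]], qstart = tips$start[ia[keep]],
        qend = tips$end[ia[keep]],
        schrom = tips$chrom[ib[keep]], sstart = tips$start[ib[keep]],
        send = tips$end[ib[keep]], stringsAsFactors = FALSE)
    })
    hits <- rbind(hits, decoys)
  }
  rownames(truth) <- rownames(hits) <- NULL

  structure(list(genomes = genomes, hits = hits, truth = truth,
                 config = config),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("Synthetic genome set:", length(x$genomes), "genome(s)\n")
  for (gn in names(x$genomes))
    cat(sprintf("  %-8s %5d genes, %3d chromosomes\n", gn,
                nrow(x$genomes[[gn]]$genes),
                length(unique(x$genomes[[gn]]$genes$chrom))))
  cat("  hits:", nrow(x$hits), " truth pairs:", nrow(x$truth), "\n")
  invisible(x)
}

#' Pool all CDS of a genome set
#'
#' @param gs A `genome_set`.
#' @return Named character vector of every CDS across all genomes (gene ids
#'   are globally unique).
#' @export
all_cds <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  do.call(c, unname(lapply(gs$genomes, `[[`, "cds")))
}

#' Pool all gene records of a genome set
#'
#' @param gs A `genome_set`.
#' @return Data frame of gene records across all genomes (chromosome names are
#'   globally unique, so gene-order ranks are well defined per chromosome).
#' @export
all_genes <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  out <- do.call(rbind, unname(lapply(gs$genomes, `[[`, "genes")))
  rownames(out) <- NULL
  out
}

#' Write a genome set to disk
#'
#' Writes, per genome, a CDS FASTA (60-column wrapped) and a GFF3 (1-based
#' inclusive, feature type "gene", strand "+"), plus the hit table, truth
#' table and configuration. All writes are atomic (temp file + rename) and the
#' bytes are a deterministic function of the configuration and seed.
#'
#' @param gs A `genome_set`.
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_genome_set <- function(gs, outdir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (gn in names(gs$genomes)) {
    g <- gs$genomes[[gn]]
    fa <- file.path(outdir, paste0(gn, ".cds.fa"))
    tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$cds), tmp,
                                width = 60L)
    file.rename(tmp, fa)
    gff <- file.path(outdir, paste0(gn, ".gff3"))
    .write_gene_gff3(g$genes, gff)
    paths <- c(paths, fa, gff)
  }
  hits <- file.path(outdir, "hits.tsv")
  .write_tsv_atomic(gs$hits, hits)
  truth <- file.path(outdir, "truth.tsv")
  .write_tsv_atomic(gs$truth, truth)
  cfg <- file.path(outdir, "sim_config.yaml")
  cfg_list <- unclass(gs$config)
  tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
  yaml::write_yaml(cfg_list, tmp)
  file.rename(tmp, cfg)
  invisible(c(paths, hits = hits, truth = truth, config = cfg))
}
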