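#' Count protospacers in screen sequencing reads
#'
#' Exact-match counting of the 20-nt expression sequence at a fixed offset
#' within each read against the expected library sequences; reads matching
#' no library member are tallied as unmatched.
#'
#' @param reads FASTQ path or character vector of read sequences
#' @param expression_seqs named character vector (sgRNA id -> 20-nt
#'   expression sequence)
#' @param offset 0-based offset of the protospacer within the read
#' @return named integer vector of counts per sgRNA id, with attribute
#'   `unmatched`
#' @export
count_protospacers <- function(reads, expression_seqs, offset = 0L) {
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  w <- nchar(expression_seqs[1])
  counts <- stats::setNames(integer(length(expression_seqs)),
                            names(expression_seqs))
  unmatched <- 0L
  if (length(reads)) {
    if (any(nchar(reads) < offset + w))
      stopf("offset %d + %d exceeds read length", offset, w)
    frag <- substring(reads, offset + 1L, offset + w)
    idx <- match(frag, expression_seqs)
    tab <- table(idx[!is.na(idx)])
    counts[as.integer(names(tab))] <- as.integer(tab)
    unmatched <- sum(is.na(idx))
  }
  attr(counts, "unmatched") <- unmatched
  counts
}

#' Growth phenotypes (gamma) from a screen count table
#'
#' sgRNAs with fewer than `min_reads` reads in BOTH the T0 and endpoint
#' samples of a replicate are excluded from that replicate. Counts are
#' depth-normalized to equal totals, log2 enrichment is computed with a
#' pseudocount, centred on the median of the non-targeting sgRNAs (so the
#' non-targeting median gamma is exactly 0 per replicate), and divided by
#' the number of cell doublings. Replicate gammas are averaged.
#'
#' @param counts data.frame: sgrna, replicate, t0, endpoint
#' @param doublings named numeric (per replicate) or scalar cell doublings
#' @param nc_ids ids of non-targeting sgRNAs (must be in the table)
#' @param pseudocount added to normalized counts before the log ratio
#' @param min_reads count filter (50)
#' @return data.frame: sgrna, one `gamma_<replicate>` column per replicate,
#'   and `gamma` (mean over replicates where defined)
#' @export
compute_gamma <- function(counts, doublings, nc_ids, pseudocount = 1,
                          min_reads = 50L) {
  assert_that(all(nc_ids %in% counts$sgrna),
              "nc_ids contains sgRNAs absent from the count table")
  assert_that(all(counts$t0 >= 0) && all(counts$endpoint >= 0),
              "counts must be nonnegative")
  reps <- unique(counts$replicate)
  if (length(doublings) == 1L)
    doublings <- stats::setNames(rep(doublings, length(reps)), reps)
  assert_that(all(doublings > 0), "doublings must be > 0")
  ids <- unique(counts$sgrna)
  out <- data.frame(sgrna = ids, stringsAsFactors = FALSE)
  for (r in reps) {
    cr <- counts[counts$replicate == r, , drop = FALSE]
    tot0 <- sum(cr$t0); tot1 <- sum(cr$endpoint)
    if (tot0 == 0 || tot1 == 0) stopf("replicate '%s': zero total depth", r)
    depth <- (tot0 + tot1) / 2
    n0 <- cr$t0 * depth / tot0
    n1 <- cr$endpoint * depth / tot1
    raw <- log2((n1 + pseudocount) / (n0 + pseudocount))
    pass <- !(cr$t0 < min_reads & cr$endpoint < min_reads)
    raw[!pass] <- NA_real_
    nc_raw <- raw[cr$sgrna %in% nc_ids]
    ncm <- stats::median(nc_raw, na.rm = TRUE)
    g <- (raw - ncm) / doublings[[as.character(r)]]
    out[[paste0("gamma_", r)]] <- g[match(ids, cr$sgrna)]
  }
  gcols <- grep("^gamma_", names(out), value = TRUE)
  out$gamma <- rowMeans(out[, gcols, drop = FALSE], na.rm = TRUE)
  out$gamma[is.nan(out$gamma)] <- NA_real_
  out
}

#' Two-sided Mann-Whitney test
#'
#' Exact when both groups are small and tie-free (matching exhaustive
#' enumeration of the U statistic's permutation distribution), otherwise
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples
#' @return two-sided p-value
#' @export
mw_test <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                      correct = TRUE)$p.value)
}

#' Smallest two-sided Mann-Whitney p obtainable for the group sizes
#'
#' The p-value floor reached when every observation in one group outranks
#' every observation in the other (relevant when many genes saturate it).
#' @param m,n group sizes
#' @return numeric p-value floor (exact, tie-free case)
#' @export
min_achievable_p <- function(m, n) {
  2 / choose(m + n, m)
}

#' Build negative-control pseudo-genes from non-targeting sgRNAs
#'
#' Samples `size` non-targeting sgRNAs (with replacement) per pseudo-gene;
#' pseudo-genes are scored downstream exactly as true genes to model noise
#' and off-target effects.
#'
#' @param nt_ids non-targeting sgRNA ids
#' @param n_genes number of pseudo-genes
#' @param size sgRNAs per pseudo-gene (10)
#' @param seed RNG seed
#' @return data.frame: gene (pseudo-gene id), sgrna
#' @export
make_nc_genes <- function(nt_ids, n_genes, size = 10L, seed = 1L) {
  assert_that(length(nt_ids) >= 1L, "need at least one non-targeting sgRNA")
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_genes), function(i)
      data.frame(gene = sprintf("NC_GENE_%04d", i),
                 sgrna = sample(nt_ids, size, replace = TRUE),
                 stringsAsFactors = FALSE)))
  })
}

# score one group of sgRNA gammas against the negative-control set
score_one <- function(g, nc_gamma, top_k = 3L) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) return(c(phenotype = NA_real_, p = NA_real_))
  top <- g[order(-abs(g))][seq_len(min(top_k, length(g)))]
  c(phenotype = mean(top), p = mw_test(g, nc_gamma))
}

#' Score genes (and negative-control pseudo-genes) from sgRNA phenotypes
#'
#' Per TSS: the phenotype is the mean of the 3 sgRNAs with the strongest
#' gamma by absolute value, and the p-value is the two-sided Mann-Whitney
#' test of all the TSS's sgRNAs against the full set of negative-control
#' sgRNAs. Genes with multiple TSSs collapse to the TSS with the lowest
#' p-value. Pseudo-genes assembled from non-targeting sgRNAs are scored
#' identically, and the z-score standardizes each phenotype to the
#' pseudo-gene phenotype distribution.
#'
#' @param phenotypes data.frame from [compute_gamma()] (sgrna, gamma)
#' @param library_map data.frame: sgrna, gene, tss_id
#' @param nc_ids non-targeting sgRNA ids present in `phenotypes`
#' @param nc_genes pseudo-gene table from [make_nc_genes()] (built
#'   internally when NULL)
#' @param n_nc_genes pseudo-genes to build when `nc_genes` is NULL
#' @param seed seed for pseudo-gene sampling
#' @param top_k sgRNAs averaged for the phenotype (3)
#' @return list: `genes` and `nc_genes` data.frames (gene, tss_id,
#'   phenotype, p, z), plus `min_p` (the Mann-Whitney floor for a full-size
#'   gene)
#' @export
score_genes <- function(phenotypes, library_map, nc_ids, nc_genes = NULL,
                        n_nc_genes = 1000L, seed = 1L, top_k = 3L) {
  if (length(nc_ids) == 0L) stopf("no negative controls supplied")
  gmap <- stats::setNames(phenotypes$gamma, phenotypes$sgrna)
  nc_gamma <- gmap[nc_ids]
  nc_gamma <- nc_gamma[!is.na(nc_gamma)]
  if (length(nc_gamma) == 0L) stopf("no negative-control sgRNA has a phenotype")
  if (is.null(nc_genes))
    nc_genes <- make_nc_genes(nc_ids, n_nc_genes, seed = seed)

  score_table <- function(map, collapse_gene = TRUE) {
    map <- map[map$sgrna %in% names(gmap), , drop = FALSE]
    key <- if (!is.null(map$tss_id)) map$tss_id else map$gene
    rows <- lapply(split(seq_len(nrow(map)), key), function(ix) {
      sc <- score_one(unname(gmap[map$sgrna[ix]]), nc_gamma, top_k)
      data.frame(gene = map$gene[ix[1]], tss_id = key[ix[1]],
                 phenotype = sc[["phenotype"]], p = sc[["p"]],
                 n_sgrnas = length(ix), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[!is.na(df$p), , drop = FALSE]
    if (collapse_gene) {
      df <- df[order(df$gene, df$p), , drop = FALSE]
      df <- df[!duplicated(df$gene), , drop = FALSE]
    }
    rownames(df) <- NULL
    df
  }

  genes <- score_table(library_map, collapse_gene = TRUE)
  ncg <- score_table(nc_genes, collapse_gene = FALSE)
  mu <- mean(ncg$phenotype); sdev <- stats::sd(ncg$phenotype)
  if (is.na(sdev) || sdev == 0) stopf("degenerate pseudo-gene distribution")
  genes$z <- (genes$phenotype - mu) / sdev
  ncg$z <- (ncg$phenotype - mu) / sdev
  list(genes = genes, nc_genes = ncg,
       min_p = min_achievable_p(10L, length(nc_gamma)))
}

#' Call hit genes with an integrated effect-size / confidence score
#'
#' The hit score is |z x -log10 p|. A gene is a hit when its score reaches
#' `threshold`; with `direction = "negative"` only genes with negative
#' phenotype z are eligible (signed score z x -log10 p <= -threshold).
#' When `threshold` is NULL it is calibrated so that the pseudo-gene pass
#' rate is approximately `nc_pass_rate`. The empirical FDR is the
#' pseudo-gene pass fraction divided by the true-gene pass fraction.
#'
#' @param gene_scores `genes` data.frame from [score_genes()]
#' @param nc_scores `nc_genes` data.frame from [score_genes()]
#' @param threshold hit-score threshold (NULL = calibrate)
#' @param nc_pass_rate calibration target for the pseudo-gene pass rate
#' @param direction "both" or "negative"
#' @return list: `hits` (gene ids), `threshold`, `fdr`, `scores` (per-gene
#'   hit scores), `nc_pass_rate`
#' @export
call_hits <- function(gene_scores, nc_scores = NULL, threshold = NULL,
                      nc_pass_rate = 0.0021, direction = c("both", "negative")) {
  direction <- match.arg(direction)
  hit_score <- function(df) {
    s <- df$z * -log10(df$p)
    if (direction == "negative") -s else abs(s)
  }
  gs <- hit_score(gene_scores)
  ns <- if (!is.null(nc_scores) && nrow(nc_scores)) hit_score(nc_scores) else NULL
  if (is.null(threshold)) {
    if (is.null(ns)) stopf("cannot calibrate a threshold without pseudo-genes")
    threshold <- as.numeric(stats::quantile(ns, 1 - nc_pass_rate, type = 1))
    # strictly above the calibration quantile
    threshold <- threshold + 1e-9
  }
  hits <- gene_scores$gene[gs >= threshold]
  fdr <- NA_real_
  if (is.null(ns)) {
    warnf("no pseudo-genes: empirical FDR unavailable")
  } else {
    frac_nc <- mean(ns >= threshold)
    frac_genes <- mean(gs >= threshold)
    fdr <- if (frac_genes > 0) frac_nc / frac_genes else NA_real_
  }
  list(hits = hits, threshold = threshold, fdr = fdr,
       scores = stats::setNames(gs, gene_scores$gene),
       nc_pass_rate = if (is.null(ns)) NA_real_ else mean(ns >= threshold))
}

#' Evaluate a screen against gold-standard gene sets
#'
#' sgRNA-level ROC ranks sgRNAs by growth phenotype (most negative first)
#' and counts those targeting essential genes as true positives and
#' non-essential genes as false positives. Gene-level precision-recall
#' ranks genes by phenotype and reports recall at the requested precision.
#' The active sgRNA fraction is the proportion of essential-targeting
#' sgRNAs with z-score < -2 relative to the non-essential-targeting sgRNA
#' gamma distribution.
#'
#' @param phenotypes data.frame (sgrna, gamma)
#' @param library_map data.frame (sgrna, gene, tss_id)
#' @param gene_scores `genes` data.frame from [score_genes()]
#' @param essential,nonessential disjoint gold-standard gene sets
#' @param precision_target precision at which recall is read out (0.95)
#' @return list: `sgrna_auc`, `sgrna_roc`, `gene_pr`,
#'   `recall_at_precision`, `active_fraction`
#' @export
evaluate_screen <- function(phenotypes, library_map, gene_scores,
                            essential, nonessential,
                            precision_target = 0.95) {
  if (length(essential) == 0L || length(nonessential) == 0L)
    stopf("gold-standard gene sets must be non-empty")
  if (length(intersect(essential, nonessential)))
    stopf("essential and non-essential sets overlap")
  gmap <- merge(phenotypes[, c("sgrna", "gamma")], library_map, by = "sgrna")
  gmap <- gmap[!is.na(gmap$gamma), , drop = FALSE]
  ess <- gmap$gene %in% essential
  non <- gmap$gene %in% nonessential
  sub <- gmap[ess | non, , drop = FALSE]
  rc <- roc_curve(-sub$gamma, sub$gene %in% essential)

  gs <- gene_scores[gene_scores$gene %in% c(essential, nonessential), , drop = FALSE]
  pr <- pr_curve(-gs$phenotype, gs$gene %in% essential)
  rap <- recall_at_precision(-gs$phenotype, gs$gene %in% essential,
                             precision_target)

  non_gamma <- gmap$gamma[non]
  ess_gamma <- gmap$gamma[ess]
  zsd <- stats::sd(non_gamma)
  active <- if (length(ess_gamma) && !is.na(zsd) && zsd > 0) {
    mean((ess_gamma - mean(non_gamma)) / zsd < -2)
  } else NA_real_

  list(sgrna_auc = rc$auc, sgrna_roc = rc, gene_pr = pr,
       recall_at_precision = rap, active_fraction = active)
}
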