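#' Planted truth for synthetic datasets
#'
#' The stated world for the generators: a positional activity term that is
#' periodic (nucleosome-like phasing, period ~190 bp) and decays away from
#' the TSS (decay length 1 kb), small sequence effects (a GC term and a
#' penalty for guanine directly downstream of the PAM), Gaussian activity
#' noise, a planted per-gene growth effect for essential genes (gamma in
#' units of log2 enrichment per doubling), and count overdispersion.
#'
#' @param amplitude positional amplitude (activity units)
#' @param period positional periodicity (bp)
#' @param decay positional decay length (bp)
#' @param noise_sd activity noise sd
#' @param seq_gc coefficient on (GC fraction - 0.5)
#' @param seq_g_after_pam coefficient on a G directly 3' of the PAM
#' @param gamma_essential planted growth effect of essential genes
#' @param dispersion negative-binomial overdispersion of screen counts
#' @return list of class `planted_truth`
#' @export
planted_truth <- function(amplitude = 1, period = 190, decay = 1000,
                          noise_sd = 0.1, seq_gc = 0.6,
                          seq_g_after_pam = -0.3,
                          gamma_essential = -0.4, dispersion = 0.05) {
  structure(list(amplitude = amplitude, period = period, decay = decay,
                 noise_sd = noise_sd, seq_gc = seq_gc,
                 seq_g_after_pam = seq_g_after_pam,
                 gamma_essential = gamma_essential, dispersion = dispersion),
            class = "planted_truth")
}

#' Planted positional activity function
#' @param d signed distance (bp, positive downstream of the TSS)
#' @param truth [planted_truth()]
#' @return positional activity contribution
#' @export
planted_position_activity <- function(d, truth = planted_truth()) {
  truth$amplitude * exp(-abs(d) / truth$decay) *
    (1 + sin(2 * pi * d / truth$period)) / 2
}

#' Generate a toy reference: genome, transcripts, CAGE peaks, chromatin
#'
#' Builds a seeded random genome of two contigs with `n_genes` genes on
#' alternating strands, a transcript TSS table, CAGE peaks placed near the
#' transcript TSSs with geometries cycling through every annotation-support
#' case (matched p1+p2 mergeable, matched p1+p2 more than 1 kb apart,
#' matched p1 alone, mislabeled primary peak within 500 bp, unlabeled
#' robust and permissive peaks within 200 bp, and no peak at all), and an
#' MNase-like chromatin track: a sinusoid phased downstream of each TSS
#' (period and decay from [planted_truth()]). Regeneration from the same
#' seed is identical. Files are written only when `dir` is given.
#'
#' @param seed RNG seed
#' @param n_genes number of genes (>= 1; >= 7 realizes every support enum)
#' @param contig_len length of each of the two contigs (bp)
#' @param truth [planted_truth()] controlling the chromatin phasing
#' @param dir optional directory to write genome.fa, transcripts.tsv,
#'   cage.bed and mnase.bedgraph
#' @return list: genome (DNAStringSet), transcripts (data.frame), cage_bed
#'   (character lines), peaks (parsed), tracks (named list of GRanges),
#'   truth
#' @export
make_toy_reference <- function(seed = 1L, n_genes = 20L, contig_len = 60000L,
                               truth = planted_truth(), dir = NULL) {
  assert_that(n_genes >= 1L, "n_genes must be >= 1")
  per_contig <- ceiling(n_genes / 2)
  spacing <- (contig_len - 4000L) %/% (per_contig + 1L)
  if (spacing < 2500L)
    stopf("contig too short for %d genes (need >= %d bp)",
          n_genes, (per_contig + 1L) * 2500L + 4000L)
  with_seed(seed, {
    contigs <- c("chrA", "chrB")
    genome <- Biostrings::DNAStringSet(vapply(contigs, function(ct)
      paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
            collapse = ""), character(1)))
    names(genome) <- contigs

    tx <- list(); bed <- character(0)
    for (g in seq_len(n_genes)) {
      ct <- contigs[(g - 1L) %% 2L + 1L]
      slot <- (g - 1L) %/% 2L + 1L
      tss <- 2000L + slot * spacing + sample(-100:100, 1L)
      strand <- if (g %% 2L == 1L) "+" else "-"
      gene <- sprintf("GENE%02d", g)
      n_tx <- sample(1:2, 1L)
      for (k in seq_len(n_tx)) {
        tx[[length(tx) + 1L]] <- data.frame(
          gene = gene, transcript = sprintf("%s.t%d", gene, k), chrom = ct,
          strand = strand, tss = tss + (k - 1L) * sample(10:60, 1L),
          stringsAsFactors = FALSE)
      }
      scenario <- (g - 1L) %% 7L
      mk <- function(start, end, label, tier, score = 10) {
        sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%s", ct, start, end, label, score,
                strand, tier)
      }
      if (scenario == 0L) {            # matched p1 + p2, mergeable
        bed <- c(bed, mk(tss - 10L, tss + 10L, paste0("p1@", gene), "robust"),
                 mk(tss + 290L, tss + 310L, paste0("p2@", gene), "robust"))
      } else if (scenario == 1L) {     # matched p1 + p2, > 1 kb apart
        bed <- c(bed, mk(tss - 10L, tss + 10L, paste0("p1@", gene), "robust"),
                 mk(tss + 1800L, tss + 1820L, paste0("p2@", gene), "robust"))
      } else if (scenario == 2L) {     # matched p1 only
        bed <- c(bed, mk(tss - 10L, tss + 10L, paste0("p1@", gene), "robust"))
      } else if (scenario == 3L) {     # primary peak with foreign symbol
        bed <- c(bed, mk(tss + 200L, tss + 220L, sprintf("p1@ALT%02d", g),
                         "robust"))
      } else if (scenario == 4L) {     # unlabeled robust peak within 200 bp
        bed <- c(bed, mk(tss + 100L, tss + 120L, ".", "robust"))
      } else if (scenario == 5L) {     # unlabeled permissive peak
        bed <- c(bed, mk(tss + 100L, tss + 120L, ".", "permissive"))
      }                                # scenario 6: no CAGE support
    }
    transcripts <- do.call(rbind, tx)

    # nucleosome-like chromatin signal phased downstream of each TSS
    bin <- 10L
    tracks <- list()
    seg <- list()
    for (ct in contigs) {
      starts <- seq(1L, contig_len - bin + 1L, by = bin)
      sig <- rep(1, length(starts))
      ctx <- transcripts[transcripts$chrom == ct, , drop = FALSE]
      for (i in seq_len(nrow(ctx))) {
        d <- if (ctx$strand[i] == "+") starts - ctx$tss[i] else ctx$tss[i] - starts
        infl <- ifelse(d >= 0 & d <= 3000,
                       (1 + sin(2 * pi * d / truth$period - pi / 2)) *
                         exp(-d / truth$decay), 0)
        sig <- pmax(sig, 1 + 2 * infl)
      }
      seg[[ct]] <- data.frame(chrom = ct, start = starts, score = sig)
    }
    seg <- do.call(rbind, seg)
    tracks$mnase <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start, width = bin), score = seg$score)

    ref <- list(genome = genome, transcripts = transcripts, cage_bed = bed,
                peaks = parse_cage_bed(bed), tracks = tracks, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
      utils::write.table(transcripts, file.path(dir, "transcripts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(bed, file.path(dir, "cage.bed"))
      tr <- tracks$mnase
      utils::write.table(
        data.frame(chrom = as.character(GenomicRanges::seqnames(tr)),
                   start = GenomicRanges::start(tr) - 1L,
                   end = GenomicRanges::end(tr), score = tr$score),
        file.path(dir, "mnase.bedgraph"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    }
    ref
  })
}

#' Simulate an sgRNA activity dataset with planted truth
#'
#' Activity = planted positional term (periodic, decaying) + planted
#' sequence term (GC and G-after-PAM effects read from the feature matrix)
#' + Gaussian noise, then rescaled per gene so the top-3-by-absolute-value
#' mean is 1 (the activity-score convention).
#'
#' @param cands candidate table ([enumerate_candidates()] output, possibly
#'   stacked over genes)
#' @param features matching feature data.frame (needs dist_primary_down;
#'   gc_fraction and base_f1_G are used when present)
#' @param truth [planted_truth()]
#' @param seed RNG seed
#' @return data.frame: sgrna, gene, phenotype (raw), activity (normalized)
#' @export
simulate_activity_dataset <- function(cands, features, truth = planted_truth(),
                                      seed = 1L) {
  d <- features$dist_primary_down
  pos <- planted_position_activity(d, truth)
  seq_term <- rep(0, nrow(cands))
  if (!is.null(features$gc_fraction))
    seq_term <- seq_term + truth$seq_gc * (features$gc_fraction - 0.5)
  if (!is.null(features$base_f1_G))
    seq_term <- seq_term + truth$seq_g_after_pam * features$base_f1_G
  noise <- if (truth$noise_sd > 0)
    with_seed(seed, rnorm(nrow(cands), 0, truth$noise_sd)) else 0
  raw <- pos + seq_term + noise
  df <- data.frame(sgrna = cands$id, gene = cands$gene, phenotype = raw,
                   stringsAsFactors = FALSE)
  compute_activity_scores(df)
}

#' Simulate pooled-screen counts with planted growth effects
#'
#' T0 abundances are lognormal; the endpoint expectation is the T0
#' abundance times 2^(gamma_true x doublings), renormalized to the target
#' depth; counts are negative-binomial with the given overdispersion
#' (dispersion 0 gives deterministic rounded expectations, the
#' noise-free limit). Non-targeting sgRNAs must have gamma_true = 0.
#'
#' @param gamma_true named numeric: true growth phenotype per sgRNA id
#' @param depth mean reads per sgRNA per sample
#' @param doublings cell doublings between T0 and endpoint
#' @param dispersion negative-binomial overdispersion (1/size)
#' @param seed RNG seed
#' @param n_replicates screen replicates
#' @return data.frame: sgrna, replicate, t0, endpoint (attribute
#'   `doublings`)
#' @export
simulate_screen_counts <- function(gamma_true, depth = 500, doublings = 10,
                                   dispersion = 0.05, seed = 1L,
                                   n_replicates = 2L) {
  ids <- names(gamma_true)
  assert_that(!is.null(ids), "gamma_true must be named by sgRNA id")
  if (depth < 100) warnf("depth %g is low; many sgRNAs may fail the count filter", depth)
  n <- length(ids)
  draw <- function(mu) {
    if (dispersion <= 0) round(mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  out <- with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      abund <- stats::rlnorm(n, 0, 0.5)
      abund <- abund / mean(abund)
      t0_mu <- depth * abund
      end_rel <- abund * 2^(gamma_true * doublings)
      end_mu <- depth * end_rel / mean(end_rel)
      data.frame(sgrna = ids, replicate = r, t0 = draw(t0_mu),
                 endpoint = draw(end_mu), stringsAsFactors = FALSE)
    })
    do.call(rbind, reps)
  })
  attr(out, "doublings") <- doublings
  out
}
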