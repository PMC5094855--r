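#' Cloning arm sequences and restriction-site patterns
#'
#' The oligo template is: 18-nt 5' PCR adapter, BstXI arm `CCACCTTGTTG`,
#' 20-nt insert (the sgRNA expression sequence), BlpI arm
#' `GTTTAAGAGCTAAGCTG`, 18-nt 3' PCR adapter — 84 bp in total.
#' @name cloning_arms
NULL

BSTXI_ARM <- "CCACCTTGTTG"
BLPI_ARM <- "GTTTAAGAGCTAAGCTG"

# recognition patterns (all three are palindromic, so scanning the given
# strand covers both)
RESTRICTION_PATTERNS <- c(BstXI = "CCA[ACGT]{6}TGG",
                          BlpI = "GCT[ACGT]AGC",
                          SbfI = "CCTGCAGG")

#' Test an assembled sequence for forbidden restriction sites
#'
#' Scans for BstXI (CCANNNNNNTGG), BlpI (GCTNAGC) and SbfI (CCTGCAGG)
#' recognition sites at any position other than the intended cloning-arm
#' positions (the BstXI site formed at the 5' arm / insert junction and
#' the BlpI site inside the 3' arm). All three sites are palindromic, so a
#' single-strand scan covers both strands. Matches spanning the insert/arm
#' junctions are caught because the scan runs over the full assembly.
#'
#' @param insert 20-nt expression sequence
#' @param adapter5,adapter3 PCR adapters (may be empty strings when
#'   filtering candidates before adapter assignment)
#' @return TRUE if a forbidden (non-intended) site is present
#' @export
has_forbidden_site <- function(insert, adapter5 = "", adapter3 = "") {
  seqs <- paste0(adapter5, BSTXI_ARM, insert, BLPI_ARM, adapter3)
  off5 <- nchar(adapter5)
  intended <- c(BstXI = off5 + 1L,
                BlpI = off5 + nchar(BSTXI_ARM) + nchar(insert) + 9L)
  for (enz in names(RESTRICTION_PATTERNS)) {
    m <- gregexpr(paste0("(?=", RESTRICTION_PATTERNS[[enz]], ")"), seqs,
                  perl = TRUE)[[1]]
    m <- m[m > 0]
    allowed <- if (enz %in% names(intended)) intended[[enz]] else integer(0)
    if (length(setdiff(m, allowed))) return(TRUE)
  }
  FALSE
}

#' Assemble a synthesis-ready 84-bp oligo
#'
#' @param expression_seq 20-nt sgRNA expression sequence (5' G + 19 nt)
#' @param adapter5,adapter3 18-nt sublibrary PCR adapters
#' @return list of class `oligo_record`: oligo (84 bp), adapter5,
#'   bstxi_arm, insert, blpi_arm, adapter3
#' @export
format_oligo <- function(expression_seq, adapter5, adapter3) {
  if (nchar(adapter5) != 18L || nchar(adapter3) != 18L)
    stopf("adapters must be 18 nt (got %d and %d)",
          nchar(adapter5), nchar(adapter3))
  if (nchar(expression_seq) != 20L)
    stopf("expression sequence must be 20 nt")
  oligo <- paste0(adapter5, BSTXI_ARM, expression_seq, BLPI_ARM, adapter3)
  stopifnot(nchar(oligo) == 84L)
  structure(list(oligo = oligo, adapter5 = adapter5, bstxi_arm = BSTXI_ARM,
                 insert = expression_seq, blpi_arm = BLPI_ARM,
                 adapter3 = adapter3), class = "oligo_record")
}

# TRUE if a candidate's target site is < min_shift bp shifted from any
# already-selected site (same strand only; opposite strands never overlap
# for this purpose)
conflicts_with_selected <- function(strand, pam, sel_strand, sel_pam,
                                    min_shift = 3L) {
  if (length(sel_pam) == 0L) return(FALSE)
  any(sel_strand == strand & abs(sel_pam - pam) < min_shift)
}

#' Select the library sgRNAs for each TSS
#'
#' Implements the selection policy: (1) up to 2 empirically validated
#' sgRNAs first, when the empirical activity score is at least 0.75, the
#' site lies within 5 kb of the TSS, the sgRNA passes the strictest
#' off-target tier, carries no extra restriction sites and is at least 3 bp
#' shifted from any previously selected target site; (2) further
#' empirically qualifying sgRNAs are not auto-included but their predicted
#' scores gain +0.2; (3) remaining slots fill by descending predicted score
#' under the same filters; (4) if fewer than `max_guides` are selected, the
#' off-target stringency is iteratively relaxed through T1..T4; (5) a TSS
#' that cannot reach `max_guides` even at T4 is not targeted (reported in
#' the `untargeted` attribute, not raised).
#'
#' Ties in predicted score break by lower genomic coordinate, then + strand
#' first; selection is deterministic given scores and tiers.
#'
#' @param cands candidate data.frame ([enumerate_candidates()])
#' @param predicted named numeric predicted activity scores (by candidate id)
#' @param tiers data.frame with columns id, tier ([offtarget_report()])
#' @param tss_units TSS unit table from [expand_tss_units()] (used for the
#'   5-kb empirical distance filter)
#' @param empirical optional data.frame with columns id, activity
#'   (empirical activity scores mapped onto candidate ids)
#' @param max_guides sgRNAs per TSS (10)
#' @param empirical_max auto-included empirical sgRNAs (2)
#' @param empirical_min_score qualifying empirical activity (0.75)
#' @param empirical_max_dist maximum distance from the TSS (5 kb)
#' @param bonus predicted-score bonus for non-included qualifying
#'   empirical sgRNAs (0.2)
#' @param min_shift minimum target-site shift (3 bp)
#' @return data.frame of library entries with attribute `untargeted`
#'   (character vector of TSS ids that could not be filled)
#' @export
select_sgrnas <- function(cands, predicted, tiers, tss_units, empirical = NULL,
                          max_guides = 10L, empirical_max = 2L,
                          empirical_min_score = 0.75,
                          empirical_max_dist = 5000L, bonus = 0.2,
                          min_shift = 3L) {
  tier_levels <- stringency_tiers()
  d <- cands
  d$predicted <- unname(predicted[d$id])
  d$tier <- tiers$tier[match(d$id, tiers$id)]
  d$empirical <- if (!is.null(empirical))
    empirical$activity[match(d$id, empirical$id)] else NA_real_
  d$forbidden <- vapply(d$expression_seq, has_forbidden_site, logical(1))
  d$tier_idx <- match(d$tier, tier_levels)
  ui <- match(d$tss_id, tss_units$tss_id)
  if (anyNA(ui)) stopf("candidates reference TSS units absent from tss_units")
  d$dist_tss <- edge_distance(tss_units$start[ui], tss_units$end[ui],
                              d$pam_3g_coord)

  entries <- list(); untargeted <- character(0)
  for (tid in unique(d$tss_id)) {
    t <- d[d$tss_id == tid, , drop = FALSE]
    sel <- t[0, , drop = FALSE]
    sel$source <- character(0)

    take <- function(row, source) {
      row$source <- source
      sel <<- rbind(sel, row)
    }

    # phase 1: empirical-first at the strictest tier
    emp_ok <- !is.na(t$empirical) & t$empirical >= empirical_min_score &
      !is.na(t$dist_tss) & abs(t$dist_tss) <= empirical_max_dist
    e <- t[emp_ok & t$tier == "T0" & !t$forbidden, , drop = FALSE]
    e <- e[order(-e$empirical, e$pam_3g_coord, e$strand != "+"), , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (nrow(sel) >= empirical_max) break
      if (conflicts_with_selected(e$strand[i], e$pam_3g_coord[i],
                                  sel$strand, sel$pam_3g_coord, min_shift)) next
      take(e[i, , drop = FALSE], "empirical")
    }
    # phase 2: remaining qualifying empirical sgRNAs get the score bonus
    bonus_ids <- t$id[emp_ok & t$tier == "T0" & !t$forbidden &
                        !(t$id %in% sel$id)]
    t$predicted[t$id %in% bonus_ids] <- t$predicted[t$id %in% bonus_ids] + bonus

    # phase 3/4: predicted-score order, relaxing tiers T0 -> T4
    t <- t[order(-t$predicted, t$pam_3g_coord, t$strand != "+"), , drop = FALSE]
    for (lvl in seq_len(5L)) {  # T0..T4
      if (nrow(sel) >= max_guides) break
      pool <- t[!is.na(t$tier_idx) & t$tier_idx <= lvl & !t$forbidden &
                  !(t$id %in% sel$id) & !is.na(t$predicted), , drop = FALSE]
      for (i in seq_len(nrow(pool))) {
        if (nrow(sel) >= max_guides) break
        if (conflicts_with_selected(pool$strand[i], pool$pam_3g_coord[i],
                                    sel$strand, sel$pam_3g_coord, min_shift)) next
        take(pool[i, , drop = FALSE], "predicted")
      }
    }

    if (nrow(sel) < max_guides) {
      untargeted <- c(untargeted, tid)
      next
    }
    sel$selection_rank <- seq_len(nrow(sel))
    sel$half <- ifelse(sel$selection_rank <= ceiling(max_guides / 2),
                       "top5", "second5")
    entries[[tid]] <- sel
  }
  out <- if (length(entries)) do.call(rbind, entries) else
    cbind(d[0, , drop = FALSE], source = character(0),
          selection_rank = integer(0), half = character(0))
  rownames(out) <- NULL
  keep_cols <- c("id", "gene", "tss_id", "chrom", "strand", "pam_3g_coord",
                 "protospacer_genomic", "expression_seq", "source",
                 "predicted", "empirical", "tier", "selection_rank", "half")
  out <- out[, intersect(keep_cols, names(out)), drop = FALSE]
  attr(out, "untargeted") <- untargeted
  out
}

#' Generate matched non-targeting negative-control protospacers
#'
#' Estimates per-position base frequencies from the library's 19-nt
#' protospacers, samples candidate sequences position-independently from
#' those frequencies, and keeps only sequences with zero alignments scoring
#' < 31 in TSS-proximal space and zero alignments scoring < 21
#' genome-wide. Exactly `n` sequences are returned; a persistently
#' near-total rejection rate aborts with a diagnostic.
#'
#' @param library library entries (or any data.frame with
#'   `protospacer_genomic`)
#' @param n number of controls to generate
#' @param genome named DNAStringSet
#' @param proximal GRanges of proximal regions
#' @param seed RNG seed (fixed seed gives an identical list)
#' @param weights mismatch penalty weights
#' @param max_draws_per_control sampling budget multiplier before aborting
#' @param index optional precomputed [genome_site_index()]
#' @return character vector of n 19-nt protospacers
#' @export
generate_negative_controls <- function(library, n, genome, proximal, seed = 1L,
                                       weights = default_mismatch_weights(),
                                       max_draws_per_control = 1000L,
                                       index = NULL) {
  assert_that(nrow(library) > 0L, "library is empty")
  if (is.null(index)) index <- genome_site_index(genome)
  protos <- library$protospacer_genomic
  plen <- nchar(protos[1])
  m <- do.call(rbind, strsplit(protos, ""))
  bases <- c("A", "C", "G", "T")
  freq <- sapply(seq_len(plen), function(j) {
    tab <- table(factor(m[, j], levels = bases))
    as.numeric(tab) / sum(tab)
  })  # 4 x plen
  accepted <- character(0)
  draws <- 0L
  with_seed(seed, {
    while (length(accepted) < n) {
      if (draws >= n * max_draws_per_control)
        stopf(paste0("negative-control rejection rate too high: ",
                     "%d draws yielded %d/%d controls"),
              draws, length(accepted), n)
      cand <- paste(vapply(seq_len(plen), function(j)
        sample(bases, 1L, prob = freq[, j]), character(1)), collapse = "")
      draws <- draws + 1L
      sites <- enumerate_offtargets(cand, score_cap = 31, weights = weights,
                                    index = index)
      ct <- offtarget_counts(sites, proximal)
      if (ct[["n_proximal"]] == 0L && ct[["n_genome"]] == 0L)
        accepted <- c(accepted, cand)
    }
  })
  accepted
}

#' Partition library entries into sublibraries and half-libraries
#'
#' The half-library is a pure function of selection rank (ranks 1-5 =
#' "top5", 6-10 = "second5"); the thematic group comes from a user-supplied
#' gene-to-group map (genes missing from the map go to "unassigned" with a
#' warning).
#'
#' @param entries library entries from [select_sgrnas()]
#' @param gene_to_group named character vector mapping gene -> group label
#' @return entries with `group` and `sublibrary` columns
#' @export
partition_sublibraries <- function(entries, gene_to_group) {
  grp <- unname(gene_to_group[entries$gene])
  if (anyNA(grp)) {
    warnf("%d genes missing from the group map; assigned 'unassigned'",
          length(unique(entries$gene[is.na(grp)])))
    grp[is.na(grp)] <- "unassigned"
  }
  entries$group <- grp
  entries$sublibrary <- paste0(grp, "_", entries$half)
  entries
}

#' Write library entries as TSV
#' @param entries library data.frame
#' @param path output path
#' @export
write_library_tsv <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
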