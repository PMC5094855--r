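#' Default per-position mismatch penalty weights
#'
#' Penalties for protospacer positions 1 (PAM-distal, 5' end) through 19
#' (PAM-proximal), increasing linearly toward the PAM so that PAM-proximal
#' mismatches are penalized most. The default vector is scaled so that a
#' perfect match scores 0, a single mismatch never reaches the genome-wide
#' threshold (21), two PAM-proximal mismatches exceed it, and three
#' PAM-proximal mismatches exceed the TSS-proximal threshold (31) — keeping
#' the semantics that near-perfect duplicates of a target site are
#' disallowed. The vector is configuration: an externally published weight
#' vector of length 19 can be dropped in verbatim.
#'
#' @return integer vector of length 19
#' @export
default_mismatch_weights <- function() {
  round(seq(1, 12, length.out = 19))
}

#' Position-weighted mismatch score between a guide and a genomic site
#'
#' Sum of per-position penalties at mismatched protospacer positions; a
#' perfect match scores 0 and the score is monotone non-decreasing in the
#' number of mismatches. Sites whose PAM is not NGG are not alignments at
#' all and score NA.
#'
#' @param query 19-nt protospacer plus NGG PAM (22 nt), guide orientation
#' @param site candidate genomic site, same length and orientation
#' @param weights per-position penalties (length 19; position 19 is
#'   PAM-proximal)
#' @return numeric score (NA if the site PAM is disrupted)
#' @export
mismatch_score <- function(query, site, weights = default_mismatch_weights()) {
  query <- toupper(query); site <- toupper(site)
  if (nchar(query) != nchar(site)) stopf("query and site lengths differ")
  plen <- length(weights)
  if (nchar(query) != plen + 3L)
    stopf("expected %d-nt protospacer + 3-nt PAM (got %d nt)",
          plen, nchar(query))
  if (substring(site, plen + 2L, plen + 3L) != "GG") return(NA_real_)
  q <- strsplit(substring(query, 1L, plen), "")[[1]]
  s <- strsplit(substring(site, 1L, plen), "")[[1]]
  sum(weights[q != s])
}

#' TSS-proximal reference regions
#'
#' 1-kb windows around each annotated TSS range (each range expanded by
#' `flank` on both sides) together with 1-kb windows at the 5' end of every
#' transcript model, merged where overlapping. Off-target alignments inside
#' these regions are the ones CRISPRi/a activity makes dangerous, so they
#' are held to the stricter score threshold.
#'
#' @param annotations TSS annotation table ([assign_tss_table()])
#' @param transcripts transcript table (gene, transcript, chrom, strand, tss)
#' @param flank half-width of each window (bp)
#' @return GRanges of merged proximal intervals
#' @export
proximal_reference <- function(annotations, transcripts, flank = 500L) {
  iv <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    iv[[length(iv) + 1L]] <- data.frame(
      chrom = a$chrom, start = max(1L, a$primary_start + 1L - flank),
      end = a$primary_end + flank)
    if (!is.na(a$secondary_start)) {
      iv[[length(iv) + 1L]] <- data.frame(
        chrom = a$chrom, start = max(1L, a$secondary_start + 1L - flank),
        end = a$secondary_end + flank)
    }
  }
  for (i in seq_len(nrow(transcripts))) {
    t0 <- as.integer(transcripts$tss[i])
    iv[[length(iv) + 1L]] <- data.frame(chrom = transcripts$chrom[i],
                                        start = max(1L, t0 + 1L - flank),
                                        end = t0 + flank)
  }
  df <- do.call(rbind, iv)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)))
}

#' Write proximal reference regions as BED
#' @param proximal GRanges from [proximal_reference()]
#' @param path BED path (0-based half-open on disk)
#' @export
write_proximal_bed <- function(proximal, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(proximal)),
                   start = GenomicRanges::start(proximal) - 1L,
                   end = GenomicRanges::end(proximal))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Enumerate scored off-target sites by exhaustive genome scan
#'
#' Every NGG-adjacent 19-nt site on either strand of every contig is
#' compared to the query protospacer with the position-weighted mismatch
#' score; sites scoring below `score_cap` are returned (including the
#' on-target site itself, score 0). Regions in `mask` (e.g. mitochondrial
#' or pseudoautosomal stand-ins) are excluded. Exhaustive scanning gives
#' exact recall with the same score semantics as a sensitivity-tuned
#' aligner.
#'
#' @param protospacer 19-nt query protospacer (guide orientation)
#' @param genome named DNAStringSet (may be NULL when `index` is supplied)
#' @param score_cap keep sites with score strictly below this value
#' @param weights per-position penalties
#' @param mask optional GRanges of excluded regions
#' @param index optional precomputed [genome_site_index()] (build once when
#'   scanning many guides against the same genome)
#' @return data.frame: chrom, site_start, site_end (0-based half-open,
#'   22-bp footprint), strand, pam_3g_coord, n_mismatch, score
#' @export
enumerate_offtargets <- function(protospacer, genome = NULL, score_cap = 31,
                                 weights = default_mismatch_weights(),
                                 mask = NULL, index = NULL) {
  protospacer <- toupper(protospacer)
  plen <- length(weights)
  assert_that(nchar(protospacer) == plen,
              "protospacer length (%d) != weights length (%d)",
              nchar(protospacer), plen)
  if (is.null(index)) {
    assert_that(!is.null(genome), "supply a genome or a site index")
    index <- genome_site_index(genome, mask = mask)
  }
  q <- strsplit(protospacer, "")[[1]]
  res <- empty_offtargets()
  if (nrow(index$sites) > 0L) {
    mism <- index$mat != matrix(q, nrow(index$mat), plen, byrow = TRUE)
    score <- as.numeric(mism %*% weights)
    keep <- score < score_cap
    if (any(keep)) {
      s <- index$sites[keep, , drop = FALSE]
      res <- data.frame(
        chrom = s$chrom, site_start = s$site_start,
        site_end = s$site_start + 22L, strand = s$strand,
        pam_3g_coord = ifelse(s$strand == "+", s$site_start + 21L,
                              s$site_start),
        n_mismatch = rowSums(mism[keep, , drop = FALSE]),
        score = score[keep], stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res
}

empty_offtargets <- function() {
  data.frame(chrom = character(), site_start = integer(),
             site_end = integer(), strand = character(),
             pam_3g_coord = integer(), n_mismatch = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Index every NGG-adjacent site in a genome
#'
#' One exhaustive scan of all contigs and strands, reused across guides.
#' Masked regions (e.g. mitochondrial or pseudoautosomal stand-ins) are
#' excluded at index time.
#'
#' @param genome named DNAStringSet
#' @param mask optional GRanges of excluded regions
#' @return list with `sites` (chrom, site_start, strand, protospacer) and
#'   `mat` (site protospacer character matrix)
#' @export
genome_site_index <- function(genome, mask = NULL) {
  out <- list()
  for (chrom in names(genome)) {
    sites <- scan_pam_sites(as.character(genome[[chrom]]))
    if (nrow(sites) == 0L) next
    out[[chrom]] <- data.frame(chrom = chrom, site_start = sites$offset,
                               strand = sites$strand,
                               protospacer = sites$protospacer,
                               stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), site_start = integer(),
               strand = character(), protospacer = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  if (!is.null(mask) && nrow(sites) > 0L) {
    gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$site_start + 1L,
                                    sites$site_start + 22L))
    sites <- sites[!IRanges::overlapsAny(gr, mask), , drop = FALSE]
  }
  mat <- if (nrow(sites)) do.call(rbind, strsplit(sites$protospacer, "")) else
    matrix(character(0), 0, 19)
  list(sites = sites, mat = mat)
}

# count statistics driving tier assignment
offtarget_counts <- function(sites, proximal,
                             thresholds = c(proximal = 31, genome = 21)) {
  n_genome <- sum(sites$score < thresholds[["genome"]])
  if (nrow(sites) > 0L) {
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$site_start + 1L, sites$site_end))
    prox <- suppressWarnings(IRanges::overlapsAny(gr, proximal))
  } else prox <- logical(0)
  n_prox <- sum(prox & sites$score < thresholds[["proximal"]])
  c(n_proximal = n_prox, n_genome = n_genome)
}

#' Stringency tier labels, strictest first
#' @return character vector c("T0","T1","T2","T3","T4","FAIL")
#' @export
stringency_tiers <- function() c("T0", "T1", "T2", "T3", "T4", "FAIL")

#' Tier from off-target count statistics
#'
#' Tiers in descending stringency: T0 = at most 1 alignment scoring < 31 in
#' TSS-proximal space AND at most 1 scoring < 21 genome-wide (the on-target
#' site itself); T1 = 1 alignment under 31 proximal (no genomic
#' constraint); T2 = 1 alignment under 21 genome-wide; T3 = 2 alignments
#' under 31 proximal; T4 = 3 alignments under 31 proximal; otherwise FAIL.
#'
#' @param n_proximal number of alignments scoring < 31 in proximal space
#' @param n_genome number of alignments scoring < 21 genome-wide
#' @return tier label (see [stringency_tiers()])
#' @export
tier_from_counts <- function(n_proximal, n_genome) {
  if (n_proximal <= 1L && n_genome <= 1L) return("T0")
  if (n_proximal <= 1L) return("T1")
  if (n_genome <= 1L) return("T2")
  if (n_proximal <= 2L) return("T3")
  if (n_proximal <= 3L) return("T4")
  "FAIL"
}

#' Classify the off-target stringency tier of an sgRNA
#'
#' @param sites scored site table from [enumerate_offtargets()] (must
#'   include the on-target site, score 0 — its absence indicates an
#'   enumeration bug and raises an error)
#' @param proximal GRanges from [proximal_reference()]
#' @param thresholds named score thresholds (proximal = 31, genome = 21)
#' @return list: `tier`, `n_proximal`, `n_genome`
#' @export
classify_stringency <- function(sites, proximal,
                                thresholds = c(proximal = 31, genome = 21)) {
  if (!any(sites$score == 0))
    stopf("on-target site (score 0) missing from site list")
  ct <- offtarget_counts(sites, proximal, thresholds)
  list(tier = tier_from_counts(ct[["n_proximal"]], ct[["n_genome"]]),
       n_proximal = ct[["n_proximal"]], n_genome = ct[["n_genome"]])
}

#' Off-target report for a set of candidates
#'
#' Runs the exhaustive scan and tier classification per candidate and
#' returns the TSV-shaped report (sgRNA id, counts, tier).
#'
#' @param cands candidate data.frame with `id` and `protospacer_genomic`
#' @param genome named DNAStringSet
#' @param proximal GRanges of proximal regions
#' @param weights per-position penalties
#' @param mask optional excluded regions
#' @param index optional precomputed [genome_site_index()]
#' @return data.frame: id, n_proximal_lt31, n_genome_lt21, tier
#' @export
offtarget_report <- function(cands, genome, proximal,
                             weights = default_mismatch_weights(),
                             mask = NULL, index = NULL) {
  if (is.null(index)) index <- genome_site_index(genome, mask = mask)
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    sites <- enumerate_offtargets(cands$protospacer_genomic[i],
                                  score_cap = 31, weights = weights,
                                  index = index)
    cl <- classify_stringency(sites, proximal)
    data.frame(id = cands$id[i], n_proximal_lt31 = cl$n_proximal,
               n_genome_lt21 = cl$n_genome, tier = cl$tier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
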