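#' Read a multi-contig genome FASTA
#' @param path FASTA path
#' @return named DNAStringSet (names trimmed to the first word)
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a genomic signal track (BigWig or bedGraph)
#' @param path file path; format chosen by extension (.bw/.bigwig vs
#'   .bedgraph/.bdg/.bg)
#' @return GRanges with a `score` column
#' @export
read_signal_track <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    rtracklayer::import(path, format = "BigWig")
  } else {
    rtracklayer::import(path, format = "bedGraph")
  }
}

# strand-aware edges of a 0-based half-open TSS range.
# "upstream"/"downstream" are in the gene's transcriptional direction;
# relative position of a coordinate x to an edge e is x - e on "+",
# e - x on "-" (positive = downstream).
tss_edges <- function(start, end, strand) {
  if (strand == "+") c(up = start, down = end) else c(up = end, down = start)
}

rel_pos <- function(coord, edge, strand) {
  if (strand == "+") coord - edge else edge - coord
}

#' Enumeration windows for CRISPRi and CRISPRa
#'
#' CRISPRi candidates lie within -25..+500 bp of a TSS-range edge; CRISPRa
#' candidates within -550..-25 bp (upstream of the TSS).
#' @param mode "CRISPRi" or "CRISPRa"
#' @return integer window c(lo, hi) in relative coordinates
#' @export
mode_window <- function(mode = c("CRISPRi", "CRISPRa")) {
  mode <- match.arg(mode)
  if (mode == "CRISPRi") c(-25L, 500L) else c(-550L, -25L)
}

#' Enumerate candidate sgRNAs around the TSS ranges of one gene
#'
#' Scans both genomic strands for 19-nt protospacers followed by an NGG PAM
#' whose position (the genomic coordinate of the 3' G of the PAM, expressed
#' relative to the gene's transcriptional direction) falls within the mode's
#' window of the upstream or downstream edge of the primary or secondary
#' TSS range. Each separately-targeted TSS unit (P1/P2 more than 1 kb apart)
#' is enumerated independently and candidates carry the unit's `tss_id`.
#' Protospacers containing ambiguous bases are skipped; windows running past
#' a contig end are truncated with a warning.
#'
#' @param genome named DNAStringSet
#' @param ann one-row TSS annotation (see [assign_tss()])
#' @param mode "CRISPRi" or "CRISPRa"
#' @param window optional c(lo, hi) override of [mode_window()]
#' @return data.frame of candidates: id, tss_id, gene, gene_strand, chrom,
#'   strand, pam_3g_coord, site_start, site_end (22-bp footprint, 0-based
#'   half-open), protospacer_genomic (19 nt), expression_seq (20 nt,
#'   5' G prepended)
#' @export
enumerate_candidates <- function(genome, ann, mode = c("CRISPRi", "CRISPRa"),
                                 window = NULL) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- mode_window(mode)
  units <- expand_tss_units(ann)
  out <- lapply(seq_len(nrow(units)), function(i)
    enumerate_unit(genome, units[i, ], ann, window))
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_candidates()
  res
}

empty_candidates <- function() {
  data.frame(id = character(), tss_id = character(), gene = character(),
             gene_strand = character(), chrom = character(),
             strand = character(), pam_3g_coord = integer(),
             site_start = integer(), site_end = integer(),
             protospacer_genomic = character(), expression_seq = character(),
             stringsAsFactors = FALSE)
}

enumerate_unit <- function(genome, unit, ann, window) {
  chrom <- unit$chrom
  if (!chrom %in% names(genome)) stopf("contig '%s' not in genome", chrom)
  clen <- length(genome[[chrom]])
  edges <- tss_edges(unit$start, unit$end, unit$strand)
  # genomic interval of allowed pam_3g coordinates (union over both edges)
  if (unit$strand == "+") {
    lo <- min(edges) + window[1]; hi <- max(edges) + window[2]
  } else {
    lo <- min(edges) - window[2]; hi <- max(edges) - window[1]
  }
  # a 22-bp site footprint extends up to 21 bp from the pam coordinate
  scan_lo <- lo - 22L; scan_hi <- hi + 22L
  if (scan_lo < 0L || scan_hi > clen) {
    warnf("enumeration window for %s truncated at contig '%s' end",
          unit$tss_id, chrom)
    scan_lo <- max(0L, scan_lo); scan_hi <- min(clen, scan_hi)
  }
  if (scan_hi - scan_lo < 22L) return(NULL)
  seq <- as.character(Biostrings::subseq(genome[[chrom]], scan_lo + 1L, scan_hi))
  sites <- scan_pam_sites(seq)
  if (nrow(sites) == 0L) return(NULL)
  sites$site_start <- sites$offset + scan_lo           # 0-based genomic
  sites$site_end <- sites$site_start + 22L
  sites$pam_3g_coord <- ifelse(sites$strand == "+",
                               sites$site_end - 1L, sites$site_start)
  ru <- vapply(sites$pam_3g_coord, rel_pos, numeric(1),
               edge = edges["up"], strand = unit$strand)
  rd <- vapply(sites$pam_3g_coord, rel_pos, numeric(1),
               edge = edges["down"], strand = unit$strand)
  # union of the windows anchored at the upstream and downstream edges
  keep <- (ru >= window[1] & ru <= window[2]) |
          (rd >= window[1] & rd <= window[2])
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) return(NULL)
  sites <- sites[!duplicated(sites[, c("pam_3g_coord", "strand")]), , drop = FALSE]
  data.frame(
    id = sprintf("%s_%s_%d.%s", unit$tss_id, chrom, sites$pam_3g_coord, sites$strand),
    tss_id = unit$tss_id, gene = unit$gene, gene_strand = unit$strand,
    chrom = chrom, strand = sites$strand, pam_3g_coord = sites$pam_3g_coord,
    site_start = sites$site_start, site_end = sites$site_end,
    protospacer_genomic = sites$protospacer,
    expression_seq = paste0("G", sites$protospacer),
    stringsAsFactors = FALSE, row.names = NULL)
}

# all 19nt+NGG sites on both strands of a sequence string.
# offset = 0-based start of the 22-bp footprint within `seq`.
scan_pam_sites <- function(seq) {
  n <- nchar(seq)
  res <- list()
  if (n >= 22L) {
    # + strand: [proto 19][N][G][G]; GG at footprint offsets 20,21
    gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
    gg <- gg[gg > 0]
    starts <- gg - 20L          # 1-based footprint start (GG at 21..22)
    starts <- starts[starts >= 1L & (starts + 21L) <= n]
    if (length(starts)) {
      proto <- substring(seq, starts, starts + 18L)
      pam_n <- substring(seq, starts + 19L, starts + 19L)
      ok <- !grepl("[^ACGT]", proto) & pam_n %in% c("A", "C", "G", "T")
      if (any(ok)) {
        res[[length(res) + 1L]] <- data.frame(
          offset = starts[ok] - 1L, strand = "+",
          protospacer = proto[ok], stringsAsFactors = FALSE)
      }
    }
    # - strand: genomic CC at footprint offsets 0,1; protospacer is the
    # reverse complement of footprint bases 3..21
    cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
    cc <- cc[cc > 0]
    starts <- cc               # 1-based footprint start
    starts <- starts[(starts + 21L) <= n]
    if (length(starts)) {
      proto_fwd <- substring(seq, starts + 3L, starts + 21L)
      pam_n <- substring(seq, starts + 2L, starts + 2L)
      ok <- !grepl("[^ACGT]", proto_fwd) & pam_n %in% c("A", "C", "G", "T")
      if (any(ok)) {
        res[[length(res) + 1L]] <- data.frame(
          offset = starts[ok] - 1L, strand = "-",
          protospacer = revcomp(proto_fwd[ok]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(offset = integer(), strand = character(),
                      protospacer = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Signed distances from candidates to TSS-range edges
#'
#' Distances run from the genomic coordinate of the 3' G of the PAM to the
#' upstream and downstream edge of the primary and (if present) secondary
#' TSS range. Sign convention: positive = downstream of the edge in the
#' gene's transcriptional direction. Missing secondary ranges give NA
#' distances (flagged, not zeroed).
#'
#' @param cands candidate data.frame from [enumerate_candidates()]
#' @param ann one-row TSS annotation
#' @return data.frame: dist_primary_up, dist_primary_down,
#'   dist_secondary_up, dist_secondary_down
#' @export
position_features <- function(cands, ann) {
  if (nrow(cands) > 0L && any(cands$chrom != ann$chrom))
    stopf("candidate and TSS annotation on different chromosomes")
  strand <- ann$strand
  pe <- tss_edges(ann$primary_start, ann$primary_end, strand)
  d <- data.frame(
    dist_primary_up = vapply(cands$pam_3g_coord, rel_pos, numeric(1),
                             edge = pe["up"], strand = strand),
    dist_primary_down = vapply(cands$pam_3g_coord, rel_pos, numeric(1),
                               edge = pe["down"], strand = strand))
  if (!is.na(ann$secondary_start)) {
    se <- tss_edges(ann$secondary_start, ann$secondary_end, strand)
    d$dist_secondary_up <- vapply(cands$pam_3g_coord, rel_pos, numeric(1),
                                  edge = se["up"], strand = strand)
    d$dist_secondary_down <- vapply(cands$pam_3g_coord, rel_pos, numeric(1),
                                    edge = se["down"], strand = strand)
  } else {
    d$dist_secondary_up <- NA_real_
    d$dist_secondary_down <- NA_real_
  }
  d
}

# target-site context in guide orientation:
# [flank5][protospacer 19][PAM 3][flank3]
candidate_context <- function(cands, genome, flank5 = 4L, flank3 = 3L) {
  vapply(seq_len(nrow(cands)), function(i) {
    chrom <- cands$chrom[i]
    clen <- length(genome[[chrom]])
    if (cands$strand[i] == "+") {
      lo <- cands$site_start[i] - flank5; hi <- cands$site_end[i] + flank3
    } else {
      lo <- cands$site_start[i] - flank3; hi <- cands$site_end[i] + flank5
    }
    if (lo < 0L || hi > clen) return(NA_character_)
    s <- as.character(Biostrings::subseq(genome[[chrom]], lo + 1L, hi))
    if (cands$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
}

#' Sequence features of sgRNA target sites
#'
#' Computes, for each candidate, per-position base one-hot indicators over
#' the 5' flank, protospacer, PAM and 3' flank; dinucleotide one-hot
#' indicators at every adjacent position pair of that context; base counts
#' and GC fraction of the protospacer; the longest homopolymer run per base
#' anywhere in the protospacer (a single, tested definition); and the
#' protospacer length. Context containing ambiguous bases yields NA for the
#' affected features.
#'
#' @param cands candidate data.frame
#' @param genome named DNAStringSet
#' @param flank5,flank3 flanking extents (nt) included in positional one-hots
#' @return numeric data.frame of features, one row per candidate
#' @export
sequence_features <- function(cands, genome, flank5 = 4L, flank3 = 3L) {
  ctx <- candidate_context(cands, genome, flank5, flank3)
  ctx_len <- flank5 + 19L + 3L + flank3
  pos_labels <- c(paste0("m", rev(seq_len(flank5))),          # 5' flank
                  paste0("p", 1:19),                          # protospacer
                  "pamN", "pamG1", "pamG2",                   # PAM
                  paste0("f", seq_len(flank3)))               # 3' flank
  bases <- c("A", "C", "G", "T")
  n <- nrow(cands)
  chm <- matrix(NA_character_, n, ctx_len)
  ok <- !is.na(ctx) & nchar(ctx) == ctx_len
  if (any(ok)) chm[ok, ] <- do.call(rbind, strsplit(ctx[ok], ""))

  cols <- list()
  # positional one-hots (PAM G1/G2 are fixed by enumeration; kept out)
  keep_pos <- setdiff(seq_len(ctx_len), flank5 + 19L + c(2L, 3L))
  for (j in keep_pos) {
    for (b in bases) {
      v <- as.numeric(chm[, j] == b)
      cols[[paste0("base_", pos_labels[j], "_", b)]] <- v
    }
  }
  # dinucleotide one-hots over every adjacent pair of the full context
  dinucs <- as.vector(outer(bases, bases, paste0))
  for (j in seq_len(ctx_len - 1L)) {
    pair <- paste0(chm[, j], chm[, j + 1L])
    lab <- paste0(pos_labels[j], pos_labels[j + 1L])
    for (dn in dinucs) {
      cols[[paste0("dinuc_", lab, "_", dn)]] <- as.numeric(pair == dn)
    }
  }
  proto <- cands$protospacer_genomic
  proto_ok <- !grepl("[^ACGT]", proto)
  for (b in bases) {
    v <- vapply(proto, function(s)
      lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), numeric(1))
    v[!proto_ok] <- NA_real_
    cols[[paste0("count_", b)]] <- unname(v)
    r <- vapply(proto, longest_run, numeric(1), base = b)
    r[!proto_ok] <- NA_real_
    cols[[paste0("homopolymer_", b)]] <- unname(r)
  }
  gc <- (cols$count_G + cols$count_C) / nchar(proto)
  cols$gc_fraction <- gc
  cols$protospacer_length <- nchar(proto)
  out <- as.data.frame(cols, check.names = FALSE)
  # one-hot columns from unreadable contexts stay NA
  onehot <- grepl("^(base|dinuc)_", names(out))
  out[!ok, onehot] <- NA_real_
  out
}

# longest run of `base` anywhere in sequence `s` (0 if absent)
longest_run <- function(s, base) {
  r <- rle(strsplit(s, "")[[1]])
  runs <- r$lengths[r$values == base]
  if (length(runs)) max(runs) else 0L
}

#' Chromatin features: per-track mean signal over the target site
#'
#' Averages the per-base track signal over the 22-bp target site including
#' the PAM. Bases not covered by any track interval contribute 0; a site
#' with no overlapping data at all (or on a contig absent from the track)
#' is marked missing (NA), never silently zeroed.
#'
#' @param cands candidate data.frame
#' @param tracks named list of GRanges with a numeric `score` column
#' @return data.frame with one `chromatin_<name>` column per track
#' @export
chromatin_features <- function(cands, tracks) {
  sites <- GenomicRanges::GRanges(
    cands$chrom, IRanges::IRanges(start = cands$site_start + 1L,
                                  end = cands$site_end))
  out <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    # suppress seqlevel-mismatch chatter: a contig absent from the track is
    # a legitimate "no data" case handled below
    hits <- suppressWarnings(GenomicRanges::findOverlaps(sites, tr))
    v <- rep(NA_real_, nrow(cands))
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::pintersect(IRanges::ranges(sites)[qi], IRanges::ranges(tr)[si])
      contrib <- tr$score[si] * IRanges::width(ov)
      sums <- tapply(contrib, qi, sum)
      idx <- as.integer(names(sums))
      v[idx] <- as.numeric(sums) / IRanges::width(sites)[idx]
    }
    out[[paste0("chromatin_", nm)]] <- v
  }
  as.data.frame(out, check.names = FALSE)
}

#' Assemble the full feature matrix for a set of candidates
#'
#' Combines position, sequence, RNA-structure and chromatin features into a
#' single numeric data.frame with a recorded roster (column names, kinds and
#' a roster hash). Feature kinds drive linearization downstream: "position"
#' columns are fit with kernel position curves, "numeric" columns are
#' binned, "binary" columns pass through.
#'
#' @param cands candidate data.frame for one gene/TSS
#' @param genome named DNAStringSet
#' @param ann one-row TSS annotation matching `cands`
#' @param tracks optional named list of signal-track GRanges (may be empty,
#'   e.g. for genomes without chromatin data)
#' @param flank5,flank3 sequence-feature flank extents
#' @param constant_region sgRNA scaffold for folding features
#' @param fold compute RNA-structure features (set FALSE to skip)
#' @return data.frame with attributes `kind` (named character) and
#'   `roster_hash`
#' @export
build_feature_matrix <- function(cands, genome, ann, tracks = list(),
                                 flank5 = 4L, flank3 = 3L,
                                 constant_region = sgrna_constant_region(),
                                 fold = TRUE) {
  pos <- position_features(cands, ann)
  seqf <- sequence_features(cands, genome, flank5, flank3)
  parts <- list(pos, seqf)
  if (fold) parts <- c(parts, list(rna_features(cands$expression_seq, constant_region)))
  if (length(tracks)) parts <- c(parts, list(chromatin_features(cands, tracks)))
  fm <- do.call(cbind, parts)
  kind <- rep("numeric", ncol(fm))
  names(kind) <- names(fm)
  kind[grepl("^dist_", names(fm))] <- "position"
  kind[grepl("^(base|dinuc)_", names(fm))] <- "binary"
  attr(fm, "kind") <- kind
  attr(fm, "roster_hash") <- fnv1a_hash(paste(names(fm), kind, sep = ":"))
  rownames(fm) <- cands$id
  fm
}

#' Feature matrices for many genes, stacked
#'
#' Runs [enumerate_candidates()] and [build_feature_matrix()] per annotation
#' row and stacks the results (all rows share one roster).
#'
#' @inheritParams build_feature_matrix
#' @param annotations TSS annotation table
#' @param mode "CRISPRi" or "CRISPRa"
#' @param ... passed to [build_feature_matrix()]
#' @return list with `candidates` (data.frame) and `features` (data.frame)
#' @export
featurize_genes <- function(genome, annotations, mode = "CRISPRi",
                            tracks = list(), ...) {
  all_c <- list(); all_f <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    cands <- enumerate_candidates(genome, ann, mode)
    if (nrow(cands) == 0L) next
    fm <- build_feature_matrix(cands, genome, ann, tracks = tracks, ...)
    all_c[[length(all_c) + 1L]] <- cands
    all_f[[length(all_f) + 1L]] <- fm
  }
  cands <- do.call(rbind, all_c)
  kind <- attr(all_f[[1]], "kind"); rh <- attr(all_f[[1]], "roster_hash")
  feats <- do.call(rbind, all_f)
  attr(feats, "kind") <- kind
  attr(feats, "roster_hash") <- rh
  list(candidates = cands, features = feats)
}
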