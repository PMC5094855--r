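#' Parse CAGE peaks from BED text
#'
#' Reads BED6-compatible lines describing CAGE (cap analysis of gene
#' expression) peaks, as distributed by the FANTOM consortium TSS classifier
#' ("p1@GENE" = strongest peak assigned to GENE, "p2@GENE" = second peak).
#' Coordinates are kept 0-based half-open throughout the package.
#'
#' An optional 7th column may carry the peak tier ("robust" or "permissive");
#' peaks without a tier column are treated as robust.
#'
#' @param x path to a BED file, or a character vector of BED lines
#' @return data.frame of class `cage_peaks` with columns chrom, start, end,
#'   strand, label, tier, score
#' @export
parse_cage_bed <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(empty_cage_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L) stopf("BED line %d: expected >= 6 fields, got %d", i, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end)) stopf("BED line %d: non-numeric coordinates", i)
    if (!(start < end)) stopf("BED line %d: start must be < end", i)
    if (!f[6] %in% c("+", "-")) stopf("BED line %d: invalid strand '%s'", i, f[6])
    tier <- if (length(f) >= 7L && f[7] %in% c("robust", "permissive")) f[7] else "robust"
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           strand = f[6], label = f[4], tier = tier,
                           score = ifelse(is.na(score), 0, score),
                           stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, out)
  class(peaks) <- c("cage_peaks", "data.frame")
  peaks
}

empty_cage_peaks <- function() {
  peaks <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      tier = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  class(peaks) <- c("cage_peaks", "data.frame")
  peaks
}

# "p1"/"p2" rank of a peak label, NA if unlabeled
peak_rank <- function(label) {
  rank <- rep(NA_character_, length(label))
  rank[grepl("^p1(@|$)", label)] <- "p1"
  rank[grepl("^p2(@|$)", label)] <- "p2"
  rank
}

# gene symbol after "p1@"/"p2@", NA if none
peak_gene <- function(label) {
  g <- sub("^p[12]@", "", label)
  g[!grepl("^p[12]@", label)] <- NA_character_
  g
}

# distance from a point coordinate to the nearest edge of a 0-based
# half-open interval; 0 if the point lies inside
edge_distance <- function(start, end, coord) {
  pmax(0L, start - coord, coord - (end - 1L))
}

#' Default distance parameters for TSS assignment
#'
#' @return list with matched_max_dist (30 kb), primary_max_dist (500 bp),
#'   unlabeled_max_dist (200 bp), merge_max_gap (1 kb)
#' @export
tss_params <- function(matched_max_dist = 30000L, primary_max_dist = 500L,
                       unlabeled_max_dist = 200L, merge_max_gap = 1000L) {
  list(matched_max_dist = as.integer(matched_max_dist),
       primary_max_dist = as.integer(primary_max_dist),
       unlabeled_max_dist = as.integer(unlabeled_max_dist),
       merge_max_gap = as.integer(merge_max_gap))
}

#' Assign a hybrid CAGE/transcript TSS annotation to one gene
#'
#' Applies the matching hierarchy in strict order:
#' 1. same-strand peaks labeled `p1@gene`/`p2@gene` within 30 kb of any
#'    transcript TSS for the gene (support `cage_matched_peaks`; among
#'    multiple matches, the peak closest to a known transcript TSS wins,
#'    ties broken by lower genomic coordinate);
#' 2. otherwise any same-strand peak labeled "p1" or "p2" within 500 bp
#'    (support `cage_primary_peaks`);
#' 3. otherwise a robust, then permissive, peak within 200 bp
#'    (support `cage_robust_peak` / `cage_permissive_peak`);
#' 4. otherwise the transcript-model coordinate itself (support `annotation`,
#'    a 1-bp range at the 5'-most transcript TSS).
#'
#' Where both a primary (p1) and secondary (p2) peak are found, they are
#' merged into a single "P1P2" range unless they are more than 1 kb apart,
#' in which case the secondary range is kept separate. Secondary peaks are
#' only used if they pass the robust tier. All distances are measured from
#' the nearest peak edge to the transcript TSS coordinate.
#'
#' @param gene gene symbol
#' @param transcripts data.frame with columns gene, transcript, chrom,
#'   strand, tss (0-based coordinate of the transcript 5' end)
#' @param peaks `cage_peaks` data.frame from [parse_cage_bed()]
#' @param params distances, see [tss_params()]
#' @return one-row data.frame: gene, chrom, strand, primary_start,
#'   primary_end, secondary_start, secondary_end, support, merged_p1p2
#' @export
assign_tss <- function(gene, transcripts, peaks, params = tss_params()) {
  tx <- transcripts[toupper(transcripts$gene) == toupper(gene), , drop = FALSE]
  if (nrow(tx) == 0L) stopf("gene '%s' has no transcript TSS", gene)
  if (length(unique(tx$strand)) != 1L)
    stopf("gene '%s': contradictory strands among transcripts", gene)
  if (length(unique(tx$chrom)) != 1L)
    stopf("gene '%s': transcripts on multiple chromosomes", gene)
  strand <- tx$strand[1]; chrom <- tx$chrom[1]
  if (!strand %in% c("+", "-")) stopf("gene '%s': invalid strand", gene)
  tsses <- as.integer(tx$tss)

  p <- peaks[peaks$chrom == chrom & peaks$strand == strand, , drop = FALSE]
  if (nrow(p) > 0L) {
    p$rank <- peak_rank(p$label)
    p$pgene <- peak_gene(p$label)
    p$dist <- vapply(seq_len(nrow(p)), function(i)
      min(edge_distance(p$start[i], p$end[i], tsses)), integer(1))
  }

  pick_closest <- function(q) {
    q <- q[order(q$dist, q$start), , drop = FALSE]
    q[1L, , drop = FALSE]
  }

  make_ann <- function(primary, secondary, support) {
    merged <- FALSE
    if (!is.null(secondary)) {
      gap <- max(0L, max(primary$start, secondary$start) -
                      min(primary$end, secondary$end))
      if (gap <= params$merge_max_gap) {
        primary <- data.frame(start = min(primary$start, secondary$start),
                              end = max(primary$end, secondary$end))
        secondary <- NULL
        merged <- TRUE
      }
    }
    data.frame(gene = gene, chrom = chrom, strand = strand,
               primary_start = primary$start, primary_end = primary$end,
               secondary_start = if (is.null(secondary)) NA_integer_ else secondary$start,
               secondary_end = if (is.null(secondary)) NA_integer_ else secondary$end,
               support = support, merged_p1p2 = merged,
               stringsAsFactors = FALSE)
  }

  if (nrow(p) > 0L) {
    # rule 1: matched p1@gene / p2@gene peaks within 30 kb
    m <- p[!is.na(p$pgene) & toupper(p$pgene) == toupper(gene) &
             p$dist <= params$matched_max_dist, , drop = FALSE]
    m2 <- m[m$rank == "p2" & m$tier == "robust", , drop = FALSE]
    m1 <- m[m$rank == "p1", , drop = FALSE]
    if (nrow(m1) > 0L || nrow(m2) > 0L) {
      if (nrow(m1) > 0L) {
        primary <- pick_closest(m1)
        secondary <- if (nrow(m2) > 0L) pick_closest(m2) else NULL
      } else {
        primary <- pick_closest(m2); secondary <- NULL
      }
      return(make_ann(primary, secondary, "cage_matched_peaks"))
    }

    # rule 2: any p1/p2-labeled peak within 500 bp
    u <- p[!is.na(p$rank) & p$dist <= params$primary_max_dist, , drop = FALSE]
    if (nrow(u) > 0L) {
      u1 <- u[u$rank == "p1", , drop = FALSE]
      primary <- if (nrow(u1) > 0L) pick_closest(u1) else pick_closest(u)
      secondary <- NULL
      if (nrow(u1) > 0L && !is.na(peak_gene(primary$label))) {
        u2 <- u[u$rank == "p2" & u$tier == "robust" & !is.na(u$pgene) &
                  toupper(u$pgene) == toupper(peak_gene(primary$label)), , drop = FALSE]
        if (nrow(u2) > 0L) secondary <- pick_closest(u2)
      }
      return(make_ann(primary, secondary, "cage_primary_peaks"))
    }

    # rule 3: robust, then permissive, peak within 200 bp
    r <- p[p$tier == "robust" & p$dist <= params$unlabeled_max_dist, , drop = FALSE]
    if (nrow(r) > 0L) return(make_ann(pick_closest(r), NULL, "cage_robust_peak"))
    pm <- p[p$tier == "permissive" & p$dist <= params$unlabeled_max_dist, , drop = FALSE]
    if (nrow(pm) > 0L) return(make_ann(pick_closest(pm), NULL, "cage_permissive_peak"))
  }

  # rule 4: transcript model only; 5'-most transcript TSS as a 1-bp range
  tss0 <- if (strand == "+") min(tsses) else max(tsses)
  make_ann(data.frame(start = tss0, end = tss0 + 1L), NULL, "annotation")
}

#' Assign TSS annotations for every gene in a transcript table
#'
#' @inheritParams assign_tss
#' @return data.frame, one row per gene (see [assign_tss()])
#' @export
assign_tss_table <- function(transcripts, peaks, params = tss_params()) {
  genes <- unique(transcripts$gene)
  do.call(rbind, lapply(genes, assign_tss, transcripts = transcripts,
                        peaks = peaks, params = params))
}

#' Read a transcript TSS table (TSV: gene, transcript, chrom, strand, tss)
#' @param path TSV path with header
#' @return data.frame
#' @export
read_transcript_tsv <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "chrom", "strand", "tss")
  missing <- setdiff(need, names(tx))
  if (length(missing)) stopf("transcript table missing columns: %s",
                             paste(missing, collapse = ", "))
  tx
}

#' Write / read TSS annotations as TSV
#'
#' Column order: gene, chrom, strand, primary_start, primary_end,
#' secondary_start, secondary_end, support, merged_p1p2 (0-based half-open).
#'
#' @param ann annotation data.frame from [assign_tss_table()]
#' @param path output TSV path
#' @export
write_tss_annotations <- function(ann, path) {
  cols <- c("gene", "chrom", "strand", "primary_start", "primary_end",
            "secondary_start", "secondary_end", "support", "merged_p1p2")
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_tss_annotations
#' @export
read_tss_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand an annotation into separately-targeted TSS units
#'
#' A merged or single-range annotation yields one unit ("P1P2" or "P1");
#' an annotation with a separate secondary range yields two units ("P1",
#' "P2"), each targeted independently (e.g. by its own 10 sgRNAs).
#'
#' @param ann annotation data.frame
#' @return data.frame with tss_id, gene, chrom, strand, start, end, unit
#' @export
expand_tss_units <- function(ann) {
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    unit1 <- if (isTRUE(a$merged_p1p2)) "P1P2" else "P1"
    out <- data.frame(tss_id = paste0(a$gene, "_", unit1), gene = a$gene,
                      chrom = a$chrom, strand = a$strand,
                      start = a$primary_start, end = a$primary_end,
                      unit = unit1, stringsAsFactors = FALSE)
    if (!is.na(a$secondary_start)) {
      out <- rbind(out, data.frame(tss_id = paste0(a$gene, "_P2"),
                                   gene = a$gene, chrom = a$chrom,
                                   strand = a$strand, start = a$secondary_start,
                                   end = a$secondary_end, unit = "P2",
                                   stringsAsFactors = FALSE))
    }
    out
  })
  do.call(rbind, rows)
}
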