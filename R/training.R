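#' Select hit genes from screen effect sizes
#'
#' A gene is kept if |effect-size z-score x log10 p-value| >= the
#' discriminant threshold in ANY screen; the screen attaining the best
#' discriminant is recorded so that sgRNA phenotypes can be extracted from
#' the screen in which the gene was a hit. The default threshold of 20
#' defines the high-confidence training set; a relaxed threshold of 7 is
#' used when gathering empirical-evidence sgRNAs for library design.
#'
#' @param tables list of per-screen data.frames with columns gene, z, p
#'   (names of the list identify the screens)
#' @param discriminant_min threshold on |z x log10 p|
#' @return data.frame: gene, screen (where the gene was a hit),
#'   discriminant
#' @export
select_hit_genes <- function(tables, discriminant_min = 20) {
  if (is.null(names(tables)))
    names(tables) <- paste0("screen", seq_along(tables))
  rows <- lapply(names(tables), function(sn) {
    t <- tables[[sn]]
    p <- t$p
    if (any(p == 0)) {
      warnf("screen '%s': p = 0 replaced with smallest representable value", sn)
      p[p == 0] <- .Machine$double.xmin
    }
    data.frame(gene = t$gene, screen = sn,
               discriminant = abs(t$z * log10(p)), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  all <- all[all$discriminant >= discriminant_min, , drop = FALSE]
  if (nrow(all) == 0L) return(all)
  # per gene keep the screen with the strongest discriminant
  all <- all[order(all$gene, -all$discriminant), ]
  all[!duplicated(all$gene), , drop = FALSE]
}

#' Compute sgRNA activity scores from gene phenotypes
#'
#' Each sgRNA's phenotype is divided by the mean of the gene's top `top_k`
#' sgRNAs by absolute value (sign preserved), so a gene's strongest sgRNAs
#' score ~1. Genes whose top-k mean is 0 are dropped with a warning.
#'
#' @param phenotypes data.frame with columns sgrna, gene, phenotype
#' @param top_k number of strongest sgRNAs averaged per gene (default 3)
#' @return data.frame: sgrna, gene, phenotype, activity
#' @export
compute_activity_scores <- function(phenotypes, top_k = 3L) {
  out <- lapply(split(phenotypes, phenotypes$gene), function(g) {
    if (nrow(g) < top_k)
      stopf("gene '%s' has %d sgRNAs; need >= %d", g$gene[1], nrow(g), top_k)
    top <- g$phenotype[order(-abs(g$phenotype))][seq_len(top_k)]
    denom <- mean(top)
    if (denom == 0) {
      warnf("gene '%s': top-%d mean phenotype is 0; gene dropped",
            g$gene[1], top_k)
      return(NULL)
    }
    g$activity <- g$phenotype / denom
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write activity-score tables (TSV: sgrna, gene, phenotype,
#' activity)
#' @param x activity data.frame
#' @param path TSV path
#' @export
write_activity_table <- function(x, path) {
  utils::write.table(x[, c("sgrna", "gene", "phenotype", "activity")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
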