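#' Minimum-free-energy RNA secondary structure (base-pair energy model)
#'
#' Lightweight nested-structure folding used for sgRNA structure features.
#' Energies are per base pair (GC = -3, AU = -2, GU = -1 kcal/mol) with a
#' minimum hairpin loop of 3 nt; pseudoknots, stacking and loop entropies
#' are not modeled. This is a simplified stand-in for full nearest-neighbor
#' thermodynamic folding exposing the same two metrics: the minimum free
#' energy and the number of paired bases in the optimal structure.
#'
#' Deterministic: the traceback prefers leaving the 3' base unpaired, then
#' the 5'-most pairing partner, so identical input gives identical output.
#'
#' @param seq RNA or DNA sequence (T is read as U; N never pairs)
#' @param pair_energy named energies for "GC","AU","GU" (kcal/mol, negative)
#' @param min_loop minimum unpaired hairpin loop length (nt)
#' @return list with `mfe` (kcal/mol, <= 0), `n_paired` (bases in pairs),
#'   and `structure` (dot-bracket string)
#' @export
fold_rna <- function(seq, pair_energy = c(GC = -3, AU = -2, GU = -1),
                     min_loop = 3L) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stopf("fold_rna: empty sequence")
  s <- chartr("T", "U", seq)
  b <- strsplit(s, "")[[1]]
  if (any(!b %in% c("A", "C", "G", "U", "N")))
    stopf("fold_rna: invalid characters in sequence")
  code <- match(b, c("A", "C", "G", "U"))
  code[is.na(code)] <- 0L
  etab <- matrix(NA_real_, 4, 4)
  etab[2, 3] <- etab[3, 2] <- pair_energy[["GC"]]
  etab[1, 4] <- etab[4, 1] <- pair_energy[["AU"]]
  etab[3, 4] <- etab[4, 3] <- pair_energy[["GU"]]
  res <- .nussinov_fold(code, etab, as.integer(min_loop))
  db <- rep(".", length(b))
  paired <- which(res$pairing > 0)
  db[paired[res$pairing[paired] > paired]] <- "("
  db[paired[res$pairing[paired] < paired]] <- ")"
  list(mfe = res$mfe, n_paired = res$n_paired,
       structure = paste(db, collapse = ""))
}

#' Standard sgRNA constant region (scaffold) sequence
#'
#' The optimized S. pyogenes sgRNA scaffold, used as the default constant
#' region when computing guide + scaffold folding metrics.
#' @return character scalar (DNA alphabet)
#' @export
sgrna_constant_region <- function() {
  paste0("GTTTAAGAGCTAAGCTGGAAACAGCATAGCAAGTTTAAATAAGGCTAGTCCGTTATCAAC",
         "TTGAAAAAGTGGCACCGAGTCGGTGC")
}

#' RNA-structure features for sgRNA expression sequences
#'
#' Computes the folding minimum free energy and paired-base count for the
#' 20-nt guide alone and for the guide joined to the sgRNA constant region.
#'
#' @param expression_seq character vector of 20-nt expression sequences
#' @param constant_region scaffold sequence appended 3' of the guide
#' @return data.frame: mfe_guide, paired_guide, mfe_full, paired_full
#' @export
rna_features <- function(expression_seq, constant_region = sgrna_constant_region()) {
  if (any(!nzchar(expression_seq))) stopf("rna_features: empty sequence")
  res <- lapply(expression_seq, function(g) {
    fg <- fold_rna(g)
    ff <- fold_rna(paste0(g, constant_region))
    c(fg$mfe, fg$n_paired, ff$mfe, ff$n_paired)
  })
  m <- do.call(rbind, res)
  data.frame(mfe_guide = m[, 1], paired_guide = m[, 2],
             mfe_full = m[, 3], paired_full = m[, 4])
}
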