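# Shared toy fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_ref <- function() cached("ref", function() {
  make_toy_reference(seed = 101, n_genes = 14, contig_len = 60000)
})

toy_annotation <- function() cached("ann", function() {
  assign_tss_table(toy_ref()$transcripts, toy_ref()$peaks)
})

toy_featurized <- function() cached("fz", function() {
  ref <- toy_ref()
  featurize_genes(ref$genome, toy_annotation(), "CRISPRi",
                  tracks = ref$tracks)
})

# single-gene transcript table helper
tx1 <- function(gene = "GENEA", chrom = "chr1", strand = "+", tss = 10000L) {
  data.frame(gene = gene, transcript = paste0(gene, ".t1"), chrom = chrom,
             strand = strand, tss = tss, stringsAsFactors = FALSE)
}

# BED line helper matching parse_cage_bed's 7-column convention
bed_line <- function(chrom, start, end, label, strand, tier = "robust",
                     score = 5) {
  sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%s", chrom, start, end, label, score,
          strand, tier)
}

# genome with a planted + strand site: proto19 + "TGG" at 0-based `at`
planted_genome <- function(proto, at, len = 3000L, seed = 99L,
                           pam = "TGG", name = "chrT") {
  stopifnot(at + nchar(proto) + 3L <= len)
  g <- guidescreen:::with_seed(seed, random_dna(len))
  # blank AG/GG-rich stretches are fine; just splice the site in
  before <- substr(g, 1L, at)
  after <- substr(g, at + nchar(proto) + 4L, len)
  s <- Biostrings::DNAStringSet(paste0(before, proto, pam, after))
  names(s) <- name
  s
}

# minimal candidate row for design-module tests
mk_cand <- function(id, tss_id = "G1_P1", gene = "G1", chrom = "chrT",
                    strand = "+", pam = 1000L, proto = NULL) {
  if (is.null(proto)) proto <- substr(random_dna(19), 1, 19)
  data.frame(id = id, tss_id = tss_id, gene = gene, gene_strand = "+",
             chrom = chrom, strand = strand, pam_3g_coord = pam,
             site_start = pam - 21L, site_end = pam + 1L,
             protospacer_genomic = proto,
             expression_seq = paste0("G", proto), stringsAsFactors = FALSE)
}

# candidate table for selection tests: n candidates spaced >= 4 bp apart,
# protospacers free of restriction sites
mk_pool <- function(n, tss_id = "G1_P1", gene = "G1", start_pam = 1000L,
                    spacing = 10L, seed = 1L) {
  guidescreen:::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- random_dna(19)
      while (has_forbidden_site(paste0("G", substr(p, 1, 19))))
        p <- random_dna(19)
      mk_cand(sprintf("%s_c%02d", tss_id, i), tss_id = tss_id, gene = gene,
              pam = start_pam + (i - 1L) * spacing, proto = p)
    }))
  })
}

tiers_for <- function(cands, tier = "T0") {
  data.frame(id = cands$id, tier = tier, stringsAsFactors = FALSE)
}

mk_units <- function(tss_id = "G1_P1", gene = "G1", chrom = "chrT",
                     strand = "+", start = 900L, end = 1100L) {
  data.frame(tss_id = tss_id, gene = gene, chrom = chrom, strand = strand,
             start = start, end = end, unit = "P1", stringsAsFactors = FALSE)
}
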