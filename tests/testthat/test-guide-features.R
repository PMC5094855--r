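mk_ann <- function(chrom = "chrT", strand = "+", ps = 1000L, pe = 1020L,
                   ss = NA_integer_, se = NA_integer_, gene = "G1") {
  data.frame(gene = gene, chrom = chrom, strand = strand,
             primary_start = ps, primary_end = pe, secondary_start = ss,
             secondary_end = se, support = "cage_matched_peaks",
             merged_p1p2 = FALSE, stringsAsFactors = FALSE)
}

test_that("enumeration equals a brute-force scan over the window (oracle)", {
  for (seed in c(1, 2, 3)) {
    g <- guidescreen:::with_seed(seed, random_dna(2600))
    genome <- Biostrings::DNAStringSet(g); names(genome) <- "chrT"
    for (strand in c("+", "-")) {
      ann <- mk_ann(strand = strand, ps = 1200L, pe = 1230L)
      for (mode in c("CRISPRi", "CRISPRa")) {
        cands <- enumerate_candidates(genome, ann, mode)
        # oracle: scan everything, filter by relative position per edge
        sites <- oracle_scan_sites(g)
        pam <- ifelse(sites$strand == "+", sites$offset0 + 21L, sites$offset0)
        edges <- if (strand == "+") c(1200L, 1230L) else c(1230L, 1200L)
        rel <- function(p, e) if (strand == "+") p - e else e - p
        w <- mode_window(mode)
        keep <- (rel(pam, edges[1]) >= w[1] & rel(pam, edges[1]) <= w[2]) |
                (rel(pam, edges[2]) >= w[1] & rel(pam, edges[2]) <= w[2])
        expected <- sites[keep, , drop = FALSE]
        got <- paste(cands$pam_3g_coord, cands$strand)
        want <- paste(pam[keep], expected$strand)
        expect_setequal(got, want)
        # protospacers agree and no candidate is duplicated
        expect_equal(sort(cands$protospacer_genomic),
                     sort(expected$protospacer))
        expect_false(any(duplicated(got)))
      }
    }
  }
})

test_that("reverse-complement symmetry of enumeration", {
  g <- guidescreen:::with_seed(7, random_dna(2400))
  genome <- Biostrings::DNAStringSet(g); names(genome) <- "chrT"
  ann <- mk_ann(strand = "+", ps = 1100L, pe = 1140L)
  cands <- enumerate_candidates(genome, ann, "CRISPRi")

  L <- nchar(g)
  genome_rc <- Biostrings::DNAStringSet(rc_string(g)); names(genome_rc) <- "chrT"
  ann_rc <- mk_ann(strand = "-", ps = L - 1140L, pe = L - 1100L)
  cands_rc <- enumerate_candidates(genome_rc, ann_rc, "CRISPRi")
  expect_setequal(cands$protospacer_genomic, cands_rc$protospacer_genomic)
})

test_that("window bounds are exact (-25/+500 CRISPRi, -550/-25 CRISPRa)", {
  # site with pam exactly at +500 from the downstream edge is included,
  # +501 is excluded; construct deterministic genome with planted sites
  proto <- "ACGTACGTACGTACGTACG"
  base <- guidescreen:::with_seed(13, gsub("[GC]", "A", random_dna(3000)))
  # no G or C in the base genome -> no PAMs on either strand except planted
  splice <- function(g, frag, at0) {
    paste0(substr(g, 1, at0), frag, substr(g, at0 + nchar(frag) + 1, nchar(g)))
  }
  ann <- mk_ann(ps = 1000L, pe = 1001L)
  # + strand: pam_3g at p means footprint start p-21 (0-based)
  for (spec in list(c(1501L, 1L), c(1502L, 0L),   # rel +500 in, +501 out
                    c(976L, 1L), c(974L, 0L))) {  # rel -25 in, -27 out
    p <- spec[1]
    g <- splice(base, paste0(proto, "TGG"), p - 21L)
    genome <- Biostrings::DNAStringSet(g); names(genome) <- "chrT"
    cands <- enumerate_candidates(genome, ann, "CRISPRi")
    expect_equal(nrow(cands), spec[2], info = sprintf("pam at %d", p))
  }
  # CRISPRa window: rel -25 in, rel -24 out
  for (spec in list(c(976L, 1L), c(977L, 0L), c(451L, 1L), c(449L, 0L))) {
    p <- spec[1]
    g <- splice(base, paste0(proto, "TGG"), p - 21L)
    genome <- Biostrings::DNAStringSet(g); names(genome) <- "chrT"
    cands <- enumerate_candidates(genome, ann, "CRISPRa")
    expect_equal(nrow(cands), spec[2], info = sprintf("CRISPRa pam at %d", p))
  }
})

test_that("expression sequence is the G-prepended 19-mer", {
  fz <- toy_featurized()
  expect_true(all(substr(fz$candidates$expression_seq, 1, 1) == "G"))
  expect_true(all(nchar(fz$candidates$expression_seq) == 20L))
  expect_equal(substring(fz$candidates$expression_seq, 2),
               fz$candidates$protospacer_genomic)
})

test_that("position features: sign convention and missing secondary", {
  cand <- mk_cand("c1", pam = 1150L)
  ann <- mk_ann(ps = 1000L, pe = 1000L)  # degenerate range: edge at 1000
  d <- position_features(cand, ann)
  expect_equal(d$dist_primary_up, 150)
  ann_m <- mk_ann(strand = "-", ps = 1000L, pe = 1000L)
  d2 <- position_features(cand, ann_m)
  expect_equal(d2$dist_primary_up, -150)
  expect_true(is.na(d$dist_secondary_up) && is.na(d$dist_secondary_down))
  # with a secondary range both distances appear
  ann_s <- mk_ann(ps = 1000L, pe = 1020L, ss = 3000L, se = 3020L)
  d3 <- position_features(cand, ann_s)
  expect_equal(d3$dist_secondary_up, 1150 - 3000)
  expect_error(position_features(mk_cand("c2", chrom = "chrX"), ann),
               "different chromosomes")
})

test_that("sequence features: homopolymers, GC, flank indicators", {
  proto <- "AAAGGGGCCTTTTTACGTA"   # runs: A=3 then T=5, G=4, C=2
  genome <- planted_genome(proto, at = 1000L, seed = 42)
  cand <- mk_cand("c1", chrom = "chrT", strand = "+", pam = 1021L,
                  proto = proto)
  cand$site_start <- 1000L; cand$site_end <- 1022L
  sf <- sequence_features(cand, genome)
  expect_equal(sf$homopolymer_A, 3)
  expect_equal(sf$homopolymer_T, 5)
  expect_equal(sf$homopolymer_G, 4)
  expect_equal(sf$count_G, 5)
  expect_equal(sf$gc_fraction, 8 / 19)
  expect_equal(sf$protospacer_length, 19)
  # all-GC protospacer has GC fraction 1
  gc <- strrep("GC", 10)
  proto2 <- substr(gc, 1, 19)
  genome2 <- planted_genome(proto2, at = 1000L, seed = 43)
  cand2 <- mk_cand("c2", strand = "+", pam = 1021L, proto = proto2)
  cand2$site_start <- 1000L; cand2$site_end <- 1022L
  expect_equal(sequence_features(cand2, genome2)$gc_fraction, 1)
  # G directly downstream of the PAM sets the flank indicator
  genome3 <- planted_genome(proto, at = 1000L, seed = 44)
  s3 <- as.character(genome3[[1]])
  substr(s3, 1023, 1023) <- "G"  # first base after the 22-bp site
  genome3 <- Biostrings::DNAStringSet(s3); names(genome3) <- "chrT"
  sf3 <- sequence_features(cand, genome3)
  expect_equal(sf3$base_f1_G, 1)
  # one-hot and dinucleotide indicators partition: exactly one per position
  onehot <- sf[grepl("^base_", names(sf))]
  expect_equal(sum(unlist(onehot)), 27)  # 4 flank5 + 19 + pamN + 3 flank3
  dn <- sf[grepl("^dinuc_", names(sf))]
  expect_equal(sum(unlist(dn)), 28)      # 28 adjacent pairs in the context
})

test_that("folding: unpairable and hairpin cases, determinism, oracle", {
  pa <- fold_rna(strrep("A", 20))
  expect_equal(pa$mfe, 0)
  expect_equal(pa$n_paired, 0)
  # perfect 8-bp stem with a 4-nt loop
  stem <- "GCGCGCGC"
  hp <- paste0(stem, "AAAA", rc_string(stem))
  fh <- fold_rna(hp)
  expect_lt(fh$mfe, 0)
  expect_gte(fh$n_paired, 16)
  expect_identical(fold_rna(hp), fold_rna(hp))
  # exhaustive-enumeration oracle on short random sequences
  for (seed in 1:8) {
    s <- guidescreen:::with_seed(seed + 500, random_dna(12))
    expect_equal(fold_rna(s)$mfe, oracle_fold_mfe(s), info = s)
  }
  expect_error(fold_rna(""), "empty")
})

test_that("rna_features returns guide and guide+scaffold metrics", {
  rf <- rna_features(c(strrep("A", 20), paste0("G", strrep("A", 19))))
  expect_equal(names(rf), c("mfe_guide", "paired_guide", "mfe_full",
                            "paired_full"))
  expect_equal(rf$mfe_guide, c(0, 0))
  expect_true(all(rf$mfe_full < 0))  # the scaffold alone folds
})

test_that("chromatin features average over the 22-bp site including PAM", {
  cand <- mk_cand("c1", pam = 1021L)
  cand$site_start <- 1000L; cand$site_end <- 1022L
  flat <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 5000), score = 2)
  cf <- chromatin_features(cand, list(flat = flat))
  expect_equal(cf$chromatin_flat, 2)
  # signal only over the 3 PAM bases still contributes (PAM included)
  pam_only <- GenomicRanges::GRanges("chrT",
                                     IRanges::IRanges(1020, 1022), score = 1)
  cf2 <- chromatin_features(cand, list(p = pam_only))
  expect_equal(cf2$chromatin_p, 3 / 22)
  # contig absent from track -> missing, not zero
  other <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 100), score = 1)
  expect_true(is.na(chromatin_features(cand, list(o = other))$chromatin_o))
})

test_that("feature rosters are identical across candidates and hashed", {
  fz <- toy_featurized()
  expect_true(!is.null(attr(fz$features, "roster_hash")))
  ref <- toy_ref(); ann <- toy_annotation()
  fm1 <- build_feature_matrix(enumerate_candidates(ref$genome, ann[1, ], "CRISPRi")[1:3, ],
                              ref$genome, ann[1, ], tracks = ref$tracks)
  expect_identical(attr(fm1, "roster_hash"), attr(fz$features, "roster_hash"))
  expect_identical(names(fm1), names(fz$features))
})
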