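test_that("empirical sgRNAs with score >= 0.75 are included first", {
  cands <- mk_pool(12)
  units <- mk_units()
  pred <- stats::setNames(seq(0.9, 0.3, length.out = 12), cands$id)
  tiers <- tiers_for(cands)
  # the lowest-predicted candidate has strong empirical evidence
  emp <- data.frame(id = cands$id[12], activity = 0.8)
  lib <- select_sgrnas(cands, pred, tiers, units, empirical = emp,
                       max_guides = 10L)
  expect_equal(lib$id[lib$selection_rank == 1], cands$id[12])
  expect_equal(lib$source[lib$selection_rank == 1], "empirical")
  # empirical score below 0.75 gets no priority
  emp2 <- data.frame(id = cands$id[12], activity = 0.6)
  lib2 <- select_sgrnas(cands, pred, tiers, units, empirical = emp2)
  expect_equal(lib2$source[lib2$selection_rank == 1], "predicted")
})

test_that("a third qualifying empirical sgRNA gets +0.2 instead of a slot", {
  cands <- mk_pool(12)
  units <- mk_units()
  pred <- stats::setNames(rep(0.5, 12), cands$id)
  pred[cands$id[4]] <- 0.45   # empirical #3: would rank below the others
  tiers <- tiers_for(cands)
  emp <- data.frame(id = cands$id[c(1, 2, 4)], activity = c(0.9, 0.85, 0.8))
  lib <- select_sgrnas(cands, pred, tiers, units, empirical = emp)
  expect_equal(lib$id[lib$selection_rank %in% 1:2], cands$id[1:2])
  expect_equal(sum(lib$source == "empirical"), 2L)
  # candidate 4 carries 0.45 + 0.2 = 0.65 and outranks the 0.5 pool
  expect_equal(lib$id[lib$selection_rank == 3], cands$id[4])
  expect_equal(lib$predicted[lib$selection_rank == 3], 0.65)
})

test_that("empirical sgRNAs beyond 5 kb of the TSS are not auto-included", {
  cands <- mk_pool(11)
  far <- mk_cand("G1_P1_far", pam = 7000L,
                 proto = cands$protospacer_genomic[1])
  far$id <- "G1_P1_far"
  far$protospacer_genomic <- substr(paste0("ATATA",
                                           cands$protospacer_genomic[1]), 1, 19)
  far$expression_seq <- paste0("G", far$protospacer_genomic)
  cands <- rbind(cands, far)
  units <- mk_units()  # unit at [900, 1100); pam 7000 is ~5.9 kb away
  pred <- stats::setNames(rep(0.5, nrow(cands)), cands$id)
  emp <- data.frame(id = "G1_P1_far", activity = 0.95)
  lib <- select_sgrnas(cands, pred, tiers_for(cands), units, empirical = emp)
  expect_false("empirical" %in% lib$source)
})

test_that("target sites shifted < 3 bp are excluded", {
  cands <- mk_pool(11, spacing = 50L)
  # candidate 11 sits 2 bp from candidate 1 on the same strand
  cands$pam_3g_coord[11] <- cands$pam_3g_coord[1] + 2L
  units <- mk_units()
  pred <- stats::setNames(c(1, seq(0.8, 0.4, length.out = 9), 0.9), cands$id)
  lib <- select_sgrnas(cands, pred, tiers_for(cands), units, max_guides = 5L)
  expect_false(cands$id[11] %in% lib$id)   # blocked by the 2-bp shift
  # an opposite-strand site at the same coordinate is never blocked
  cands$strand[11] <- "-"
  lib2 <- select_sgrnas(cands, pred, tiers_for(cands), units, max_guides = 5L)
  expect_true(cands$id[11] %in% lib2$id)
})

test_that("tier relaxation fills remaining slots in order", {
  cands <- mk_pool(14)
  units <- mk_units()
  pred <- stats::setNames(seq(0.95, 0.3, length.out = 14), cands$id)
  tiers <- tiers_for(cands)
  tiers$tier <- c(rep("T0", 8), "T1", "T1", "T2", "FAIL", "FAIL", "FAIL")
  lib <- select_sgrnas(cands, pred, tiers, units)
  expect_equal(nrow(lib), 10L)
  expect_equal(sum(lib$tier == "T0"), 8L)
  expect_equal(sum(lib$tier == "T1"), 2L)
  # the T2 candidate was not needed
  expect_false(any(lib$tier == "T2"))
  # all T0 entries rank above the relaxed-tier entries
  expect_true(max(lib$selection_rank[lib$tier == "T0"]) <
                min(lib$selection_rank[lib$tier == "T1"]))

  # if even T4 cannot reach 10, the TSS goes untargeted
  tiers$tier <- c(rep("T0", 8), rep("FAIL", 6))
  lib2 <- select_sgrnas(cands, pred, tiers, units)
  expect_equal(nrow(lib2), 0L)
  expect_equal(attr(lib2, "untargeted"), "G1_P1")
})

test_that("selection is deterministic with documented tie-breaking", {
  cands <- mk_pool(12)
  units <- mk_units()
  pred <- stats::setNames(rep(0.5, 12), cands$id)  # all tied
  lib1 <- select_sgrnas(cands, pred, tiers_for(cands), units)
  lib2 <- select_sgrnas(cands, pred, tiers_for(cands), units)
  expect_identical(lib1, lib2)
  # ties resolve by ascending genomic coordinate
  expect_equal(lib1$pam_3g_coord, sort(lib1$pam_3g_coord))
})

test_that("forbidden restriction sites are detected, arms excepted", {
  clean <- "GACGTACGTACGTACGTACG"
  expect_false(has_forbidden_site(clean))
  # SbfI inside the insert
  expect_true(has_forbidden_site(paste0("G", "CCTGCAGG", "ACGTACGTACG")))
  # SbfI formed across the insert / BlpI-arm junction: insert ends CCTGCAG
  # and the arm contributes the final G
  junction <- paste0("G", "ACGTACGTACGT", "CCTGCAG")
  expect_equal(nchar(junction), 20L)
  expect_true(has_forbidden_site(junction))
  # BstXI formed away from the intended arm position
  expect_true(has_forbidden_site(paste0("G", "CCATTTTTTTGG", "ACGTACG")))
  # intended arm sites alone do not trip the filter, with or without
  # adapters
  expect_false(has_forbidden_site(clean, strrep("AT", 9), strrep("TA", 9)))
})

test_that("oligo format is the 84-bp template", {
  insert <- "GACGTACGTACGTACGTACG"
  a5 <- "ATCGATCGATCGATCGAT"; a3 <- "TTAACCGGTTAACCGGTT"
  ol <- format_oligo(insert, a5, a3)
  expect_equal(nchar(ol$oligo), 84L)
  expect_equal(ol$bstxi_arm, "CCACCTTGTTG")
  expect_equal(ol$blpi_arm, "GTTTAAGAGCTAAGCTG")
  # characters between the arms recover the expression sequence
  expect_equal(substr(ol$oligo, 30, 49), insert)
  # the insert begins with G at template position 30 (1-based)
  expect_equal(substr(ol$oligo, 30, 30), "G")
  expect_error(format_oligo(insert, "SHORT", a3), "18 nt")
  expect_error(format_oligo(substr(insert, 1, 19), a5, a3), "20 nt")
})

test_that("negative controls mirror base composition and avoid the genome", {
  ref <- toy_ref()
  ann <- toy_annotation()
  prox <- proximal_reference(ann, ref$transcripts)
  idx <- genome_site_index(ref$genome)
  lib <- guidescreen:::with_seed(31, data.frame(
    protospacer_genomic = vapply(1:60, function(i) random_dna(19),
                                 character(1)), stringsAsFactors = FALSE))
  nc <- generate_negative_controls(lib, 400, proximal = prox, seed = 33,
                                   index = idx)
  expect_length(nc, 400)
  # per-position sampled frequencies within 5% (abs) of the library profile
  prof_lib <- oracle_base_profile(lib$protospacer_genomic)
  prof_nc <- oracle_base_profile(nc)
  expect_lt(max(abs(prof_lib - prof_nc)), 0.10)
  # every control has zero proximal (<31) and zero genomic (<21) alignments
  for (s in nc[1:10]) {
    sites <- enumerate_offtargets(s, score_cap = 31, index = idx)
    ct <- guidescreen:::offtarget_counts(sites, prox)
    expect_equal(unname(ct), c(0L, 0L))
  }
  # fixed seed reproduces the list exactly
  nc2 <- generate_negative_controls(lib, 25, proximal = prox, seed = 33,
                                    index = idx)
  expect_identical(nc2, nc[1:25])
  # a library whose profile forces perfect genomic matches aborts
  hit <- idx$sites$protospacer[1]
  lib_bad <- data.frame(protospacer_genomic = rep(hit, 10))
  expect_error(generate_negative_controls(lib_bad, 5, proximal = prox,
                                          seed = 34, index = idx,
                                          max_draws_per_control = 20L),
               "rejection rate")
})

test_that("sublibrary partition is a function of rank and the gene map", {
  cands <- mk_pool(12)
  units <- mk_units()
  pred <- stats::setNames(seq(0.9, 0.3, length.out = 12), cands$id)
  lib <- select_sgrnas(cands, pred, tiers_for(cands), units)
  expect_equal(lib$half[lib$selection_rank == 3], "top5")
  expect_equal(lib$half[lib$selection_rank == 7], "second5")
  part <- partition_sublibraries(lib, c(G1 = "kinases"))
  expect_true(all(part$group == "kinases"))
  expect_true(all(part$sublibrary %in% c("kinases_top5", "kinases_second5")))
  expect_equal(sum(table(part$sublibrary)), nrow(lib))
  expect_warning(partition_sublibraries(lib, c(OTHER = "x")), "unassigned")
  part2 <- partition_sublibraries(lib, c(G1 = "kinases"))
  expect_identical(part, part2)
})
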