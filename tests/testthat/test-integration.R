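# helpers to assemble per-patient profiles from raw pieces
profile_of <- function(calls, snvs, subtype = "ETV6_RUNX1",
                       copy_states = NULL) {
  cs <- stats::setNames(rep(2L, 23), setdiff(CONTIGS$chrom, "chrY"))
  if (!is.null(copy_states)) cs[names(copy_states)] <- copy_states
  list(patient_id = "P1", subtype = subtype, calls = calls, snvs = snvs,
       copy_states = cs)
}

empty_snvs <- data.frame(variant_id = character(), sample_id = character(),
                         chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         gene = character(), effect = character(),
                         vaf = numeric())

snv_in <- function(sym, id = "v1", effect = "missense", patient = "P1") {
  g <- GENES$genes[GENES$genes$symbol == sym, ]
  data.frame(variant_id = id, sample_id = paste0(patient, "_T"),
             chrom = g$chrom, pos = floor((g$start + g$end) / 2),
             ref = "A", alt = "T", gene = sym, effect = effect, vaf = 0.4)
}

del_in <- function(sym, id = "d1", pad = 0, vaf = NA, patient = "P1") {
  g <- GENES$genes[GENES$genes$symbol == sym, ]
  del_call(id, g$start - pad, g$end + pad, chrom = g$chrom,
           sample = paste0(patient, "_T"), vaf = vaf)
}

test_that("double hits require SV and SNV in the same gene and patient", {
  stag2_del <- del_in("STAG2", "sv_stag2")
  stag2_snv <- snv_in("STAG2", "v_stag2")
  profiles <- list(P1 = profile_of(stag2_del, stag2_snv))
  hits <- detect_double_hits(profiles, GENES)
  expect_equal(hits$gene, "STAG2")
  expect_equal(hits$sv_evidence, "sv_stag2")
  expect_equal(hits$snv_evidence, "v_stag2")
  # SV alone is not a double hit
  expect_equal(nrow(detect_double_hits(
    list(P1 = profile_of(del_in("ETV6"), empty_snvs)), GENES)), 0)
  # SV and SNV in different patients do not combine
  profiles2 <- list(P1 = profile_of(del_in("ETV6"), empty_snvs),
                    P2 = modifyList(profile_of(del_in("ETV6")[0, ],
                                               snv_in("ETV6", patient = "P2")),
                                    list(patient_id = "P2")))
  expect_equal(nrow(detect_double_hits(profiles2, GENES)), 0)
})

test_that("double hits equal the intersection of SV-hit and SNV-hit patient sets", {
  co <- cohort30()
  profiles <- build_patient_profiles(co$cs$somatic, co$sim$truth$snvs,
                                     co$sim$samples, CONTIGS)
  hits <- detect_double_hits(profiles, GENES)
  # independent recomputation per gene from the raw tables
  g <- GENES$genes
  for (sym in unique(hits$gene)) {
    gi <- g[g$symbol == sym, ]
    sv_pat <- unique(vapply(profiles, function(pr) {
      ok <- !pr$calls$sv_type %in% c("aneuploidy_gain", "aneuploidy_loss",
                                     "cnn_loh")
      if (length(leukosv:::sv_hits_region(
        pr$calls[ok, , drop = FALSE], gi$chrom,
        min(gi$start, gi$promoter_start),
        max(gi$end, gi$promoter_end)))) pr$patient_id else NA_character_
    }, character(1)))
    snv_pat <- unique(vapply(profiles, function(pr)
      if (any(pr$snvs$chrom == gi$chrom & pr$snvs$pos >= gi$start &
              pr$snvs$pos < gi$end)) pr$patient_id else NA_character_,
      character(1)))
    want <- sort(intersect(sv_pat[!is.na(sv_pat)], snv_pat[!is.na(snv_pat)]))
    expect_equal(sort(hits$patient_id[hits$gene == sym]), want)
  }
})

test_that("IKZF1plus truth table over all criterion combinations", {
  for (ik in c(FALSE, TRUE)) for (co in c(FALSE, TRUE))
    for (erg in c(FALSE, TRUE)) {
      calls <- del_call("dummy", 1, 2)[0, ]
      if (ik) calls <- rbind(calls, del_in("IKZF1", "ik"))
      if (co) calls <- rbind(calls, del_in("PAX5", "px"))
      if (erg) calls <- rbind(calls, del_in("ERG", "er"))
      res <- evaluate_ikzf1_plus(profile_of(calls, empty_snvs), GENES)
      expect_identical(res$status, ik && co && !erg,
                       info = sprintf("ik=%s co=%s erg=%s", ik, co, erg))
    }
})

test_that("IKZF1plus co-deletion may come from CDKN2A/B, PAX5 or PAR1", {
  for (co_gene in c("CDKN2A", "CDKN2B", "PAX5")) {
    calls <- rbind(del_in("IKZF1", "ik"), del_in(co_gene, "co"))
    expect_true(evaluate_ikzf1_plus(profile_of(calls, empty_snvs),
                                    GENES)$status)
  }
  par1 <- par1_region()
  calls <- rbind(del_in("IKZF1", "ik"),
                 del_call("par", par1$start + 1000, par1$start + 90000,
                          chrom = "chrX", sample = "P1_T"))
  expect_true(evaluate_ikzf1_plus(profile_of(calls, empty_snvs),
                                  GENES)$status)
  # a missing required gene model is an error
  slim <- GENES
  slim$genes <- slim$genes[slim$genes$symbol != "ERG", ]
  expect_error(evaluate_ikzf1_plus(profile_of(del_in("IKZF1"), empty_snvs),
                                   slim), "ERG")
})

test_that("the two reported IKZF1 cases behave as described", {
  # exon-level IKZF1 deletion plus PAX5 deletion, no ERG deletion: fulfilled
  all13 <- rbind(
    del_call("ik13", 50306321, 50348483, chrom = "chr7", sample = "P1_T",
             vaf = 0.45),
    del_call("px13", 36841198, 36916988, chrom = "chr9", sample = "P1_T",
             vaf = 0.44))
  r13 <- evaluate_ikzf1_plus(profile_of(all13, empty_snvs), GENES)
  expect_true(r13$status)
  expect_false(r13$subclonal)
  expect_equal(r13$rationale$IKZF1, "ik13")
  expect_equal(r13$rationale$PAX5, "px13")
  # subclonal IKZF1 deletion alone: not fulfilled, subclonal flag set
  all55 <- del_call("ik55", 50306321, 50399656, chrom = "chr7",
                    sample = "P1_T", vaf = 0.06)
  r55 <- evaluate_ikzf1_plus(profile_of(all55, empty_snvs), GENES)
  expect_false(r55$status)
  expect_true(r55$subclonal)
})

test_that("hyperdiploid risk rule matches its truth table on a CN grid", {
  rule <- function(cn5, cn17, cn18, cn20) {
    t17 <- cn17 >= 3; t18 <- cn18 >= 3
    (!t17 && !t18) || ((t17 || t18) && (cn5 >= 3 || cn20 >= 3))
  }
  for (cn5 in 2:4) for (cn17 in 2:4) for (cn18 in 2:4) for (cn20 in 2:4) {
    pr <- profile_of(del_call("x", 1, 2)[0, ], empty_snvs, subtype = "HD",
                     copy_states = c(chr5 = cn5, chr17 = cn17,
                                     chr18 = cn18, chr20 = cn20))
    expect_identical(classify_hd_risk(pr),
                     if (rule(cn5, cn17, cn18, cn20)) "poor" else "not_poor",
                     info = paste(cn5, cn17, cn18, cn20))
  }
  # the three anchor profiles
  pr <- function(...) profile_of(del_call("x", 1, 2)[0, ], empty_snvs,
                                 subtype = "HD", copy_states = c(...))
  expect_equal(classify_hd_risk(pr(chr17 = 2L, chr18 = 2L)), "poor")
  expect_equal(classify_hd_risk(pr(chr17 = 3L, chr5 = 3L)), "poor")
  expect_equal(classify_hd_risk(pr(chr17 = 3L, chr18 = 2L, chr5 = 2L,
                                   chr20 = 2L)), "not_poor")
  # non-HD profiles are out of scope for the rule
  expect_equal(classify_hd_risk(profile_of(del_call("x", 1, 2)[0, ],
                                           empty_snvs)), "not_applicable")
  # exclusive-or reading flips the both-trisomic case
  both <- pr(chr17 = 3L, chr18 = 3L, chr5 = 3L)
  expect_equal(classify_hd_risk(both), "poor")
  expect_equal(classify_hd_risk(both,
                                pipeline_config(hd_trisomy_exclusive = TRUE)),
               "not_poor")
})

test_that("copy states derive from whole-chromosome calls", {
  len21 <- CONTIGS$length[CONTIGS$chrom == "chr21"]
  calls <- del_call("g21", 0, len21, chrom = "chr21",
                    sv_type = "aneuploidy_gain", sample = "P1_T")
  calls$cn <- 4L
  sm <- mini_samples("P1", "HD")
  profiles <- build_patient_profiles(calls, empty_snvs, sm, CONTIGS)
  expect_equal(profiles$P1$copy_states[["chr21"]], 4L)
  expect_equal(profiles$P1$copy_states[["chr1"]], 2L)
})

test_that("fusion prediction pairs genes across breakends with orientation", {
  g <- GENES$genes
  pds5b <- g[g$symbol == "PDS5B", ]   # chr13, + strand
  stag2 <- g[g$symbol == "STAG2", ]   # chrX, + strand
  # retain 5' of PDS5B (left side, + strand) and 3' of STAG2 (right side)
  tra <- tra_call("t1", "chr13", pds5b$start + 5000, "chrX",
                  stag2$start + 20000, orient1 = "left", orient2 = "right")
  f <- predict_fusions(tra, GENES)
  expect_equal(nrow(f), 1)
  expect_equal(f$gene5, "PDS5B")
  expect_equal(f$gene3, "STAG2")
  expect_true(f$orientation_compatible)
  expect_equal(f$confidence, "putative")
  # swapped breakend order recovers the same fusion (role swap)
  tra_sw <- tra_call("t2", "chrX", stag2$start + 20000, "chr13",
                     pds5b$start + 5000, orient1 = "right", orient2 = "left")
  f2 <- predict_fusions(tra_sw, GENES)
  expect_equal(f2$gene5, "PDS5B")
  expect_equal(f2$gene3, "STAG2")
  expect_true(f2$orientation_compatible)
  # SFMBT2 (- strand) to DGKD (+ strand)
  sf <- g[g$symbol == "SFMBT2", ]; dg <- g[g$symbol == "DGKD", ]
  tra3 <- tra_call("t3", "chr10", sf$end - 5000, "chr2", dg$start + 30000,
                   orient1 = "right", orient2 = "right")
  f3 <- predict_fusions(tra3, GENES)
  expect_equal(f3$gene5, "SFMBT2")
  expect_equal(f3$gene3, "DGKD")
  expect_true(f3$orientation_compatible)
  # incompatible orientations are reported but flagged
  tra4 <- tra_call("t4", "chr13", pds5b$start + 5000, "chrX",
                   stag2$start + 20000, orient1 = "right", orient2 = "right")
  f4 <- predict_fusions(tra4, GENES)
  expect_false(f4$orientation_compatible)
  # a breakend in a gene desert yields no candidates
  tra5 <- tra_call("t5", "chr13", pds5b$start + 5000, "chr6", 20e6)
  expect_equal(nrow(predict_fusions(tra5, GENES)), 0)
  # unknown orientation: candidate kept with NA compatibility
  tra6 <- tra_call("t6", "chr13", pds5b$start + 5000, "chrX",
                   stag2$start + 20000, orient1 = "unknown",
                   orient2 = "unknown")
  expect_true(is.na(predict_fusions(tra6, GENES)$orientation_compatible))
})
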