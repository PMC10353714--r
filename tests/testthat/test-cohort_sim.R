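test_that("simulation is reproducible and rejects degenerate sizes", {
  s1 <- simulate_cohort(n_per_subtype = 1, seed = 99)
  s2 <- simulate_cohort(n_per_subtype = 1, seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$calls, s2$calls)
  s3 <- simulate_cohort(n_per_subtype = 1, seed = 100)
  expect_false(identical(s1$truth$events, s3$truth$events))
  expect_error(simulate_cohort(n_per_subtype = 0, seed = 1), "n_per_subtype")
})

test_that("germline truth is shared and somatic truth is tumor-only", {
  sim <- simulate_cohort(n_per_subtype = 2, seed = 7)
  ev <- sim$truth$events
  expect_true(all(ev$origin %in% c("germline", "somatic")))
  # every hallmark translocation is present in every ETV6::RUNX1 tumor
  e_pat <- sim$samples$patient_id[sim$samples$subtype == "ETV6_RUNX1" &
                                    sim$samples$role == "tumor"]
  hall <- ev[ev$hallmark & ev$sv_type == "inter_translocation", ]
  expect_true(all(e_pat %in% hall$patient_id))
  t1221 <- hall[hall$chrom1 == "chr12" & hall$chrom2 == "chr21", ]
  expect_setequal(t1221$patient_id, e_pat)
})

test_that("germline events are jointly emitted or jointly dropped", {
  sim <- simulate_cohort(n_per_subtype = 2, seed = 7)
  for (pid in names(sim$calls)) {
    sc <- sim$calls[[pid]]
    germ <- sim$truth$events$event_id[
      sim$truth$events$patient_id == pid &
        sim$truth$events$origin == "germline"]
    for (m in c("DN", "RVP")) {
      in_t <- germ %in% sub("_(DN|RVP)$", "", sc[[paste0(m, "_T")]]$call_id)
      in_n <- germ %in% sub("_(DN|RVP)$", "", sc[[paste0(m, "_N")]]$call_id)
      expect_identical(in_t, in_n)
    }
  }
})

test_that("caller sensitivity is non-decreasing in VAF and size", {
  models <- default_caller_models()
  vafs <- seq(0, 0.6, by = 0.02)
  sizes <- c(100, 400, 500, 1000, 5e4, 5e5, 5e6, 5e7)
  for (m in models) {
    for (sz in sizes) {
      s <- vapply(vafs, function(v)
        leukosv:::caller_sensitivity(m, v, sz), numeric(1))
      expect_true(all(diff(s) >= -1e-12))
    }
    for (v in c(0.06, 0.2, 0.5)) {
      s <- vapply(sizes, function(sz)
        leukosv:::caller_sensitivity(m, v, sz), numeric(1))
      expect_true(all(diff(s) >= -1e-12))
    }
  }
})

test_that("platform emulation: detection limits, DN floor, blind regions", {
  annot <- ANNOT
  models <- default_caller_models()
  mk_ev <- function(id, sv_type, chrom, pos1, pos2, vaf, size = NA) {
    e <- leukosv:::truth_event(id, "P1", "somatic", sv_type, chrom, pos1,
                               chrom2 = if (sv_type == "inter_translocation")
                                 "chr2" else chrom,
                               pos2 = pos2, vaf = vaf)
    if (!is.na(size)) e$size_bp <- size
    e
  }
  # a 40 kb clonal deletion: below the 50 kb array limit, seen by OGM
  ev <- mk_ev("e40k", "deletion", "chr1", 10e6, 10e6 + 40000, 0.5)
  arr <- emulate_caller(ev, models$CytoSNP12, 1, "P1_T", "tumor", annot)
  ogm <- emulate_caller(ev, models$RVP, 1, "P1_T", "tumor", annot)
  expect_equal(arr$log$reason, "below_min_size")
  expect_true(ogm$log$emitted)
  # VAF 0.06 is under the DN de novo assembly floor but RVP retains it
  sub <- mk_ev("esub", "deletion", "chr1", 10e6, 10.2e6, 0.06)
  dn <- emulate_caller(sub, models$DN, 1, "P1_T", "tumor", annot)
  expect_equal(dn$log$reason, "below_vaf_floor")
  expect_gt(leukosv:::caller_sensitivity(models$RVP, 0.06, 2e5), 0)
  # a centromere-spanning translocation is invisible to OGM
  cen1 <- annot$blacklist[annot$blacklist$name == "chr1_cen", ]
  tra <- mk_ev("ecen", "inter_translocation", "chr1",
               floor((cen1$start + cen1$end) / 2), 30e6, 0.5)
  out <- emulate_caller(tra, models$DN, 1, "P1_T", "tumor", annot)
  expect_equal(out$log$reason, "blind_region")
})

test_that("focal-deletion burden medians land in the configured windows", {
  co <- cohort30()
  ev <- co$sim$truth$events
  del <- ev[ev$origin == "somatic" & ev$sv_type == "deletion" &
              ev$size_bp < 5e6, ]
  per_case <- table(factor(del$patient_id,
                           levels = unique(co$sim$samples$patient_id)))
  sub <- co$sim$samples$subtype[match(names(per_case),
                                      co$sim$samples$patient_id)]
  med_e <- median(per_case[sub == "ETV6_RUNX1"])
  med_h <- median(per_case[sub == "HD"])
  expect_gte(med_e, 10); expect_lte(med_e, 17)
  expect_gte(med_h, 2); expect_lte(med_h, 6)
})

test_that("emitted call files round-trip through the dialect readers", {
  out <- withr::local_tempdir()
  sim <- simulate_cohort(n_per_subtype = 1, seed = 5, out_dir = out)
  pid <- sim$samples$patient_id[1]
  dn <- read_sv_table(file.path(out, paste0(pid, ".dn_t.sv.tsv")),
                      contigs = CONTIGS)
  expect_identical(dn, {
    x <- sim$calls[[pid]]$DN_T
    rownames(x) <- NULL
    x
  })
  seg <- read_cn_segments(file.path(out, paste0(pid, ".array_t.seg.tsv")),
                          sim$array_of[1], CONTIGS)
  orig <- sim$calls[[pid]]$ARRAY_T
  rownames(orig) <- rownames(seg) <- NULL
  expect_identical(seg[, c("chrom", "start", "end", "state", "n_probes")],
                   orig[, c("chrom", "start", "end", "state", "n_probes")])
  snv <- read_small_variants(file.path(out, "cohort.vcf"), sim$samples)
  expect_equal(nrow(snv), nrow(sim$truth$snvs))
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt))
  expect_identical(key(snv), key(sim$truth$snvs))
})
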