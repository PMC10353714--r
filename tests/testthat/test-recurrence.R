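samples3 <- mini_samples(c("P1", "P2", "P3", "P4"))

test_that("MAR is the intersection of supporting spans from >= 3 patients", {
  calls <- rbind(del_call("c1", 100, 200, sample = "P1_T"),
                 del_call("c2", 150, 250, sample = "P2_T"),
                 del_call("c3", 180, 300, sample = "P3_T"))
  mars <- compute_mars(calls, samples3)
  expect_equal(nrow(mars), 1)
  expect_equal(mars$start, 180)
  expect_equal(mars$end, 200)
  expect_equal(mars$n_cases, 3)
  # same spans in only two patients: below the recurrence floor
  two <- calls[1:2, ]
  expect_equal(nrow(compute_mars(two, samples3)), 0)
  # multiple calls from one patient count once
  dup <- rbind(calls[1:2, ], del_call("c4", 160, 240, sample = "P2_T"))
  expect_equal(nrow(compute_mars(dup, samples3)), 0)
})

test_that("empty full intersection splits into maximal sub-clusters", {
  # chain [0,10), [5,20), [15,30): maximal subsets {1,2} and {2,3}
  calls <- rbind(del_call("c1", 1000, 11000, sample = "P1_T"),
                 del_call("c2", 6000, 21000, sample = "P2_T"),
                 del_call("c3", 16000, 31000, sample = "P3_T"),
                 del_call("c4", 6500, 20000, sample = "P4_T"))
  cfg <- pipeline_config(recurrence_min_cases = 2)
  mars <- compute_mars(calls, samples3, cfg)
  expect_equal(nrow(mars), 2)
  expect_equal(mars$start, c(6500, 16000))
  expect_equal(mars$end, c(11000, 20000))
})

test_that("MAR detection equals the exhaustive subset-enumeration oracle", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    starts <- floor(runif(n, 0, 5e4))
    ends <- starts + floor(runif(n, 5e3, 4e4))
    pts <- sprintf("P%d", sample(1:5, n, replace = TRUE))
    calls <- sv_calls(call_id = sprintf("c%d", 1:n),
                      sample_id = paste0(pts, "_T"), sv_type = "deletion",
                      chrom1 = "chr1", pos1 = starts, pos2 = ends,
                      callers = "DN")
    sm <- mini_samples(sprintf("P%d", 1:5))
    mars <- compute_mars(calls, sm)
    want <- bf_mars(starts, ends, pts, 3L)
    expect_equal(nrow(mars), nrow(want))
    if (nrow(want)) {
      expect_equal(mars$start, want$start)
      expect_equal(mars$end, want$end)
    }
  }
})

test_that("MAR invariants: containment, monotonicity, permutation stability", {
  set.seed(9)
  n <- 30
  starts <- floor(runif(n, 0, 2e5))
  ends <- starts + floor(runif(n, 1e4, 1e5))
  pts <- sprintf("P%d", sample(1:8, n, replace = TRUE))
  calls <- sv_calls(call_id = sprintf("c%d", 1:n),
                    sample_id = paste0(pts, "_T"), sv_type = "deletion",
                    chrom1 = "chr1", pos1 = starts, pos2 = ends,
                    callers = "DN")
  sm <- mini_samples(sprintf("P%d", 1:8))
  mars <- compute_mars(calls, sm)
  sup <- attr(mars, "supporting")
  # every MAR region is contained in every supporting call's span
  for (k in seq_len(nrow(mars))) {
    ids <- sup$call_id[sup$mar_id == mars$mar_id[k]]
    m <- calls[calls$call_id %in% ids, ]
    expect_true(all(m$pos1 <= mars$start[k] & m$pos2 >= mars$end[k]))
  }
  # raising the recurrence floor never increases the MAR count
  counts <- vapply(2:6, function(k)
    nrow(compute_mars(calls, sm, pipeline_config(recurrence_min_cases = k))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  # permuting patient input order leaves the result invariant
  perm <- compute_mars(calls[sample(n), ], sm)
  expect_equal(perm$start, mars$start)
  expect_equal(perm$patients, mars$patients)
})

test_that("insertions participate via a padded point span", {
  ins <- function(id, pos, sample) {
    x <- del_call(id, pos, pos + 1, sample = sample, sv_type = "insertion")
    x$size_bp <- 1500
    x
  }
  calls <- rbind(ins("i1", 5000, "P1_T"), ins("i2", 5000, "P2_T"),
                 del_call("d3", 4000, 6000, sample = "P3_T"))
  mars <- compute_mars(calls, samples3)
  expect_equal(nrow(mars), 1)
  expect_equal(mars$n_cases, 3)
  expect_equal(mars$sv_types, "deletion,insertion")
})

test_that("target assignment: gene body, promoter, nearest, distal", {
  g <- GENES$genes
  cdkn2a <- g[g$symbol == "CDKN2A", ]
  mk_mar <- function(chrom, s, e)
    structure(data.frame(mar_id = "M1", chrom = chrom, start = s, end = e,
                         n_cases = 3L, patients = "P1,P2,P3",
                         sv_types = "deletion"),
              class = c("leukosv_mars", "data.frame"))
  # inside the gene body
  m <- assign_targets(mk_mar("chr9", cdkn2a$start + 100, cdkn2a$end - 100),
                      GENES)
  expect_match(m$target_genes, "CDKN2A")
  # 6 kb upstream of a + strand gene: intergenic with signed distance -6 kb
  cd55 <- g[g$symbol == "CD55", ]
  m2 <- assign_targets(mk_mar("chr1", cd55$start - 8000, cd55$start - 6000),
                       GENES)
  expect_true(is.na(m2$target_genes))
  expect_equal(m2$nearest_gene, "CD55")
  expect_equal(m2$nearest_distance, -6000)
  expect_equal(m2$intergenic, "intergenic_proximal")
  # beyond the 20 kb window: distal
  m3 <- assign_targets(mk_mar("chr1", cd55$start - 72000, cd55$start - 70000),
                       GENES)
  expect_equal(m3$intergenic, "intergenic_distal")
})

test_that("subtype specificity labels follow the supporting cases", {
  sm <- mini_samples(c("E1", "E2", "E3", "H1"),
                     c("ETV6_RUNX1", "ETV6_RUNX1", "ETV6_RUNX1", "HD"))
  mars <- data.frame(mar_id = c("M1", "M2"), chrom = "chr1",
                     start = c(1, 100), end = c(50, 200),
                     n_cases = 3L, patients = c("E1,E2,E3", "E1,E2,H1"),
                     sv_types = "deletion")
  out <- subtype_specificity(mars, sm)
  expect_equal(out$specificity, c("ETV6_RUNX1_specific", "common"))
})
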