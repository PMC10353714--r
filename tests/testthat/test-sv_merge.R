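test_that("matching predicate: overlap, identity, distance, symmetry", {
  p <- match_params()
  a <- del_call("a", 100000, 200000)
  b <- del_call("b", 105000, 195000, caller = "ARRAY")  # loss-like, ro = 0.9
  expect_true(match_calls(a, b, p))
  expect_true(match_calls(a, a, p))                     # reflexive
  far <- del_call("c", 10100000, 10101000)
  near <- del_call("d", 100000, 101000)
  expect_false(match_calls(near, far, p))               # 10 Mb apart
  # symmetric in (a, b)
  x <- del_call("x", 50000, 80000)
  y <- del_call("y", 62000, 110000)
  expect_equal(match_calls(x, y, p), match_calls(y, x, p))
  # type classes: deletion never matches duplication
  d <- del_call("e", 100000, 200000, sv_type = "duplication")
  expect_false(match_calls(a, d, p))
  # translocations: both breakends within tolerance, either orientation
  t1 <- tra_call("t1", "chr12", 11800000, "chr21", 34900000)
  t2 <- tra_call("t2", "chr21", 34905000, "chr12", 11792000)
  expect_true(match_calls(t1, t2, p))
  t3 <- tra_call("t3", "chr12", 11800000, "chr21", 36000000)
  expect_false(match_calls(t1, t3, p))
})

test_that("interval-tree candidate generation equals the O(n^2) oracle", {
  set.seed(11)
  p <- match_params()
  for (rep in 1:6) {
    A <- random_call_set(18, caller = "DN")
    B <- random_call_set(18, caller = "RVP")
    got <- leukosv:::match_pairs(A, B, p)
    want <- bf_match_pairs(A, B, p)
    key <- function(d) sort(paste(d$i, d$j))
    expect_identical(key(got), key(want))
  }
})

test_that("dual-pipeline merge collapses matched pairs and keeps the rest", {
  dn <- del_call("d1", 100000, 150000, sample = "S1", caller = "DN")
  rvp <- rbind(del_call("r1", 100800, 149500, sample = "S1", caller = "RVP"),
               del_call("r2", 9e6, 9.2e6, sample = "S1", caller = "RVP"))
  m <- merge_pipelines(dn, rvp, NULL, contigs = CONTIGS)
  expect_equal(nrow(m), 2)
  expect_setequal(m$callers, c("DN,RVP", "RVP"))
  # DN coordinates win on the merged member
  merged <- m[m$callers == "DN,RVP", ]
  expect_equal(merged$pos1, 100000)
  expect_equal(merged$call_id, "d1")
  # mixed samples are rejected
  expect_error(merge_pipelines(dn, del_call("z", 1, 10, sample = "S2",
                                            caller = "RVP"), NULL,
                               contigs = CONTIGS), "single sample")
})

test_that("CN segments join the merge only at >= 5 Mb and when unmatched", {
  dn <- del_call("d1", 100000, 150000, sample = "S1", caller = "DN")
  rvp <- dn[0, ]
  cn <- data.frame(sample_id = "S1", chrom = c("chr2", "chr3"),
                   start = c(10e6, 20e6), end = c(16e6, 22e6),
                   state = "loss", n_probes = 0L, cn = 1L)
  m <- merge_pipelines(dn, rvp, cn, contigs = CONTIGS)
  expect_equal(sum(m$callers == "CN"), 1)               # 6 Mb kept, 2 Mb dropped
  expect_equal(m$chrom1[m$callers == "CN"], "chr2")
  # a CN segment matching an existing call annotates provenance instead
  cn2 <- data.frame(sample_id = "S1", chrom = "chr2", start = 10e6,
                    end = 16e6, state = "loss", n_probes = 0L, cn = 1L)
  dn2 <- del_call("d2", 10.05e6, 15.98e6, chrom = "chr2", sample = "S1")
  m2 <- merge_pipelines(dn2, rvp, cn2, contigs = CONTIGS)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$callers, "DN,CN")
})

test_that("merge is deterministic, order-invariant and bounded in size", {
  set.seed(3)
  dn <- random_call_set(25, caller = "DN")
  rvp <- random_call_set(25, caller = "RVP")
  m1 <- merge_pipelines(dn, rvp, NULL, contigs = CONTIGS)
  m2 <- merge_pipelines(dn[sample(nrow(dn)), ], rvp[sample(nrow(rvp)), ],
                        NULL, contigs = CONTIGS)
  expect_identical(m1, m2)
  expect_lte(nrow(m1), nrow(dn) + nrow(rvp))
  # idempotent: re-merging the merged set with empty inputs is identity
  m3 <- merge_pipelines(m1, m1[0, ], NULL, contigs = CONTIGS)
  expect_identical(m3[, names(m1)], m1)
})

test_that("greedy 1-to-1 matching agrees with optimal matching on >= 99% of instances", {
  # instances drawn from the dual-pipeline noise model the merge faces:
  # the second callset is a jittered replicate of part of the first,
  # plus pipeline-private extras
  set.seed(21)
  p <- match_params()
  agree <- 0L; total <- 120L
  for (r in seq_len(total)) {
    A <- random_call_set(10, span = c(1e6, 9e7), size = c(2e3, 3e5),
                         caller = "DN")
    shared <- A[sample(nrow(A), 7), ]
    jit <- floor(runif(nrow(shared), -5000, 5000))
    p1 <- pmax(0, shared$pos1 + jit)
    p2 <- shared$pos2 + floor(runif(nrow(shared), -5000, 5000))
    B <- sv_calls(call_id = paste0("r", seq_len(nrow(shared))),
                  sample_id = "S1", sv_type = "deletion", chrom1 = "chr1",
                  pos1 = p1, pos2 = pmax(p2, p1 + 200), callers = "RVP")
    B <- rbind(B, random_call_set(3, span = c(1e6, 9e7), size = c(2e3, 3e5),
                                  caller = "RVP"))
    pairs <- leukosv:::match_pairs(A, B, p)
    greedy <- nrow(leukosv:::greedy_assign(pairs, A, B))
    optimal <- bf_max_matching(pairs, nrow(A), nrow(B))
    if (greedy == optimal) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.99)
})

test_that("germline subtraction partitions the tumor callset", {
  g1 <- del_call("g1", 500000, 600000, sample = "T1")
  s1 <- del_call("s1", 5e6, 5.1e6, sample = "T1")
  n1 <- del_call("n1", 500400, 599700, sample = "N1")
  out <- subtract_germline(rbind(g1, s1), n1)
  expect_equal(out$somatic$call_id, "s1")
  expect_equal(out$removed$call_id, "g1")
  # partition law
  expect_setequal(c(out$somatic$call_id, out$removed$call_id), c("g1", "s1"))
  # empty normal removes nothing
  out2 <- subtract_germline(rbind(g1, s1), n1[0, ])
  expect_equal(nrow(out2$somatic), 2)
  # a missing matched normal is an explicit error unless overridden
  expect_error(subtract_germline(rbind(g1, s1), NULL), "allow_unmatched")
  out3 <- subtract_germline(rbind(g1, s1), NULL, allow_unmatched = TRUE)
  expect_equal(nrow(out3$somatic), 2)
})

test_that("filter thresholds are inclusive with exact boundary behavior", {
  cfg <- pipeline_config()
  calls <- rbind(del_call("a_keep", 10e6, 10e6 + 50000, caller = "ARRAY"),
                 del_call("a_small", 10e6, 10e6 + 49999, caller = "ARRAY"),
                 del_call("a_probes", 10e6, 10e6 + 50000, caller = "ARRAY"),
                 del_call("o_keep", 10e6, 10e6 + 500, caller = "DN"),
                 del_call("o_small", 10e6, 10e6 + 499, caller = "DN"),
                 del_call("l_keep", 10e6, 15e6, sv_type = "cnn_loh",
                          caller = "ARRAY"),
                 del_call("l_small", 10e6, 15e6 - 1, sv_type = "cnn_loh",
                          caller = "ARRAY"))
  # boundary probe counts: exactly 20 is kept, 19 is filtered
  calls$n_probes <- c(20L, 25L, 19L, NA, NA, NA, NA)
  out <- apply_filters(calls, cfg, BLACKLIST, CONTIGS)
  expect_setequal(out$kept$call_id, c("a_keep", "o_keep", "l_keep"))
  st <- setNames(out$filtered$filter_status, out$filtered$call_id)
  expect_equal(st[["a_small"]], "filtered:min_size")
  expect_equal(st[["a_probes"]], "filtered:min_probes")
  expect_equal(st[["o_small"]], "filtered:min_size")
  expect_equal(st[["l_small"]], "filtered:cnnloh_min_size")
  # partition law
  expect_equal(nrow(out$kept) + nrow(out$filtered), nrow(calls))
})

test_that("blacklisted focal calls are removed with their region class", {
  igh <- BLACKLIST[BLACKLIST$name == "IGH", ]
  calls <- rbind(
    del_call("in_igh", igh$start + 1000, igh$start + 60000, chrom = "chr14"),
    del_call("clean", 60e6, 60.06e6, chrom = "chr14"),
    tra_call("tra_igh", "chr14", igh$start + 5000, "chr8", 30e6))
  out <- apply_filters(calls, pipeline_config(), BLACKLIST, CONTIGS)
  expect_setequal(out$filtered$call_id, c("in_igh", "tra_igh"))
  expect_true(all(out$filtered$filter_status == "filtered:IG_TR"))
  # translocations bypass size rules but not the blacklist
  expect_equal(out$kept$call_id, "clean")
})

test_that("size classification separates focal, large and whole-chromosome", {
  cfg <- pipeline_config()
  calls <- rbind(
    del_call("f", 10e6, 13.6e6),                         # 3.6 Mb focal
    del_call("l", 1e6, 18e6, chrom = "chr12"),           # 17 Mb large
    del_call("w", 0, CONTIGS$length[CONTIGS$chrom == "chr21"],
             chrom = "chr21", sv_type = "aneuploidy_gain"),
    tra_call("t", "chr1", 1e6, "chr2", 1e6))
  expect_equal(classify_size(calls, cfg, CONTIGS),
               c("focal", "large", "whole_chromosome", "focal"))
  # a >= 95% span is whole-chromosome even without the aneuploidy type
  near_whole <- del_call("nw", 0, round(0.96 * CONTIGS$length[1]),
                         chrom = "chr1")
  expect_equal(classify_size(near_whole, cfg, CONTIGS), "whole_chromosome")
})
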