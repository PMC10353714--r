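# Shared builders and memoized cohort objects for the test suite.

ANNOT <- load_annotation()
CONTIGS <- ANNOT$contigs
GENES <- ANNOT$models
BLACKLIST <- ANNOT$blacklist
CYTOBANDS <- ANNOT$cytobands

# terse SV-call builders
del_call <- function(id, s, e, chrom = "chr1", sample = "S1", caller = "DN",
                     vaf = NA, sv_type = "deletion", ...) {
  sv_calls(call_id = id, sample_id = sample, sv_type = sv_type,
           chrom1 = chrom, pos1 = s, pos2 = e, vaf = vaf, callers = caller,
           ...)
}

tra_call <- function(id, chrom1, pos1, chrom2, pos2, orient1 = "left",
                     orient2 = "left", sample = "S1", caller = "DN") {
  sv_calls(call_id = id, sample_id = sample, sv_type = "inter_translocation",
           chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
           orient1 = orient1, orient2 = orient2, callers = caller)
}

mini_samples <- function(patients, subtypes = NULL) {
  if (is.null(subtypes)) subtypes <- rep("ETV6_RUNX1", length(patients))
  do.call(rbind, lapply(seq_along(patients), function(i)
    data.frame(sample_id = paste0(patients[i], c("_T", "_N")),
               patient_id = patients[i], subtype = subtypes[i],
               role = c("tumor", "normal"), blast_fraction = c(0.8, 0))))
}

# the cohort used by the recovery checks: 30 + 30 patients, fixed seed
.cohort_cache <- new.env(parent = emptyenv())

cohort30 <- function() {
  if (is.null(.cohort_cache$sim)) {
    .cohort_cache$sim <- simulate_cohort(n_per_subtype = 30, seed = 1)
    .cohort_cache$somatic <- cohort_somatic(.cohort_cache$sim)
  }
  list(sim = .cohort_cache$sim, cs = .cohort_cache$somatic)
}
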