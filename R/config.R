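#' Pipeline configuration
#'
#' Holds every numeric threshold the filtering and recurrence stages use.
#' Defaults follow the study design: SNP-array deletions/duplications are
#' kept at >= 20 probes and >= 50 kb, copy-neutral LOH at >= 5 Mb, OGM calls
#' at >= 500 bp, the focal/large boundary sits at 5 Mb, recurrence requires
#' >= 3 cases, and intergenic MARs are linked to genes within 20 kb.
#' All thresholds are inclusive ("at least").
#'
#' @param array_min_probes minimum probe support for array del/dup calls.
#' @param array_min_cnv_bp minimum size (bp) for array del/dup calls.
#' @param cnnloh_min_bp minimum size (bp) for copy-neutral LOH segments.
#' @param ogm_min_sv_bp minimum size (bp) for OGM calls (translocations exempt).
#' @param focal_large_boundary_bp boundary between focal and large SVs.
#' @param whole_chrom_fraction fraction of the contig length at or above
#'   which a large call counts as a whole-chromosome (aneuploidy) event.
#' @param recurrence_min_cases minimum distinct patients supporting a MAR.
#' @param intergenic_proximity_bp window for nearest-gene annotation of
#'   intergenic MARs.
#' @param promoter_bp promoter window upstream of the 5' gene end
#'   (strand-aware).
#' @param fusion_window_bp window around a translocation breakend when
#'   collecting fusion partner genes.
#' @param detection_limits named vector of per-platform minimum detectable
#'   sizes (bp).
#' @param match list of matching tolerances, see [match_params()].
#' @param hd_trisomy_exclusive if `TRUE`, the hyperdiploid risk rule reads
#'   "either trisomy 17 or 18" as exclusive-or.
#' @return A list of class `leukosv_config`.
#' @export
pipeline_config <- function(array_min_probes = 20L,
                            array_min_cnv_bp = 50000L,
                            cnnloh_min_bp = 5000000L,
                            ogm_min_sv_bp = 500L,
                            focal_large_boundary_bp = 5000000L,
                            whole_chrom_fraction = 0.95,
                            recurrence_min_cases = 3L,
                            intergenic_proximity_bp = 20000L,
                            promoter_bp = 2000L,
                            fusion_window_bp = 10000L,
                            detection_limits = c(CytoSNP12 = 50000,
                                                 CytoScanHD = 1000,
                                                 OGM = 500),
                            match = match_params(),
                            hd_trisomy_exclusive = FALSE) {
  cfg <- list(array_min_probes = as.integer(array_min_probes),
              array_min_cnv_bp = as.integer(array_min_cnv_bp),
              cnnloh_min_bp = as.integer(cnnloh_min_bp),
              ogm_min_sv_bp = as.integer(ogm_min_sv_bp),
              focal_large_boundary_bp = as.integer(focal_large_boundary_bp),
              whole_chrom_fraction = whole_chrom_fraction,
              recurrence_min_cases = as.integer(recurrence_min_cases),
              intergenic_proximity_bp = as.integer(intergenic_proximity_bp),
              promoter_bp = as.integer(promoter_bp),
              fusion_window_bp = as.integer(fusion_window_bp),
              detection_limits = detection_limits,
              match = match,
              hd_trisomy_exclusive = isTRUE(hd_trisomy_exclusive))
  thr <- c(cfg$array_min_probes, cfg$array_min_cnv_bp, cfg$cnnloh_min_bp,
           cfg$ogm_min_sv_bp, cfg$focal_large_boundary_bp,
           cfg$recurrence_min_cases, cfg$intergenic_proximity_bp)
  if (any(thr <= 0)) stop("all thresholds must be > 0")
  if (cfg$focal_large_boundary_bp < cfg$array_min_cnv_bp)
    stop("focal/large boundary must be >= array minimum CNV size")
  class(cfg) <- "leukosv_config"
  cfg
}

#' Matching tolerances for the cross-call/cross-platform matching predicate
#'
#' Two calls of compatible type class match when their reciprocal overlap is
#' at least `reciprocal_overlap_min` or both breakpoint distances are within
#' the platform-pair tolerance. Karyotype events match at cytoband
#' resolution (plus/minus one band) and do not use a bp tolerance.
#'
#' @param reciprocal_overlap_min minimum reciprocal overlap fraction.
#' @param tol_ogm_ogm breakpoint tolerance (bp) between two OGM callsets.
#' @param tol_ogm_array breakpoint tolerance (bp) between OGM and array.
#' @param karyotype_band_slop number of neighboring cytobands allowed when
#'   matching band-resolution events.
#' @return A list of class `leukosv_match_params`.
#' @export
match_params <- function(reciprocal_overlap_min = 0.5,
                         tol_ogm_ogm = 20000L,
                         tol_ogm_array = 50000L,
                         karyotype_band_slop = 1L) {
  if (reciprocal_overlap_min <= 0 || reciprocal_overlap_min > 1)
    stop("reciprocal_overlap_min must be in (0, 1]")
  if (tol_ogm_ogm <= 0 || tol_ogm_array <= 0)
    stop("tolerances must be > 0")
  structure(list(reciprocal_overlap_min = reciprocal_overlap_min,
                 tol_ogm_ogm = as.integer(tol_ogm_ogm),
                 tol_ogm_array = as.integer(tol_ogm_array),
                 karyotype_band_slop = as.integer(karyotype_band_slop)),
            class = "leukosv_match_params")
}

# platform family of a call from its caller provenance
caller_platform <- function(callers) {
  fam <- function(s) {
    cs <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (any(cs %in% c("DN", "RVP", "CN"))) "OGM"
    else if ("ARRAY" %in% cs) "ARRAY"
    else if ("KARYOTYPE" %in% cs) "KARYOTYPE"
    else if ("FISH" %in% cs) "FISH"
    else "OGM"
  }
  vapply(callers, fam, character(1), USE.NAMES = FALSE)
}

# bp tolerance for a platform pair
pair_tolerance <- function(platform_a, platform_b, params) {
  ifelse(platform_a == "OGM" & platform_b == "OGM",
         params$tol_ogm_ogm, params$tol_ogm_array)
}

#' Pseudoautosomal region 1 (PAR1) on chromosome X
#'
#' Returned as a named-region record (not a gene) for the IKZF1plus rule,
#' in internal 0-based half-open coordinates.
#'
#' @return A one-row data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
par1_region <- function() {
  data.frame(name = "PAR1", chrom = "chrX", start = 10000L, end = 2781479L)
}
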