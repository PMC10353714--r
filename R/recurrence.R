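# Minimal altered regions (MARs): recurrence across the cohort.

#' Compute minimal altered regions across a cohort
#'
#' Pass-filter somatic focal calls with spans (deletions, duplications,
#' insertions; SV type is otherwise ignored) are clustered per chromosome
#' by single-linkage any-overlap across patients. Within each cluster the
#' elementary-segment sweep keeps every maximal set of calls with a
#' non-empty common intersection; each such set supported by at least
#' `recurrence_min_cases` distinct patients yields one MAR, the
#' intersection of all supporting spans. Insertions participate via their
#' point span padded by 1 bp on each side. Multiple calls from one patient
#' count once toward the case number. The output is deterministic and
#' ordered left to right; permuting the input leaves it invariant.
#'
#' @param calls somatic, pass-filter SV-call data.frame for the cohort.
#' @param samples sample sheet mapping `sample_id` to `patient_id`.
#' @param config pipeline configuration.
#' @param contigs contig table (used for the focal size classification).
#' @return data.frame of class `leukosv_mars` with columns `mar_id, chrom,
#'   start, end, n_cases, patients, sv_types` plus a `supporting` attribute
#'   (one row per supporting call).
#' @export
compute_mars <- function(calls, samples, config = pipeline_config(),
                         contigs = read_contigs()) {
  keep <- calls$filter_status == "pass" &
    calls$sv_type %in% c("deletion", "duplication", "insertion") &
    classify_size(calls, config, contigs) == "focal"
  x <- calls[keep, , drop = FALSE]
  empty <- data.frame(mar_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_cases = integer(),
                      patients = character(), sv_types = character())
  if (!nrow(x)) return(structure(empty, supporting = x, class = c("leukosv_mars", "data.frame")))
  x$patient_id <- samples$patient_id[match(x$sample_id, samples$sample_id)]
  if (anyNA(x$patient_id)) stop("calls from samples missing in the sample sheet")
  # insertions: point span padded +/- 1 bp
  ins <- x$sv_type == "insertion"
  x$mstart <- ifelse(ins, x$pos1 - 1, x$pos1)
  x$mend <- ifelse(ins, pmax(x$pos2, x$pos1 + 1) + 1, x$pos2)
  gr <- GenomicRanges::GRanges(x$chrom1, IRanges::IRanges(x$mstart + 1, x$mend))
  # single-linkage overlap clusters = reduced ranges
  red <- GenomicRanges::reduce(gr)
  cl <- GenomicRanges::findOverlaps(gr, red, select = "first")
  mars <- list()
  support <- list()
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    sets <- maximal_cover_sets(x$mstart[idx], x$mend[idx])
    for (s in sets) {
      members <- idx[s$members]
      pts <- unique(x$patient_id[members])
      if (length(pts) < config$recurrence_min_cases) next
      mid <- length(mars) + 1L
      mars[[mid]] <- data.frame(
        chrom = x$chrom1[members[1]], start = s$start, end = s$end,
        n_cases = length(pts),
        patients = paste(sort(pts), collapse = ","),
        sv_types = paste(sort(unique(x$sv_type[members])), collapse = ","))
      support[[mid]] <- data.frame(
        chrom = x$chrom1[members[1]], start = s$start, end = s$end,
        call_id = x$call_id[members], sample_id = x$sample_id[members],
        patient_id = x$patient_id[members], sv_type = x$sv_type[members])
    }
  }
  if (!length(mars)) return(structure(empty, supporting = x[0, ],
                                      class = c("leukosv_mars", "data.frame")))
  out <- do.call(rbind, mars)
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  support <- support[ord]
  out$mar_id <- sprintf("MAR_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  sup <- do.call(rbind, lapply(seq_along(support), function(i)
    cbind(mar_id = out$mar_id[i], support[[i]])))
  structure(out[, c("mar_id", "chrom", "start", "end", "n_cases",
                    "patients", "sv_types")],
            supporting = sup, class = c("leukosv_mars", "data.frame"))
}

# All maximal subsets of intervals with non-empty common intersection,
# found by sweeping the elementary segments between sorted breakpoints:
# a covering set is maximal iff it is not a strict subset of the covering
# set of any other segment. Returns list of (members, start, end) with the
# intersection span [max starts, min ends) of the member intervals.
maximal_cover_sets <- function(starts, ends) {
  bp <- sort(unique(c(starts, ends)))
  if (length(bp) < 2) return(list())
  segs <- lapply(seq_len(length(bp) - 1L), function(i) {
    s <- bp[i]; e <- bp[i + 1L]
    which(starts <= s & ends >= e)
  })
  segs <- segs[vapply(segs, length, integer(1)) > 0]
  keys <- vapply(segs, paste, character(1), collapse = ",")
  segs <- segs[!duplicated(keys)]
  is_max <- vapply(seq_along(segs), function(i)
    !any(vapply(seq_along(segs), function(j)
      j != i && length(segs[[i]]) < length(segs[[j]]) &&
        all(segs[[i]] %in% segs[[j]]), logical(1))), logical(1))
  lapply(segs[is_max], function(m)
    list(members = m, start = max(starts[m]), end = min(ends[m])))
}

#' Assign target genes (or nearest gene) to MARs
#'
#' A gene is a target when its body or promoter overlaps the MAR region.
#' MARs without a target are annotated with the nearest gene within the
#' intergenic proximity window, with a signed distance (negative when the
#' MAR lies upstream of the gene's transcription start), or labeled
#' intergenic-distal.
#'
#' @param mars from [compute_mars()].
#' @param models gene models from [read_gene_models()].
#' @param config pipeline configuration.
#' @return `mars` with added columns `target_genes`, `nearest_gene`,
#'   `nearest_distance`, `intergenic`.
#' @export
assign_targets <- function(mars, models, config = pipeline_config()) {
  mars$target_genes <- NA_character_
  mars$nearest_gene <- NA_character_
  mars$nearest_distance <- NA_real_
  mars$intergenic <- NA_character_
  if (!nrow(mars)) return(mars)
  g <- models$genes
  ggr <- genes_granges(models, include_promoter = TRUE)
  mgr <- df_granges(mars)
  hits <- GenomicRanges::findOverlaps(mgr, ggr)
  for (i in seq_len(nrow(mars))) {
    sym <- sort(unique(ggr$symbol[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]))
    if (length(sym)) {
      mars$target_genes[i] <- paste(sym, collapse = ",")
      mars$intergenic[i] <- "genic"
      next
    }
    same <- g[g$chrom == mars$chrom[i], , drop = FALSE]
    if (!nrow(same)) { mars$intergenic[i] <- "intergenic_distal"; next }
    gap <- pmax(same$start - mars$end[i], mars$start[i] - same$end, 0)
    j <- which.min(gap)
    if (gap[j] <= config$intergenic_proximity_bp) {
      # negative sign: MAR on the upstream (5') side of the gene
      upstream <- if (same$strand[j] == "+") mars$end[i] <= same$start[j]
                  else mars$start[i] >= same$end[j]
      mars$nearest_gene[i] <- same$symbol[j]
      mars$nearest_distance[i] <- if (upstream) -gap[j] else gap[j]
      mars$intergenic[i] <- "intergenic_proximal"
    } else {
      mars$intergenic[i] <- "intergenic_distal"
    }
  }
  mars
}

#' Label MAR subtype specificity
#'
#' A MAR is subtype-specific iff all supporting cases share one subtype.
#'
#' @param mars from [compute_mars()].
#' @param samples sample sheet with `patient_id` and `subtype`.
#' @return `mars` with an added `specificity` column
#'   (`ETV6_RUNX1_specific`, `HD_specific`, or `common`).
#' @export
subtype_specificity <- function(mars, samples) {
  sub_of <- function(patients) {
    pts <- strsplit(patients, ",", fixed = TRUE)[[1]]
    st <- unique(samples$subtype[match(pts, samples$patient_id)])
    if (length(st) == 1) paste0(st, "_specific") else "common"
  }
  mars$specificity <- if (nrow(mars))
    vapply(mars$patients, sub_of, character(1), USE.NAMES = FALSE)
  else character()
  mars
}
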