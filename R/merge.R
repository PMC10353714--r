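# Matching predicate and the merge/subtract/filter stages.

# overlap length of two 0-based half-open intervals (vectorized)
interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# reciprocal overlap = min(ov/len1, ov/len2); 0 when either length is 0
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- interval_overlap(s1, e1, s2, e2)
  l1 <- pmax(e1 - s1, 0); l2 <- pmax(e2 - s2, 0)
  ifelse(l1 > 0 & l2 > 0, pmin(ov / l1, ov / l2), 0)
}

# pairwise match evaluation for one (a-row, b-row) combination; returns a
# score (NA = no match): reciprocal overlap for interval calls, else
# 1/(1+mean breakend distance) so larger is better for both paths
match_score_pair <- function(a, b, params) {
  ca <- sv_type_class(a$sv_type); cb <- sv_type_class(b$sv_type)
  if (ca != cb) return(NA_real_)
  tol <- pair_tolerance(caller_platform(a$callers),
                        caller_platform(b$callers), params)
  if (ca == "inter") {
    if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2) {
      d1 <- abs(a$pos1 - b$pos1); d2 <- abs(a$pos2 - b$pos2)
      if (d1 <= tol && d2 <= tol) return(1 / (1 + (d1 + d2) / 2))
    }
    if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1) {
      d1 <- abs(a$pos1 - b$pos2); d2 <- abs(a$pos2 - b$pos1)
      if (d1 <= tol && d2 <= tol) return(1 / (1 + (d1 + d2) / 2))
    }
    return(NA_real_)
  }
  if (a$chrom1 != b$chrom1) return(NA_real_)
  ro <- reciprocal_overlap(a$pos1, a$pos2, b$pos1, b$pos2)
  d1 <- abs(a$pos1 - b$pos1); d2 <- abs(a$pos2 - b$pos2)
  if (ro >= params$reciprocal_overlap_min) return(ro)
  if (d1 <= tol && d2 <= tol) return(max(ro, 1 / (1 + (d1 + d2) / 2)))
  NA_real_
}

#' Do two SV calls describe the same event?
#'
#' Symmetric matching predicate used across pipelines and platforms: the
#' type classes must be compatible (deletion pools with copy loss,
#' duplication with gain), and either the reciprocal overlap reaches the
#' configured minimum or both breakpoint distances are within the
#' platform-pair tolerance. Interchromosomal translocations match when
#' both breakend pairs are within tolerance on matching chromosomes.
#'
#' @param a,b one-row SV-call data.frames.
#' @param params matching tolerances from [match_params()].
#' @return `TRUE` or `FALSE`.
#' @export
match_calls <- function(a, b, params = match_params()) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  !is.na(match_score_pair(as.list(a), as.list(b), params))
}

# all matching (i, j) pairs between two call sets, with scores.
# Candidate generation uses interval-tree overlap queries (GenomicRanges)
# padded by the largest tolerance; candidates are then checked exactly.
match_pairs <- function(A, B, params) {
  if (!nrow(A) || !nrow(B))
    return(data.frame(i = integer(), j = integer(), score = numeric()))
  pad <- max(params$tol_ogm_ogm, params$tol_ogm_array)
  grA <- GenomicRanges::GRanges(A$chrom1,
    IRanges::IRanges(pmin(A$pos1, A$pos2) + 1, pmax(A$pos1, A$pos2, A$pos1 + 1)))
  grB <- GenomicRanges::GRanges(B$chrom1,
    IRanges::IRanges(pmin(B$pos1, B$pos2) + 1, pmax(B$pos1, B$pos2, B$pos1 + 1)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(grA, grB, maxgap = pad))
  cand <- unique(data.frame(i = S4Vectors::queryHits(hits),
                            j = S4Vectors::subjectHits(hits)))
  # translocations can share no interval on chrom1; add class-level pairs
  interA <- which(A$sv_type == "inter_translocation")
  interB <- which(B$sv_type == "inter_translocation")
  if (length(interA) && length(interB))
    cand <- unique(rbind(cand, expand.grid(i = interA, j = interB)))
  if (!nrow(cand))
    return(data.frame(i = integer(), j = integer(), score = numeric()))
  cand$score <- vapply(seq_len(nrow(cand)), function(k) {
    sc <- match_score_pair(as.list(A[cand$i[k], ]), as.list(B[cand$j[k], ]),
                           params)
    if (is.na(sc)) NA_real_ else sc
  }, numeric(1))
  cand[!is.na(cand$score), , drop = FALSE]
}

# deterministic greedy 1-to-1 assignment: by descending score, ties broken
# by leftmost coordinate then call ids
greedy_assign <- function(pairs, A, B) {
  if (!nrow(pairs)) return(pairs[0, c("i", "j")])
  ord <- order(-pairs$score, A$chrom1[pairs$i], pmin(A$pos1, A$pos2)[pairs$i],
               A$call_id[pairs$i], B$call_id[pairs$j])
  pairs <- pairs[ord, , drop = FALSE]
  used_i <- logical(nrow(A)); used_j <- logical(nrow(B))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  pairs[keep, c("i", "j"), drop = FALSE]
}

# canonical call-table sort used before greedy matching so the merge result
# does not depend on input row order
canonical_sort <- function(calls) {
  calls[order(calls$chrom1, pmin(calls$pos1, calls$pos2),
              pmax(calls$pos1, calls$pos2), calls$sv_type, calls$call_id), ,
        drop = FALSE]
}

join_callers <- function(a, b) {
  cs <- unique(c(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]]))
  paste(cs[order(match(cs, CALLER_LABELS))], collapse = ",")
}

#' Convert copy-number segments to SV calls
#'
#' Losses become deletions, gains duplications, CNN-LOH stays `cnn_loh`;
#' segments covering at least the whole-chromosome fraction of their contig
#' become aneuploidy calls. Neutral segments are dropped.
#'
#' @param segments CN segment data.frame.
#' @param contigs contig table.
#' @param config pipeline configuration.
#' @param caller provenance label to attach (default `"CN"`; use
#'   `"ARRAY"` for SNP-array segment tracks).
#' @return SV-call data.frame.
#' @export
cn_segments_to_calls <- function(segments, contigs, config = pipeline_config(),
                                 caller = "CN") {
  segments <- segments[segments$state != "neutral", , drop = FALSE]
  if (!nrow(segments)) return(empty_sv_calls())
  len <- contigs$length[match(segments$chrom, contigs$chrom)]
  whole <- (segments$end - segments$start) >= config$whole_chrom_fraction * len
  sv_type <- ifelse(segments$state == "cnn_loh", "cnn_loh",
             ifelse(segments$state == "loss",
                    ifelse(whole, "aneuploidy_loss", "deletion"),
                    ifelse(whole, "aneuploidy_gain", "duplication")))
  ids <- if ("seg_id" %in% names(segments)) paste0(segments$seg_id, "_", caller)
         else sprintf("%s_%s_%d", caller, segments$sample_id,
                      seq_len(nrow(segments)))
  out <- sv_calls(call_id = ids,
                  sample_id = segments$sample_id, sv_type = sv_type,
                  chrom1 = segments$chrom, pos1 = segments$start,
                  pos2 = segments$end, callers = caller)
  out$n_probes <- segments$n_probes
  out$cn <- segments$cn
  out
}

#' Merge dual-pipeline OGM calls with the large-event CN track
#'
#' Calls detected by both the de novo (DN) and rare-variant (RVP) pipelines
#' collapse into one call with `callers = "DN,RVP"`, keeping the DN
#' coordinates (the DN assembly is the primary callset); unmatched calls
#' are retained with single-caller provenance. CN-tool segments are added
#' only when at least 5 Mb (the focal/large boundary) and not matching any
#' DN/RVP call. The result is deterministic regardless of input row order.
#'
#' @param dn,rvp SV-call data.frames from the two pipelines (one sample).
#' @param cn CN segment data.frame from the OGM CN tool (may be NULL).
#' @param params matching tolerances.
#' @param config pipeline configuration.
#' @param contigs contig table.
#' @return Merged SV-call data.frame with provenance.
#' @export
merge_pipelines <- function(dn, rvp, cn = NULL, params = match_params(),
                            config = pipeline_config(),
                            contigs = read_contigs()) {
  sam <- unique(c(dn$sample_id, rvp$sample_id,
                  if (!is.null(cn)) cn$sample_id))
  if (length(sam) > 1)
    stop("merge_pipelines expects calls from a single sample, got: ",
         paste(sam, collapse = ", "))
  dn <- canonical_sort(dn); rvp <- canonical_sort(rvp)
  pairs <- greedy_assign(match_pairs(dn, rvp, params), dn, rvp)
  merged <- dn
  if (nrow(pairs)) {
    merged$callers[pairs$i] <- vapply(seq_len(nrow(pairs)), function(k)
      join_callers(dn$callers[pairs$i[k]], rvp$callers[pairs$j[k]]),
      character(1))
    # keep the higher VAF when the DN member has none
    na_vaf <- is.na(merged$vaf[pairs$i])
    merged$vaf[pairs$i][na_vaf] <- rvp$vaf[pairs$j][na_vaf]
    rvp_rest <- rvp[-pairs$j, , drop = FALSE]
  } else rvp_rest <- rvp
  merged <- rbind(merged, rvp_rest)
  if (!is.null(cn) && nrow(cn)) {
    cn_calls <- cn_segments_to_calls(cn, contigs, config, caller = "CN")
    cn_calls <- cn_calls[cn_calls$size_bp >= config$focal_large_boundary_bp, ,
                         drop = FALSE]
    if (nrow(cn_calls)) {
      cn_calls <- canonical_sort(cn_calls)
      cpairs <- greedy_assign(match_pairs(cn_calls, merged, params),
                              cn_calls, merged)
      if (nrow(cpairs)) {
        merged$callers[cpairs$j] <- vapply(seq_len(nrow(cpairs)), function(k)
          join_callers(merged$callers[cpairs$j[k]],
                       cn_calls$callers[cpairs$i[k]]), character(1))
        cn_calls <- cn_calls[-cpairs$i, , drop = FALSE]
      }
      common <- intersect(names(merged), names(cn_calls))
      merged <- rbind(merged[, common, drop = FALSE],
                      cn_calls[, common, drop = FALSE])
    }
  }
  merged <- canonical_sort(merged)
  rownames(merged) <- NULL
  merged
}

#' Subtract matched-normal calls from a tumor callset
#'
#' A tumor call is removed iff it matches any call in the matched normal
#' under [match_calls()]. The two outputs partition the input exactly.
#'
#' @param tumor,normal SV-call data.frames of one patient's tumor and
#'   matched normal sample. `normal = NULL` requires `allow_unmatched`.
#' @param params matching tolerances.
#' @param allow_unmatched set `TRUE` to run without a matched normal
#'   (no call is removed).
#' @return List with elements `somatic` and `removed`.
#' @export
subtract_germline <- function(tumor, normal, params = match_params(),
                              allow_unmatched = FALSE) {
  if (is.null(normal)) {
    if (!allow_unmatched)
      stop("no matched normal; pass allow_unmatched = TRUE to keep all calls")
    return(list(somatic = tumor, removed = tumor[0, , drop = FALSE]))
  }
  if (!nrow(tumor)) return(list(somatic = tumor, removed = tumor))
  pairs <- match_pairs(tumor, normal, params)
  hit <- sort(unique(pairs$i))
  list(somatic = tumor[setdiff(seq_len(nrow(tumor)), hit), , drop = FALSE],
       removed = tumor[hit, , drop = FALSE])
}

#' Apply probe, size and blacklist filters
#'
#' Array-derived deletions/duplications are kept iff they have at least the
#' configured probe support and size; CNN-LOH segments are kept iff at
#' least the CNN-LOH minimum size; OGM calls are kept iff at least the OGM
#' minimum size (translocations are exempt from size rules but not from the
#' blacklist). Focal calls whose span — or, for translocations, either
#' breakend — overlaps an IG/TR locus, centromere or reference gap are
#' removed; large and whole-chromosome events necessarily cross such
#' regions (an arm-to-arm duplication or a trisomy is not a centromeric
#' artifact) and are exempt from the blacklist. Every removal carries a
#' machine-readable reason in `filter_status`.
#'
#' @param calls SV-call data.frame; array calls may carry `n_probes`.
#' @param config pipeline configuration.
#' @param blacklist region set from [read_blacklist()].
#' @param contigs contig table (for the focal/large classification).
#' @return List with `kept` and `filtered` (the two partition the input);
#'   `filtered$filter_status` holds `"filtered:<reason>"`.
#' @export
apply_filters <- function(calls, config = pipeline_config(),
                          blacklist = read_blacklist(),
                          contigs = read_contigs()) {
  if (!nrow(calls)) return(list(kept = calls, filtered = calls))
  reason <- rep(NA_character_, nrow(calls))
  focal <- classify_size(calls, config, contigs) == "focal"
  # blacklist overlap (focal spans; breakends for translocations)
  if (nrow(blacklist)) {
    bgr <- df_granges(blacklist)
    span <- calls$sv_type %in% SPAN_TYPES
    g1 <- GenomicRanges::GRanges(calls$chrom1,
            IRanges::IRanges(calls$pos1 + 1,
                             ifelse(span, pmax(calls$pos2, calls$pos1 + 1),
                                    calls$pos1 + 1)))
    hit1 <- suppressWarnings(
      GenomicRanges::findOverlaps(g1, bgr, select = "first"))
    g2 <- GenomicRanges::GRanges(calls$chrom2,
            IRanges::IRanges(calls$pos2 + 1, calls$pos2 + 1))
    hit2 <- suppressWarnings(
      GenomicRanges::findOverlaps(g2, bgr, select = "first"))
    hit2[span] <- NA_integer_
    cls <- ifelse(!is.na(hit1), blacklist$class[hit1], blacklist$class[hit2])
    cls[!focal] <- NA_character_
    reason[!is.na(cls)] <- cls[!is.na(cls)]
  }
  platform <- caller_platform(calls$callers)
  n_probes <- if ("n_probes" %in% names(calls)) calls$n_probes else
    rep(NA_integer_, nrow(calls))
  deldup <- calls$sv_type %in% c("deletion", "duplication")
  size_exempt <- calls$sv_type %in% c("inter_translocation",
                                      "aneuploidy_gain", "aneuploidy_loss")
  arr <- platform == "ARRAY"
  conv <- platform %in% c("KARYOTYPE", "FISH")
  need <- is.na(reason) & !size_exempt & !conv
  # array probe/size rules for del/dup
  i <- need & arr & deldup & !is.na(n_probes) & n_probes < config$array_min_probes
  reason[i] <- "min_probes"
  i <- is.na(reason) & need & arr & deldup & calls$size_bp < config$array_min_cnv_bp
  reason[i] <- "min_size"
  # CNN-LOH minimum size (any platform)
  i <- is.na(reason) & need & calls$sv_type == "cnn_loh" &
    calls$size_bp < config$cnnloh_min_bp
  reason[i] <- "cnnloh_min_size"
  # OGM minimum SV size
  i <- is.na(reason) & need & !arr & calls$sv_type != "cnn_loh" &
    calls$size_bp < config$ogm_min_sv_bp
  reason[i] <- "min_size"
  kept <- calls[is.na(reason), , drop = FALSE]
  filtered <- calls[!is.na(reason), , drop = FALSE]
  if (nrow(filtered))
    filtered$filter_status <- paste0("filtered:", reason[!is.na(reason)])
  list(kept = kept, filtered = filtered)
}

#' Classify call size: focal, large, or whole-chromosome
#'
#' Focal below the 5 Mb boundary (translocations are focal by convention),
#' large at or above it, whole-chromosome when the span covers at least the
#' configured fraction of the contig (aneuploidy types are always
#' whole-chromosome).
#'
#' @param calls SV-call data.frame.
#' @param config pipeline configuration.
#' @param contigs contig table.
#' @return Character vector along `calls`.
#' @export
classify_size <- function(calls, config = pipeline_config(),
                          contigs = read_contigs()) {
  if (!nrow(calls)) return(character())
  out <- rep("focal", nrow(calls))
  span <- calls$sv_type %in% SPAN_TYPES
  large <- span & calls$size_bp >= config$focal_large_boundary_bp
  out[large] <- "large"
  len <- contigs$length[match(calls$chrom1, contigs$chrom)]
  whole <- span & !is.na(len) & calls$size_bp >= config$whole_chrom_fraction * len
  out[whole | calls$sv_type %in% c("aneuploidy_gain", "aneuploidy_loss")] <-
    "whole_chromosome"
  out[calls$sv_type == "inter_translocation"] <- "focal"
  out
}
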