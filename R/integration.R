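# Per-patient integration of SV and SNV evidence.

#' Build per-patient profiles
#'
#' Joins each patient's pass-filter somatic SV calls and small variants and
#' derives a per-chromosome integer copy-state map from whole-chromosome
#' calls (aneuploidies, whole-chromosome CN segments). The baseline is 2
#' for every contig; a gain call raises the state to its `cn` value when
#' recorded, else to 3; a loss lowers it to `cn` or 1.
#'
#' @param calls somatic SV-call data.frame (cohort).
#' @param snvs small-variant data.frame (cohort).
#' @param samples sample sheet.
#' @param contigs contig table.
#' @param config pipeline configuration.
#' @return Named list of profiles, one per tumor patient: each a list with
#'   `patient_id`, `subtype`, `calls`, `snvs`, `copy_states`.
#' @export
build_patient_profiles <- function(calls, snvs, samples,
                                   contigs = read_contigs(),
                                   config = pipeline_config()) {
  tum <- samples[samples$role %in% c("tumor", "relapse"), , drop = FALSE]
  chroms <- setdiff(contigs$chrom, "chrY")
  lapply(stats::setNames(nm = unique(tum$patient_id)), function(p) {
    sids <- tum$sample_id[tum$patient_id == p]
    pc <- calls[calls$sample_id %in% sids & calls$filter_status == "pass", ,
                drop = FALSE]
    ps <- snvs[snvs$sample_id %in% sids, , drop = FALSE]
    cs <- stats::setNames(rep(2L, length(chroms)), chroms)
    whole <- pc[classify_size(pc, config, contigs) == "whole_chromosome", ,
                drop = FALSE]
    for (i in seq_len(nrow(whole))) {
      ch <- whole$chrom1[i]
      if (!ch %in% names(cs)) next
      cnv <- if ("cn" %in% names(whole)) whole$cn[i] else NA_integer_
      if (whole$sv_type[i] %in% c("aneuploidy_gain", "duplication"))
        cs[ch] <- max(cs[ch], if (!is.na(cnv)) cnv else 3L)
      else if (whole$sv_type[i] %in% c("aneuploidy_loss", "deletion"))
        cs[ch] <- min(cs[ch], if (!is.na(cnv)) cnv else 1L)
    }
    list(patient_id = p, subtype = tum$subtype[tum$patient_id == p][1],
         calls = pc, snvs = ps, copy_states = cs)
  })
}

# call ids of somatic SVs hitting a gene region (body + promoter, or a
# translocation breakend inside the window)
sv_hits_region <- function(calls, chrom, start, end) {
  if (!nrow(calls)) return(character())
  span <- calls$sv_type %in% SPAN_TYPES
  hit1 <- calls$chrom1 == chrom &
    ifelse(span, calls$pos1 < end & calls$pos2 > start,
           calls$pos1 >= start & calls$pos1 < end)
  hit2 <- !span & calls$chrom2 == chrom &
    calls$pos2 >= start & calls$pos2 < end
  calls$call_id[hit1 | hit2]
}

#' Detect genes hit by both an SV and a small variant in the same patient
#'
#' A double hit is a (patient, gene) pair where at least one pass-filter
#' somatic SV overlaps the gene (body or promoter, or a translocation
#' breakend inside it) and at least one somatic SNV/indel lies within the
#' gene body of the same patient. SNVs are located positionally against
#' the same gene models used for the SV side. Numerical alterations
#' (whole-chromosome aneuploidies, CNN-LOH) are not gene-level evidence
#' and are excluded from the SV side.
#'
#' @param profiles from [build_patient_profiles()].
#' @param models gene models.
#' @return data.frame `patient_id, gene, sv_evidence, sv_types,
#'   snv_evidence, snv_effects` (one row per double hit).
#' @export
detect_double_hits <- function(profiles, models) {
  g <- models$genes
  out <- list()
  for (pr in profiles) {
    calls <- pr$calls[!pr$calls$sv_type %in%
                        c("aneuploidy_gain", "aneuploidy_loss", "cnn_loh"), ,
                      drop = FALSE]
    if (!nrow(calls) || !nrow(pr$snvs)) next
    for (i in seq_len(nrow(g))) {
      gs <- min(g$start[i], g$promoter_start[i])
      ge <- max(g$end[i], g$promoter_end[i])
      sv_ids <- sv_hits_region(calls, g$chrom[i], gs, ge)
      if (!length(sv_ids)) next
      in_gene <- pr$snvs$chrom == g$chrom[i] &
        pr$snvs$pos >= g$start[i] & pr$snvs$pos < g$end[i]
      if (!any(in_gene)) next
      sv_types <- calls$sv_type[match(sv_ids, calls$call_id)]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pr$patient_id, gene = g$symbol[i],
        sv_evidence = paste(sv_ids, collapse = ","),
        sv_types = paste(sv_types, collapse = ","),
        snv_evidence = paste(pr$snvs$variant_id[in_gene], collapse = ","),
        snv_effects = paste(pr$snvs$effect[in_gene], collapse = ","))
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), gene = character(),
                      sv_evidence = character(), sv_types = character(),
                      snv_evidence = character(), snv_effects = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate the IKZF1plus copy-number profile
#'
#' IKZF1plus: at least one deletion overlapping IKZF1, at least one
#' deletion overlapping CDKN2A, CDKN2B, PAX5 or the PAR1 region, and no
#' deletion overlapping ERG. A subclonal flag is attached when the best
#' IKZF1 deletion has VAF < 0.1 (the profile itself is evaluated
#' regardless of clonality; interpretation is left to the user).
#'
#' @param profile one profile from [build_patient_profiles()].
#' @param models gene models; must contain IKZF1, CDKN2A, CDKN2B, PAX5, ERG.
#' @param par1 PAR1 named-region record, see [par1_region()].
#' @param config pipeline configuration.
#' @return List with `status` (logical), `subclonal` (logical), and
#'   `rationale`, a named list of supporting call ids per criterion.
#' @export
evaluate_ikzf1_plus <- function(profile, models, par1 = par1_region(),
                                config = pipeline_config()) {
  g <- models$genes
  need <- c("IKZF1", "CDKN2A", "CDKN2B", "PAX5", "ERG")
  miss <- setdiff(need, g$symbol)
  if (length(miss))
    stop("gene model(s) required for IKZF1plus missing: ",
         paste(miss, collapse = ", "))
  dels <- profile$calls[profile$calls$sv_type == "deletion", , drop = FALSE]
  hits_gene <- function(sym) {
    gi <- g[g$symbol == sym, ]
    sv_hits_region(dels, gi$chrom, gi$start, gi$end)
  }
  ikzf1 <- hits_gene("IKZF1")
  co <- list(CDKN2A = hits_gene("CDKN2A"), CDKN2B = hits_gene("CDKN2B"),
             PAX5 = hits_gene("PAX5"),
             PAR1 = sv_hits_region(dels, par1$chrom, par1$start, par1$end))
  erg <- hits_gene("ERG")
  status <- length(ikzf1) > 0 && any(lengths(co) > 0) && length(erg) == 0
  vafs <- dels$vaf[match(ikzf1, dels$call_id)]
  subclonal <- length(ikzf1) > 0 && all(is.na(vafs) | vafs < 0.1) &&
    any(!is.na(vafs) & vafs < 0.1)
  list(status = status, subclonal = subclonal,
       rationale = c(list(IKZF1 = ikzf1), co, list(ERG_exclusion = erg)))
}

#' Classify hyperdiploid aneuploidy risk
#'
#' Poor-risk profile for classical hyperdiploid BCP-ALL: no trisomy of
#' chromosomes 17 and 18, or trisomy of 17 or 18 together with trisomy of
#' 5 or 20. Trisomy means copy number >= 3 (tetrasomy also qualifies:
#' the rule is about the presence of gains). Non-HD profiles return
#' `not_applicable`. With `hd_trisomy_exclusive` the "either 17 or 18"
#' clause is read as exclusive-or.
#'
#' @param profile one profile from [build_patient_profiles()], or any list
#'   with `subtype` and a named `copy_states` vector.
#' @param config pipeline configuration.
#' @return `"poor"`, `"not_poor"`, or `"not_applicable"`.
#' @export
classify_hd_risk <- function(profile, config = pipeline_config()) {
  if (!identical(profile$subtype, "HD")) return("not_applicable")
  cs <- profile$copy_states
  cn <- function(ch) if (ch %in% names(cs)) cs[[ch]] else 2L
  t17 <- cn("chr17") >= 3; t18 <- cn("chr18") >= 3
  t5 <- cn("chr5") >= 3; t20 <- cn("chr20") >= 3
  either_1718 <- if (config$hd_trisomy_exclusive) xor(t17, t18) else (t17 || t18)
  if ((!t17 && !t18) || (either_1718 && (t5 || t20))) "poor" else "not_poor"
}

#' Approximate putative fusion genes from a translocation
#'
#' For each breakend, genes overlapping it (or within a window) are paired
#' across the junction. A pair is orientation-compatible when the retained
#' sides and gene strands admit a head-to-tail (5' to 3') transcript; with
#' unknown orientations compatibility is NA. Breakpoint resolution is
#' label-scale, so every candidate is labeled putative; no codon-phase
#' check is attempted.
#'
#' @param call one-row SV-call data.frame with two breakends
#'   (inter- or intrachromosomal translocation).
#' @param models gene models.
#' @param config pipeline configuration (`fusion_window_bp`).
#' @return data.frame `gene5, gene3, orientation_compatible, confidence`.
#' @export
predict_fusions <- function(call, models, config = pipeline_config()) {
  stopifnot(nrow(call) == 1)
  if (!call$sv_type %in% c("inter_translocation", "intra_translocation"))
    stop("predict_fusions expects a translocation call")
  g <- models$genes
  w <- config$fusion_window_bp
  near <- function(chrom, pos)
    which(g$chrom == chrom & g$start - w <= pos & g$end + w > pos)
  g1 <- near(call$chrom1, call$pos1)
  g2 <- near(call$chrom2, call$pos2)
  empty <- data.frame(gene5 = character(), gene3 = character(),
                      orientation_compatible = logical(),
                      confidence = character())
  if (!length(g1) || !length(g2)) return(empty)
  # role of a gene at a breakend: which part of the transcript is retained
  # on the kept side of the junction
  role <- function(gi, orient) {
    if (orient == "unknown") return(NA_character_)
    keep5 <- (orient == "left") == (g$strand[gi] == "+")
    if (keep5) "five_prime" else "three_prime"
  }
  out <- list()
  for (i in g1) for (j in g2) {
    r1 <- role(i, call$orient1); r2 <- role(j, call$orient2)
    if (is.na(r1) || is.na(r2)) {
      out[[length(out) + 1L]] <- data.frame(
        gene5 = g$symbol[i], gene3 = g$symbol[j],
        orientation_compatible = NA, confidence = "putative")
    } else if (r1 == "five_prime" && r2 == "three_prime") {
      out[[length(out) + 1L]] <- data.frame(
        gene5 = g$symbol[i], gene3 = g$symbol[j],
        orientation_compatible = TRUE, confidence = "putative")
    } else if (r1 == "three_prime" && r2 == "five_prime") {
      out[[length(out) + 1L]] <- data.frame(
        gene5 = g$symbol[j], gene3 = g$symbol[i],
        orientation_compatible = TRUE, confidence = "putative")
    } else {
      out[[length(out) + 1L]] <- data.frame(
        gene5 = g$symbol[i], gene3 = g$symbol[j],
        orientation_compatible = FALSE, confidence = "putative")
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
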