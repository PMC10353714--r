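# Cohort summaries and the rank-sum comparison between subtypes.

BURDEN_TYPES <- c("deletion", "duplication", "insertion", "inversion",
                  "intra_translocation", "inter_translocation")

#' Per-case SV burden table
#'
#' Counts pass-filter, non-hallmark somatic SVs per case and type (the
#' subtype-defining translocation and whole-chromosome alterations are
#' excluded via the `hallmark` flag and the size classification), split
#' into focal and large. `total` is the row sum over the type columns.
#'
#' @param calls somatic SV-call data.frame (cohort).
#' @param samples sample sheet.
#' @param config pipeline configuration.
#' @param contigs contig table.
#' @return data.frame with one row per tumor case: `patient_id, subtype,
#'   total, <type counts>, n_focal, n_large`.
#' @export
burden_per_case <- function(calls, samples, config = pipeline_config(),
                            contigs = read_contigs()) {
  tum <- samples[samples$role == "tumor", , drop = FALSE]
  x <- calls[calls$filter_status == "pass" & !calls$hallmark, , drop = FALSE]
  x <- x[x$sv_type %in% BURDEN_TYPES, , drop = FALSE]
  sclass <- classify_size(x, config, contigs)
  x <- x[sclass != "whole_chromosome", , drop = FALSE]
  sclass <- sclass[sclass != "whole_chromosome"]
  x$patient_id <- samples$patient_id[match(x$sample_id, samples$sample_id)]
  rows <- lapply(seq_len(nrow(tum)), function(i) {
    xi <- x$patient_id == tum$patient_id[i]
    cnt <- vapply(BURDEN_TYPES, function(tp)
      sum(xi & x$sv_type == tp), integer(1))
    c(list(patient_id = tum$patient_id[i], subtype = tum$subtype[i],
           total = sum(cnt)), as.list(cnt),
      list(n_focal = sum(xi & sclass == "focal"),
           n_large = sum(xi & sclass == "large")))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (rank sum with midranks)
#'
#' U is computed from midranks. For small samples (nx + ny <= `exact_max`)
#' the permutation distribution of U is enumerated exactly — including
#' under ties — and the two-sided p-value is
#' P(|U - nx*ny/2| >= |u - nx*ny/2|) (the permutation distribution of U is
#' symmetric about nx*ny/2 under group-label exchange). Otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. Degenerate input (all values identical) gives p = 1.
#'
#' @param x,y numeric vectors (counts), each non-empty.
#' @param exact_max largest nx + ny for which exact enumeration is used.
#' @return List with `U` (for `x`), `z`, `p_two_sided`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, z = 0, p_two_sided = 1, method = "degenerate"))
  if (nx + ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, z = NA_real_, p_two_sided = p, method = "exact"))
  }
  n <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0)
    return(list(U = U, z = 0, p_two_sided = 1, method = "degenerate"))
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(v)
  list(U = U, z = z, p_two_sided = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Caller-provenance composition of a merged callset
#'
#' @param calls merged SV-call data.frame with a `callers` column.
#' @return data.frame `callers, n, fraction, percent` (fractions sum to 1;
#'   percent rounded half-up to one decimal).
#' @export
provenance_summary <- function(calls) {
  if (!nrow(calls)) stop("empty callset")
  canon <- vapply(strsplit(calls$callers, ",", fixed = TRUE), function(cs)
    paste(cs[order(match(cs, CALLER_LABELS))], collapse = ","), character(1))
  tab <- table(canon)
  out <- data.frame(callers = names(tab), n = as.integer(tab))
  out$fraction <- out$n / sum(out$n)
  out$percent <- round_half_up(100 * out$fraction, 1)
  out[order(-out$n, out$callers), ]
}

#' Fold change between two counts
#'
#' @param a,b counts (numerator, denominator); `b` must be non-zero.
#' @return List with `ratio` (exact) and `ratio_1dp` (half-up, one
#'   decimal, the reporting convention for fold differences).
#' @export
fold_changes <- function(a, b) {
  if (b == 0) stop("zero denominator in fold change")
  list(ratio = a / b, ratio_1dp = round_half_up(a / b, 1))
}

#' Oncoprint-style alteration matrix
#'
#' Cases by MARs; each cell is an alteration code built from the SV types
#' supporting the MAR in that case (DEL/DUP/INS), plus `SNV` when a target
#' gene of the MAR carries a small variant in the case.
#'
#' @param mars annotated MARs ([compute_mars()] then [assign_targets()]).
#' @param snvs small-variant data.frame.
#' @param samples sample sheet.
#' @return Character matrix (cases x MARs), `""` for unaltered.
#' @export
build_oncoprint <- function(mars, snvs, samples) {
  sup <- attr(mars, "supporting")
  cases <- unique(samples$patient_id[samples$role == "tumor"])
  m <- matrix("", nrow = length(cases), ncol = nrow(mars),
              dimnames = list(cases, mars$mar_id))
  code <- c(deletion = "DEL", duplication = "DUP", insertion = "INS",
            inversion = "INV", intra_translocation = "TRA",
            inter_translocation = "TRA")
  snv_pt <- snvs
  if (nrow(snvs))
    snv_pt$patient_id <- samples$patient_id[match(snvs$sample_id,
                                                  samples$sample_id)]
  for (k in seq_len(nrow(mars))) {
    sk <- sup[sup$mar_id == mars$mar_id[k], , drop = FALSE]
    targets <- if (!is.na(mars$target_genes[k]))
      strsplit(mars$target_genes[k], ",")[[1]] else character()
    for (p in cases) {
      codes <- unique(code[sk$sv_type[sk$patient_id == p]])
      if (nrow(snvs) && length(targets) &&
          any(snv_pt$patient_id == p & snv_pt$gene %in% targets))
        codes <- c(codes, "SNV")
      if (length(codes)) m[p, k] <- paste(sort(codes), collapse = "+")
    }
  }
  m
}

#' Circos-style segment and link exports
#'
#' Interval calls become per-chromosome segments; translocations and
#' inversions become links between their breakends.
#'
#' @param calls SV-call data.frame.
#' @return List with `segments` (chrom, start, end, sv_type) and `links`
#'   (chrom1, pos1, chrom2, pos2, sv_type).
#' @export
circos_links <- function(calls) {
  seg_types <- c("deletion", "duplication", "insertion",
                 "aneuploidy_gain", "aneuploidy_loss", "cnn_loh")
  s <- calls[calls$sv_type %in% seg_types, , drop = FALSE]
  l <- calls[calls$sv_type %in% c("inversion", "intra_translocation",
                                  "inter_translocation"), , drop = FALSE]
  list(segments = data.frame(chrom = s$chrom1, start = s$pos1, end = s$pos2,
                             sv_type = s$sv_type),
       links = data.frame(chrom1 = l$chrom1, pos1 = l$pos1,
                          chrom2 = l$chrom2, pos2 = l$pos2,
                          sv_type = l$sv_type))
}
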