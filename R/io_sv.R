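# TSV dialects are 1-based inclusive on disk (as printed in reports);
# everything in memory is 0-based half-open.

SV_FILE_COLS <- c("call_id", "sample_id", "chrom1", "pos1", "chrom2", "pos2",
                  "sv_type", "size_bp", "vaf", "orient1", "orient2",
                  "callers", "filter_status", "hallmark")

empty_sv_calls <- function() {
  data.frame(call_id = character(), sample_id = character(),
             sv_type = character(), chrom1 = character(), pos1 = integer(),
             chrom2 = character(), pos2 = integer(), orient1 = character(),
             orient2 = character(), size_bp = numeric(), vaf = numeric(),
             callers = character(), filter_status = character(),
             hallmark = logical(), stringsAsFactors = FALSE)
}

#' Construct a structural-variant call table
#'
#' Builds the internal SV-call data.frame used throughout the pipeline and
#' validates its invariants (known sv_type, 0 <= pos1 < pos2 for span types,
#' different contigs for interchromosomal translocations, non-empty caller
#' provenance, VAF in \[0, 1\] when present).
#'
#' For span-shaped types (deletions, duplications, insertions, inversions,
#' intrachromosomal translocations, aneuploidies, CNN-LOH) `pos1`/`pos2`
#' are the 0-based half-open span; for interchromosomal translocations they
#' are the two breakend positions.
#'
#' @param call_id,sample_id,sv_type,chrom1,pos1,chrom2,pos2 core fields.
#' @param orient1,orient2 breakend orientations (`left`/`right`/`unknown`):
#'   the side of the junction that is retained.
#' @param size_bp event size (0 when undefined, e.g. translocations).
#' @param vaf variant allele fraction or NA.
#' @param callers comma-joined subset of DN,RVP,CN,ARRAY,KARYOTYPE,FISH.
#' @param filter_status `"pass"` or `"filtered:<reason>"`.
#' @param hallmark subtype-defining lesion flag (set by the simulator or
#'   upstream curation; hallmark events are excluded from burden counts).
#' @return Validated SV-call data.frame.
#' @export
sv_calls <- function(call_id, sample_id, sv_type, chrom1, pos1,
                     chrom2 = chrom1, pos2, orient1 = "unknown",
                     orient2 = "unknown", size_bp = NA_real_, vaf = NA_real_,
                     callers, filter_status = "pass", hallmark = FALSE) {
  df <- data.frame(call_id = as.character(call_id),
                   sample_id = as.character(sample_id),
                   sv_type = as.character(sv_type),
                   chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                   chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                   orient1 = as.character(orient1),
                   orient2 = as.character(orient2),
                   size_bp = as.numeric(size_bp), vaf = as.numeric(vaf),
                   callers = as.character(callers),
                   filter_status = as.character(filter_status),
                   hallmark = as.logical(hallmark),
                   stringsAsFactors = FALSE)
  span <- df$sv_type %in% SPAN_TYPES
  df$size_bp[span & df$sv_type != "insertion"] <-
    df$pos2[span & df$sv_type != "insertion"] -
    df$pos1[span & df$sv_type != "insertion"]
  df$size_bp[is.na(df$size_bp)] <- 0
  validate_sv_calls(df)
  df
}

validate_sv_calls <- function(calls, contigs = NULL) {
  if (!nrow(calls)) return(invisible(calls))
  bad_type <- setdiff(unique(calls$sv_type), SV_TYPES)
  if (length(bad_type)) stop("unknown sv_type: ", paste(bad_type, collapse = ", "))
  span <- calls$sv_type %in% SPAN_TYPES
  if (any(calls$pos1[span] < 0) || any(calls$pos1[span] >= calls$pos2[span]))
    stop("span calls require 0 <= start < end")
  inter <- calls$sv_type == "inter_translocation"
  if (any(calls$chrom1[inter] == calls$chrom2[inter]))
    stop("interchromosomal translocation with identical contigs")
  if (any(!nzchar(calls$callers)))
    stop("caller provenance must be non-empty")
  known <- vapply(strsplit(calls$callers, ",", fixed = TRUE),
                  function(cs) all(cs %in% CALLER_LABELS), logical(1))
  if (!all(known)) stop("unknown caller label in provenance")
  v <- calls$vaf[!is.na(calls$vaf)]
  if (any(v < 0 | v > 1)) stop("vaf outside [0, 1]")
  if (anyDuplicated(calls$call_id)) stop("duplicate call_id")
  if (!is.null(contigs))
    check_contigs(c(calls$chrom1, calls$chrom2), contigs, "SV call table")
  invisible(calls)
}

#' Read a structural-variant call table
#'
#' TSV dialect with header columns `call_id, chrom1, pos1, chrom2, pos2,
#' sv_type, size_bp, vaf` (positions 1-based inclusive; `vaf` may be `.`)
#' and optional `sample_id, orient1, orient2, callers, filter_status,
#' hallmark` columns. Coordinates are converted to 0-based half-open, the
#' caller label is attached, and sizes of span-shaped calls are recomputed
#' from the coordinates (printed sizes are not trusted).
#'
#' @param path TSV file.
#' @param caller caller label to attach (ignored when the file carries a
#'   `callers` column).
#' @param contigs contig table from [read_contigs()]; rows on unknown
#'   contigs are rejected.
#' @param sample_id sample to attach when the file has no `sample_id`
#'   column (defaults to the file name stem).
#' @return SV-call data.frame (see [sv_calls()]).
#' @export
read_sv_table <- function(path, caller = NULL, contigs = read_contigs(),
                          sample_id = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("NA", "."),
                           quote = "", comment.char = "")
  need <- c("call_id", "chrom1", "pos1", "chrom2", "pos2", "sv_type",
            "size_bp", "vaf")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(raw)) return(empty_sv_calls())
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  pos1 <- num("pos1"); pos2 <- num("pos2")
  bad <- which(is.na(pos1) | is.na(pos2) | !raw$sv_type %in% SV_TYPES)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
  if (anyDuplicated(raw$call_id))
    stop("duplicate call_id in ", path)
  check_contigs(c(raw$chrom1, raw$chrom2), contigs, path)
  span <- raw$sv_type %in% SPAN_TYPES
  # 1-based inclusive (s, e) -> 0-based half-open [s-1, e)
  p1 <- ifelse(span, pos1 - 1, pos1 - 1)
  p2 <- ifelse(span, pos2, pos2 - 1)
  sid <- if ("sample_id" %in% names(raw)) raw$sample_id
         else rep(sample_id %||% sub("\\.[^.]*$", "", basename(path)), nrow(raw))
  callers <- if ("callers" %in% names(raw)) raw$callers
             else if (!is.null(caller)) rep(caller, nrow(raw))
             else stop("no caller label given and no callers column present")
  df <- sv_calls(call_id = raw$call_id, sample_id = sid, sv_type = raw$sv_type,
                 chrom1 = raw$chrom1, pos1 = p1, chrom2 = raw$chrom2, pos2 = p2,
                 orient1 = if ("orient1" %in% names(raw)) raw$orient1 else "unknown",
                 orient2 = if ("orient2" %in% names(raw)) raw$orient2 else "unknown",
                 size_bp = num("size_bp"), vaf = num("vaf"),
                 callers = callers,
                 filter_status = if ("filter_status" %in% names(raw))
                   raw$filter_status else "pass",
                 hallmark = if ("hallmark" %in% names(raw))
                   as.logical(raw$hallmark) else FALSE)
  validate_sv_calls(df, contigs)
  df
}

#' Write a structural-variant call table
#'
#' Inverse of [read_sv_table()]: converts the internal 0-based half-open
#' coordinates back to the 1-based inclusive dialect. Reading the written
#' file reproduces all fields bit-exactly.
#'
#' @param calls SV-call data.frame.
#' @param path output TSV.
#' @export
write_sv_table <- function(calls, path) {
  validate_sv_calls(calls)
  span <- calls$sv_type %in% SPAN_TYPES
  out <- data.frame(call_id = calls$call_id, sample_id = calls$sample_id,
                    chrom1 = calls$chrom1,
                    pos1 = format_pos(calls$pos1 + 1),
                    chrom2 = calls$chrom2,
                    pos2 = format_pos(ifelse(span, calls$pos2, calls$pos2 + 1)),
                    sv_type = calls$sv_type,
                    size_bp = format_pos(calls$size_bp),
                    vaf = ifelse(is.na(calls$vaf), ".",
                                 formatC(calls$vaf, digits = 17, format = "g")),
                    orient1 = calls$orient1, orient2 = calls$orient2,
                    callers = calls$callers,
                    filter_status = calls$filter_status,
                    hallmark = calls$hallmark)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_pos <- function(x) formatC(x, format = "d")

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- copy-number segments --------------------------------------------------

ARRAY_PLATFORMS <- c("CytoSNP12", "CytoScanHD")
CN_PLATFORMS <- c(ARRAY_PLATFORMS, "OGM_CN")
CN_STATES <- c("loss", "gain", "neutral", "cnn_loh")

#' Read copy-number segments (SEG-like dialect)
#'
#' TSV with header `sample_id, chrom, start, end, state, n_probes` and an
#' optional integer `cn` column; coordinates 1-based inclusive, converted
#' to 0-based half-open. `state` is one of loss/gain/neutral/cnn_loh.
#' For array platforms `n_probes` must be present and positive; size and
#' CNN-LOH filters are applied later, the reader keeps all segments.
#'
#' @param path TSV file.
#' @param platform one of `"CytoSNP12"`, `"CytoScanHD"`, `"OGM_CN"`.
#' @param contigs contig table.
#' @return data.frame `sample_id, chrom, start, end, state, n_probes, cn,
#'   platform`.
#' @export
read_cn_segments <- function(path, platform, contigs = read_contigs()) {
  platform <- match.arg(platform, CN_PLATFORMS)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("NA", "."))
  need <- c("sample_id", "chrom", "start", "end", "state", "n_probes")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(raw))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), state = character(),
                      n_probes = integer(), cn = integer(),
                      platform = character()))
  start1 <- suppressWarnings(as.numeric(raw$start))
  end1 <- suppressWarnings(as.numeric(raw$end))
  if (anyNA(start1) || anyNA(end1)) stop("malformed coordinates in ", path)
  check_contigs(raw$chrom, contigs, path)
  if (any(!raw$state %in% CN_STATES))
    stop("unknown CN state in ", path)
  n_probes <- suppressWarnings(as.integer(raw$n_probes))
  if (platform %in% ARRAY_PLATFORMS && (anyNA(n_probes) || any(n_probes <= 0)))
    stop("array platform requires positive n_probes")
  n_probes[is.na(n_probes)] <- 0L
  seg <- data.frame(sample_id = raw$sample_id, chrom = raw$chrom,
                    start = start1 - 1, end = end1, state = raw$state,
                    n_probes = n_probes,
                    cn = if ("cn" %in% names(raw))
                      suppressWarnings(as.integer(raw$cn)) else NA_integer_,
                    platform = platform)
  if ("seg_id" %in% names(raw)) seg$seg_id <- raw$seg_id
  if (any(seg$end - seg$start <= 0)) stop("zero-length segment in ", path)
  seg
}

#' Write copy-number segments
#' @param segments data.frame from [read_cn_segments()].
#' @param path output TSV.
#' @export
write_cn_segments <- function(segments, path) {
  out <- data.frame(sample_id = segments$sample_id, chrom = segments$chrom,
                    start = format_pos(segments$start + 1),
                    end = format_pos(segments$end),
                    state = segments$state, n_probes = segments$n_probes,
                    cn = ifelse(is.na(segments$cn), ".",
                                format_pos(segments$cn)))
  if ("seg_id" %in% names(segments)) out$seg_id <- segments$seg_id
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample sheet ----------------------------------------------------------

#' Read a sample sheet
#'
#' TSV with columns `sample_id, patient_id, subtype, role, blast_fraction`;
#' subtype in `{ETV6_RUNX1, HD}`, role in `{tumor, normal, relapse}`. Each
#' tumor must have exactly one matched normal for the same patient.
#'
#' @param path TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  sm <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(blast_fraction = "numeric"),
                          stringsAsFactors = FALSE)
  validate_sample_sheet(sm)
}

validate_sample_sheet <- function(sm) {
  need <- c("sample_id", "patient_id", "subtype", "role", "blast_fraction")
  miss <- setdiff(need, names(sm))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!sm$subtype %in% c("ETV6_RUNX1", "HD"))) stop("unknown subtype")
  if (any(!sm$role %in% c("tumor", "normal", "relapse"))) stop("unknown role")
  bf <- sm$blast_fraction[!is.na(sm$blast_fraction)]
  if (any(bf < 0 | bf > 1)) stop("blast_fraction outside [0, 1]")
  for (p in unique(sm$patient_id[sm$role == "tumor"])) {
    if (sum(sm$patient_id == p & sm$role == "normal") != 1L)
      stop("tumor without exactly one matched normal: ", p)
  }
  sm
}

#' Write a sample sheet
#' @param samples sample metadata data.frame.
#' @param path output TSV.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- small variants (VCF) --------------------------------------------------

EFFECT_MAP <- c(missense = "missense", missense_variant = "missense",
                frameshift = "frameshift", frameshift_variant = "frameshift",
                stopgain = "stopgain", stop_gained = "stopgain",
                splice = "splice", splice_acceptor_variant = "splice",
                splice_donor_variant = "splice", splice_region_variant = "splice",
                inframe_indel = "inframe_indel",
                inframe_insertion = "inframe_indel",
                inframe_deletion = "inframe_indel",
                other = "other")

map_effect <- function(effect) {
  out <- unname(EFFECT_MAP[effect])
  unknown <- is.na(out) & !is.na(effect)
  if (any(unknown)) {
    warning("unknown effect string(s) mapped to 'other': ",
            paste(unique(effect[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  out[is.na(out)] <- "other"
  out
}

#' Read somatic small variants from a VCF
#'
#' Expects a VCF 4.x with per-sample genotypes and `GENE`/`EFFECT` INFO
#' annotation (the dialect written by the cohort simulator) and a per-sample
#' `VAF` FORMAT field. One row is emitted per carrier sample-allele;
#' records with no carrier among the requested samples are dropped. Effect
#' strings outside the closed vocabulary are mapped to `"other"` with a
#' warning.
#'
#' @param path VCF file (plain text or bgzip).
#' @param samples sample sheet; only these sample ids are scanned.
#' @return data.frame `variant_id, sample_id, chrom, pos, ref, alt, gene,
#'   effect, vaf` with 0-based `pos`.
#' @export
read_small_variants <- function(path, samples) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  vafm <- if ("VAF" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$VAF else NULL
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(info)) as.character(info$GENE)
          else rep(NA_character_, length(rr))
  effect <- if ("EFFECT" %in% names(info)) map_effect(as.character(info$EFFECT))
            else rep("other", length(rr))
  keep_samples <- intersect(colnames(gt), samples$sample_id)
  out <- list()
  for (s in keep_samples) {
    carrier <- gt[, s] %in% c("0/1", "1/0", "1/1", "0|1", "1|0", "1|1")
    if (!any(carrier)) next
    idx <- which(carrier)
    alt <- vapply(idx, function(i)
      as.character(rr$ALT[[i]][1]), character(1))
    out[[s]] <- data.frame(
      variant_id = paste0(names(rr)[idx], "_", s),
      sample_id = s,
      chrom = as.character(GenomicRanges::seqnames(rr))[idx],
      pos = GenomicRanges::start(rr)[idx] - 1L,
      ref = as.character(rr$REF)[idx],
      alt = alt,
      gene = gene[idx], effect = effect[idx],
      vaf = if (!is.null(vafm)) as.numeric(vafm[idx, s]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(), sample_id = character(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      effect = character(), vaf = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$ref == res$alt)) stop("variant with ref == alt")
  res
}

#' Write small variants as a simple annotated VCF
#'
#' Emits a minimal VCF 4.2 with `GENE`/`EFFECT` INFO annotation and
#' `GT:VAF` per-sample fields, one column per tumor sample. This is the
#' companion writer of [read_small_variants()].
#'
#' @param snvs small-variant data.frame (0-based `pos`).
#' @param path output file.
#' @param sample_ids column order of the VCF genotype block.
#' @export
write_small_variants <- function(snvs, path, sample_ids = unique(snvs$sample_id)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  if (!nrow(snvs)) return(invisible(path))
  key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt, sep = ":")
  for (k in unique(key)) {
    rows <- snvs[key == k, , drop = FALSE]
    r1 <- rows[1, ]
    info <- sprintf("GENE=%s;EFFECT=%s",
                    ifelse(is.na(r1$gene), ".", r1$gene), r1$effect)
    cells <- vapply(sample_ids, function(s) {
      hit <- rows$sample_id == s
      if (any(hit)) sprintf("0/1:%.4f", rows$vaf[which(hit)[1]]) else "0/0:."
    }, character(1))
    writeLines(paste(c(r1$chrom, r1$pos + 1L, sub(":.*", "", r1$variant_id),
                       r1$ref, r1$alt, ".", "PASS", info, "GT:VAF", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---- karyotype / FISH event lists -----------------------------------------

#' Read a karyotype or FISH event list (cytoband resolution)
#'
#' TSV with header `event_id, sample_id, sv_type, chrom1, band1, chrom2,
#' band2` (band2/chrom2 may be `.` for one-locus events; `band = "*"`
#' denotes the whole chromosome). Band labels are expanded to genomic
#' intervals via the cytoband map; breakend orientations are unknown at
#' this resolution.
#'
#' @param path TSV file.
#' @param cytobands cytoband map from [read_cytobands()].
#' @param caller provenance label, `"KARYOTYPE"` or `"FISH"`.
#' @param contigs contig table.
#' @return SV-call data.frame with extra `band1`, `band2` columns.
#' @export
read_karyotype_events <- function(path, cytobands = read_cytobands(),
                                  caller = "KARYOTYPE",
                                  contigs = read_contigs()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("NA", "."))
  need <- c("event_id", "sample_id", "sv_type", "chrom1", "band1")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(raw)) {
    out <- empty_sv_calls(); out$band1 <- character(); out$band2 <- character()
    return(out)
  }
  check_contigs(raw$chrom1, contigs, path)
  span_of <- function(chrom, band) {
    if (is.na(band) || band == "*") {
      len <- contigs$length[contigs$chrom == chrom]
      list(start = 0L, end = len)
    } else band_interval(cytobands, chrom, band)
  }
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    if (r$sv_type == "inter_translocation") {
      s1 <- span_of(r$chrom1, r$band1)
      s2 <- span_of(r$chrom2, r$band2)
      sv_calls(call_id = r$event_id, sample_id = r$sample_id,
               sv_type = r$sv_type, chrom1 = r$chrom1,
               pos1 = floor((s1$start + s1$end) / 2), chrom2 = r$chrom2,
               pos2 = floor((s2$start + s2$end) / 2), callers = caller)
    } else {
      s1 <- span_of(r$chrom1, r$band1)
      e <- if (!is.na(r$band2) && nzchar(r$band2))
        span_of(r$chrom1, r$band2)$end else s1$end
      sv_calls(call_id = r$event_id, sample_id = r$sample_id,
               sv_type = r$sv_type, chrom1 = r$chrom1, pos1 = s1$start,
               pos2 = e, callers = caller)
    }
  })
  out <- do.call(rbind, rows)
  out$band1 <- raw$band1
  out$band2 <- ifelse(is.na(raw$band2), NA_character_, raw$band2)
  validate_sv_calls(out, contigs)
  out
}
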