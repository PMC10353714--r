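# Cross-platform verification of conventional-method calls by OGM.

#' Match conventional-platform reference calls against OGM calls
#'
#' Each reference call (SNP-array segment call, karyotype event, FISH
#' fusion) is matched to at most one OGM call. Array calls use
#' [match_calls()] with the OGM-array tolerance; karyotype and FISH events
#' match at cytoband resolution: an OGM call of compatible type class
#' whose span or breakends fall within the reference bands extended by
#' `karyotype_band_slop` neighboring bands. Matching is per sample and
#' stable under permutation of call order.
#'
#' @param reference SV-call data.frame with callers in
#'   `{ARRAY, KARYOTYPE, FISH}` (karyotype rows may carry `band1`/`band2`).
#' @param ogm SV-call data.frame with OGM provenance.
#' @param params matching tolerances.
#' @param cytobands cytoband map (needed for band-resolution events).
#' @return data.frame `ref_id, platform, sample_id, matched_ogm_id,
#'   verified, basis` with one row per reference call.
#' @export
match_platform <- function(reference, ogm, params = match_params(),
                           cytobands = read_cytobands()) {
  n <- nrow(reference)
  rec <- data.frame(ref_id = reference$call_id,
                    platform = caller_platform(reference$callers),
                    sample_id = reference$sample_id,
                    matched_ogm_id = NA_character_,
                    verified = FALSE, basis = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n || !nrow(ogm)) return(rec)
  used <- character(0)
  ord <- order(reference$sample_id, reference$chrom1,
               pmin(reference$pos1, reference$pos2), reference$call_id)
  for (i in ord) {
    r <- reference[i, ]
    cand <- ogm[ogm$sample_id == r$sample_id &
                  !(ogm$call_id %in% used), , drop = FALSE]
    if (!nrow(cand)) next
    if (rec$platform[i] %in% c("KARYOTYPE", "FISH")) {
      m <- match_band_level(r, cand, params, cytobands)
      basis <- "band"
    } else {
      pp <- match_pairs(r, cand, params)
      m <- if (nrow(pp)) cand$call_id[pp$j[which.max(pp$score)]] else NA
      basis <- "overlap"
    }
    if (!is.na(m)) {
      rec$matched_ogm_id[i] <- m
      rec$verified[i] <- TRUE
      rec$basis[i] <- basis
      used <- c(used, m)
    }
  }
  rec
}

# band-resolution matching: compatible type class and position(s) within the
# reference band interval(s) extended by `karyotype_band_slop` bands
match_band_level <- function(r, cand, params, cytobands) {
  slop <- params$karyotype_band_slop
  cls <- sv_type_class(r$sv_type)
  cand <- cand[sv_type_class(cand$sv_type) == cls, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  expand <- function(chrom, pos, band) {
    b <- if (!is.null(band) && !is.na(band) && nzchar(band) && band != "*") {
      band_interval(cytobands, chrom, band, slop = slop)
    } else {
      bl <- band_lookup(cytobands, chrom, pos)
      if (is.na(bl)) return(list(start = pos - 1e7, end = pos + 1e7))
      band_interval(cytobands, chrom, sub("^[0-9XY]+", "", bl), slop = slop)
    }
    b
  }
  if (cls == "inter") {
    b1 <- expand(r$chrom1, r$pos1, r[["band1"]])
    b2 <- expand(r$chrom2, r$pos2, r[["band2"]])
    ok <- (cand$chrom1 == r$chrom1 & cand$chrom2 == r$chrom2 &
             cand$pos1 >= b1$start & cand$pos1 < b1$end &
             cand$pos2 >= b2$start & cand$pos2 < b2$end) |
          (cand$chrom1 == r$chrom2 & cand$chrom2 == r$chrom1 &
             cand$pos1 >= b2$start & cand$pos1 < b2$end &
             cand$pos2 >= b1$start & cand$pos2 < b1$end)
  } else {
    b1 <- expand(r$chrom1, r$pos1, r[["band1"]])
    b2 <- if (!is.null(r[["band2"]]) && !is.na(r[["band2"]]) &&
              nzchar(r[["band2"]]))
      expand(r$chrom1, r$pos2, r[["band2"]]) else b1
    ok <- cand$chrom1 == r$chrom1 &
      cand$pos1 < b2$end & cand$pos2 > b1$start
  }
  if (!any(ok)) return(NA_character_)
  hit <- cand[ok, , drop = FALSE]
  hit$call_id[order(-hit$size_bp, hit$call_id)][1]
}

#' Per-platform and overall concordance rates
#'
#' Percentages are rounded half-up to the nearest integer, the reporting
#' convention of diagnostic concordance tables. Platforms without calls
#' are omitted; an all-empty input is an error.
#'
#' @param records from [match_platform()] (or any data.frame with
#'   `platform` and `verified` columns). Whether the overall denominator
#'   should count an event seen by several conventional platforms once or
#'   per platform is a reporting choice: pass raw records for the
#'   per-platform (raw) summary, or collapse them first with
#'   [dedupe_reference()] for the deduplicated one.
#' @return data.frame `platform, verified, total, percent` with a final
#'   `overall` row.
#' @export
concordance_rates <- function(records) {
  if (!nrow(records)) stop("no concordance records")
  platforms <- unique(records$platform)
  rows <- lapply(platforms, function(p) {
    r <- records[records$platform == p, ]
    data.frame(platform = p, verified = sum(r$verified), total = nrow(r))
  })
  out <- do.call(rbind, rows)
  out <- out[out$total > 0, , drop = FALSE]
  out <- rbind(out, data.frame(platform = "overall",
                               verified = sum(records$verified),
                               total = nrow(records)))
  out$percent <- as.integer(round_half_up(100 * out$verified / out$total))
  out
}

#' Collapse reference calls seen by several conventional platforms
#'
#' Reference calls from the same sample that describe the same event under
#' [match_calls()] (e.g. a large deletion reported by both karyotype and
#' array) are grouped single-linkage; one representative per group is kept,
#' preferring the platform with base-pair resolution (ARRAY over KARYOTYPE
#' over FISH).
#'
#' @param reference SV-call data.frame of conventional-platform calls.
#' @param params matching tolerances.
#' @return Subset of `reference` with one row per distinct event.
#' @export
dedupe_reference <- function(reference, params = match_params()) {
  if (nrow(reference) < 2) return(reference)
  pref <- match(caller_platform(reference$callers),
                c("ARRAY", "KARYOTYPE", "FISH"))
  grp <- seq_len(nrow(reference))
  for (s in unique(reference$sample_id)) {
    idx <- which(reference$sample_id == s)
    if (length(idx) < 2) next
    pp <- match_pairs(reference[idx, , drop = FALSE],
                      reference[idx, , drop = FALSE], params)
    pp <- pp[pp$i < pp$j, , drop = FALSE]
    for (k in seq_len(nrow(pp))) {
      a <- grp[idx[pp$i[k]]]; b <- grp[idx[pp$j[k]]]
      grp[grp == b] <- a
    }
  }
  keep <- vapply(split(seq_len(nrow(reference)), grp), function(m)
    m[order(pref[m], reference$call_id[m])][1], integer(1))
  out <- reference[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Size distributions by platform with detection-limit annotations
#'
#' Log-spaced size histograms of deletions and duplications per platform,
#' with per-platform counts above each platform's own detection limit and
#' the count of calls one platform sees below the other platform's limit
#' (the "cryptic" fraction).
#'
#' @param calls_by_platform named list of SV-call data.frames, e.g.
#'   `list(OGM = ..., CytoSNP12 = ...)`; names must appear in
#'   `config$detection_limits`.
#' @param config pipeline configuration.
#' @param breaks_per_decade histogram resolution.
#' @return List with `histogram` (platform, sv_type, bin_lo, bin_hi, count)
#'   and `summary` (platform, sv_type, n_total, n_above_own_limit, and
#'   `n_below_<other>` columns).
#' @export
size_histograms <- function(calls_by_platform, config = pipeline_config(),
                            breaks_per_decade = 4L) {
  platforms <- names(calls_by_platform)
  stopifnot(all(platforms %in% names(config$detection_limits)))
  breaks <- 10^seq(2, 8, by = 1 / breaks_per_decade)
  hists <- list(); summaries <- list()
  for (p in platforms) {
    calls <- calls_by_platform[[p]]
    for (tp in c("deletion", "duplication")) {
      sz <- calls$size_bp[calls$sv_type == tp]
      if (length(sz)) {
        b <- cut(sz, breaks = c(0, breaks, Inf), right = FALSE)
        cnt <- table(b)
        nz <- which(cnt > 0)
        hists[[paste(p, tp)]] <- data.frame(
          platform = p, sv_type = tp,
          bin_lo = c(0, breaks, Inf)[nz], bin_hi = c(breaks, Inf, Inf)[nz],
          count = as.integer(cnt[nz]))
      }
      srow <- data.frame(platform = p, sv_type = tp, n_total = length(sz),
                         n_above_own_limit =
                           sum(sz >= config$detection_limits[[p]]))
      for (q in platforms)
        srow[[paste0("n_below_", q)]] <-
          sum(sz < config$detection_limits[[q]])
      summaries[[paste(p, tp)]] <- srow
    }
  }
  list(histogram = if (length(hists)) do.call(rbind, hists) else
         data.frame(platform = character(), sv_type = character(),
                    bin_lo = numeric(), bin_hi = numeric(), count = integer()),
       summary = do.call(rbind, summaries))
}
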