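# Synthetic tumor/normal cohort with per-platform caller emulation.
#
# Cohort-level randomness (event placement, burdens, VAFs) uses R's RNG
# seeded once from the config. Caller emulation instead uses counter-based
# draws keyed by (event id, platform[, role]) hashed with the seed, so a
# germline event is jointly emitted or jointly dropped in tumor and matched
# normal under the same caller model, while breakpoint jitter still differs
# between the two assays.

# ---- deterministic keyed draws (FNV-1a 32-bit + Box-Muller) ---------------

fnv1a32 <- function(s) {
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- bitwXor_num(h, x)
    h <- mulmod32(h, 16777619)
  }
  h
}

# xor for non-negative doubles < 2^32 (bitwXor works on 31-bit ints)
bitwXor_num <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# (a * b) mod 2^32 without double-precision loss
mulmod32 <- function(a, b) {
  hi <- (a %/% 65536) * b %% 4294967296
  lo <- (a %% 65536) * b
  (hi * 65536 + lo) %% 4294967296
}

keyed_uniform <- function(key, seed) {
  (fnv1a32(paste0(key, "#", seed)) + 0.5) / 4294967296
}

keyed_normal <- function(key, seed, sd = 1) {
  u1 <- keyed_uniform(paste0(key, ":a"), seed)
  u2 <- keyed_uniform(paste0(key, ":b"), seed)
  sd * sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

# ---- subtype profiles ------------------------------------------------------

#' Default subtype profiles for the simulated cohort
#'
#' Encodes the statistical structure of the two emulated subtypes:
#' the ETV6::RUNX1 hallmark translocation in every tumor with a 9/30
#' three-way variant probability; hyperdiploid per-chromosome gain
#' patterns (tetrasomy 21 in 29/30 with one trisomic case, trisomy 14 in
#' 24/30 / tetrasomy 14 in 6/30, configurable gains elsewhere);
#' negative-binomial focal-deletion burdens with medians 13.5 and 4;
#' recurrent-gene panels with per-case hit probabilities (ETV6 0.27,
#' CDKN2A 0.23, PAX5 0.22, ...); and SNV/indel count distributions with
#' medians 18 and 13.5 and subtype-specific gene weights.
#'
#' @return Named list with `ETV6_RUNX1` and `HD` profiles.
#' @export
default_subtype_profiles <- function() {
  common_sv_panel <- c(ETV6 = 0.27, CDKN2A = 0.23, PAX5 = 0.22, NSD2 = 0.17,
                       RAG2 = 0.17, MKKS = 0.17, CD200 = 0.15, ZCCHC7 = 0.13,
                       STAG2 = 0.12, FOCAD = 0.08, IKBKB = 0.07, ZMYM1 = 0.05,
                       MANBA = 0.05, MSRA = 0.05, SFMBT2 = 0.05, IKZF1 = 0.03,
                       MBNL1 = 0.03)
  list(
    ETV6_RUNX1 = list(
      subtype = "ETV6_RUNX1",
      hallmark = "t12_21",
      p_three_way = 9 / 30,
      aneuploidy_gain = list(chr21 = list(p = 7 / 30, p_tetra = 0),
                             chr16 = list(p = 1 / 30, p_tetra = 0)),
      monosomy_x_prob = 1 / 30,
      focal_del_nb = c(size = 3, mu = 14.5),
      del_size = list(meanlog = log(40500), sdlog = 1.3,
                      min = 1000, max = 3600000),
      rates = c(insertion = 2.2, duplication = 0.35, inversion = 0.45,
                intra_translocation = 0.9, inter_translocation = 1.1),
      large = list(del_rate = 31 / 30, dup_rate = 13 / 30, p_12p = 0.35),
      cnnloh_whole_prob = 1 / 30, cnnloh_arm_prob = 0.05,
      sv_panel = c(common_sv_panel,
                   BTG1 = 0.33, ATF7IP = 0.30, UHRF1 = 0.17, UBA2 = 0.17,
                   GPRC5A = 0.17, NCOA6 = 0.13, MED13L = 0.10, MIB1 = 0.10),
      snv_nb = c(size = 1.3, mu = 22),
      snv_panel = c(NRAS = 0.07, NSD2 = 0.10, ETV6 = 0.09, UBA2 = 0.11,
                    CCDC168 = 0.11, STAG2 = 0.04, BTG1 = 0.05, MANBA = 0.03,
                    TBL1XR1 = 0.05),
      subclonal_frac = 0.15),
    HD = list(
      subtype = "HD",
      hallmark = "hyperdiploid",
      p_three_way = 0,
      aneuploidy_gain = list(chr21 = list(p = 1, p_tetra = 29 / 30),
                             chr14 = list(p = 1, p_tetra = 6 / 30),
                             chr4 = list(p = 0.8, p_tetra = 0.1),
                             chr6 = list(p = 0.8, p_tetra = 0.1),
                             chr10 = list(p = 0.8, p_tetra = 0.05),
                             chr17 = list(p = 0.8, p_tetra = 0.05),
                             chr18 = list(p = 0.75, p_tetra = 0.05),
                             chrX = list(p = 0.6, p_tetra = 0.05),
                             chr5 = list(p = 0.10, p_tetra = 0),
                             chr20 = list(p = 0.15, p_tetra = 0),
                             chr8 = list(p = 0.05, p_tetra = 0),
                             chr12 = list(p = 0.05, p_tetra = 0)),
      monosomy_x_prob = 0,
      focal_del_nb = c(size = 2.5, mu = 4.6),
      del_size = list(meanlog = log(40500), sdlog = 1.3,
                      min = 1000, max = 3600000),
      rates = c(insertion = 0.8, duplication = 0.2, inversion = 0.15,
                intra_translocation = 0.35, inter_translocation = 7 / 30),
      large = list(del_rate = 8 / 30, dup_rate = 20 / 30, p_12p = 0),
      cnnloh_whole_prob = 4 / 30, cnnloh_arm_prob = 0.05,
      sv_panel = common_sv_panel,
      snv_nb = c(size = 5, mu = 14.5),
      snv_panel = c(NRAS = 0.40, KRAS = 0.27, CREBBP = 0.20, FLT3 = 0.17,
                    PTPN11 = 0.10, NSD2 = 0.10, ETV6 = 0.09, STAG2 = 0.04,
                    MANBA = 0.03),
      subclonal_frac = 0.15)
  )
}

#' Default caller models for the emulated platforms
#'
#' Each model carries the platform detection limit, breakpoint noise,
#' a VAF sensitivity ramp (non-decreasing in VAF and size), blind regions
#' (centromeres for OGM; a low-probe-density IKZF1-like gap for the
#' arrays), and a false-call rate. The DN model additionally drops calls
#' below a de novo assembly VAF floor that the RVP model retains.
#'
#' @param blacklist blacklist regions (centromere rows blind the OGM
#'   models).
#' @return Named list of caller models.
#' @export
default_caller_models <- function(blacklist = read_blacklist()) {
  cen <- blacklist[blacklist$class == "centromere", , drop = FALSE]
  array_gap <- data.frame(chrom = "chr7", start = 50250000, end = 50450000)
  list(
    DN = list(platform = "OGM", label = "DN", kind = "sv",
              emits = c("deletion", "duplication", "insertion", "inversion",
                        "intra_translocation", "inter_translocation"),
              min_size = 500, jitter_sd = 3000, vaf_floor = 0.15,
              sens_max = 0.85, vaf_ramp = 0.25, blind = cen,
              false_rate = 0.1),
    RVP = list(platform = "OGM", label = "RVP", kind = "sv",
               emits = c("deletion", "duplication", "insertion", "inversion",
                         "intra_translocation", "inter_translocation"),
               min_size = 500, jitter_sd = 3000, vaf_floor = 0,
               sens_max = 0.98, vaf_ramp = 0.10, blind = cen,
               false_rate = 0.3),
    CN = list(platform = "OGM_CN", label = "CN", kind = "cn",
              emits = c("deletion", "duplication", "aneuploidy_gain",
                        "aneuploidy_loss"),
              min_size = 5000000, jitter_sd = 50000, vaf_floor = 0.1,
              sens_max = 0.97, vaf_ramp = 0.2, blind = cen[0, ],
              false_rate = 0),
    CytoSNP12 = list(platform = "CytoSNP12", label = "ARRAY", kind = "array",
                     emits = c("deletion", "duplication", "cnn_loh",
                               "aneuploidy_gain", "aneuploidy_loss"),
                     min_size = 50000, jitter_sd = 10000, vaf_floor = 0.10,
                     sens_max = 0.96, vaf_ramp = 0.22, blind = array_gap,
                     false_rate = 0, probe_spacing = 10300),
    CytoScanHD = list(platform = "CytoScanHD", label = "ARRAY", kind = "array",
                      emits = c("deletion", "duplication", "cnn_loh",
                                "aneuploidy_gain", "aneuploidy_loss"),
                      min_size = 1000, jitter_sd = 1000, vaf_floor = 0.10,
                      sens_max = 0.96, vaf_ramp = 0.22, blind = array_gap,
                      false_rate = 0, probe_spacing = 1160),
    KARYOTYPE = list(platform = "KARYOTYPE", label = "KARYOTYPE",
                     kind = "karyotype",
                     emits = c("deletion", "duplication", "inter_translocation",
                               "aneuploidy_gain", "aneuploidy_loss"),
                     min_size = 10000000, jitter_sd = 0, vaf_floor = 0.2,
                     sens_max = 0.9, vaf_ramp = 0.3, blind = cen[0, ],
                     false_rate = 0),
    FISH = list(platform = "FISH", label = "FISH", kind = "fish",
                emits = "inter_translocation",
                min_size = 0, jitter_sd = 0, vaf_floor = 0.05,
                sens_max = 1.0, vaf_ramp = 0.05, blind = cen[0, ],
                false_rate = 0)
  )
}

# emission probability; non-decreasing in vaf and size
caller_sensitivity <- function(model, vaf, size_bp, breakend = FALSE) {
  if (!breakend && size_bp < model$min_size) return(0)
  if (is.na(vaf)) vaf <- 0.5
  if (vaf < model$vaf_floor) return(0)
  model$sens_max * min(1, vaf / model$vaf_ramp)
}

overlaps_regions <- function(chrom, start, end, regions) {
  if (!nrow(regions)) return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i)
    any(regions$chrom == chrom[i] & regions$start < end[i] &
          regions$end > start[i]), logical(1))
}

# ---- truth construction ----------------------------------------------------

truth_event <- function(event_id, patient_id, origin, sv_type, chrom1, pos1,
                        chrom2 = chrom1, pos2, orient1 = "unknown",
                        orient2 = "unknown", size_bp = NA, vaf = NA,
                        hallmark = FALSE, gene = NA_character_,
                        cn = NA_integer_) {
  if (sv_type %in% SPAN_TYPES && sv_type != "insertion")
    size_bp <- pos2 - pos1
  if (sv_type == "inter_translocation") size_bp <- 0
  data.frame(event_id = event_id, patient_id = patient_id, origin = origin,
             sv_type = sv_type, chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
             pos2 = pos2, orient1 = orient1, orient2 = orient2,
             size_bp = size_bp, vaf = vaf, hallmark = hallmark, gene = gene,
             cn = cn, stringsAsFactors = FALSE)
}

# rejection-sample a span avoiding blacklist regions
random_span <- function(size, contigs, blacklist, exclude_chroms = "chrY") {
  ct <- contigs[!contigs$chrom %in% exclude_chroms, , drop = FALSE]
  for (i in 1:60) {
    ch <- sample(ct$chrom, 1, prob = ct$length)
    len <- ct$length[ct$chrom == ch]
    if (size >= len - 2e6) next
    s <- floor(stats::runif(1, 1e6, len - size - 1e6))
    if (!any(overlaps_regions(ch, s - 5e4, s + size + 5e4, blacklist)))
      return(list(chrom = ch, start = s, end = s + size))
  }
  stop("could not place event of size ", size)
}

clonal_vaf <- function(blast) max(0.05, min(0.6, blast / 2 +
                                              stats::runif(1, -0.03, 0.03)))

# somatic truth for one tumor
simulate_patient_somatic <- function(patient_id, profile, blast, annot) {
  ev <- list()
  eid <- 0L
  nid <- function() {
    eid <<- eid + 1L
    sprintf("%s_s%03d", patient_id, eid)
  }
  add <- function(e) ev[[length(ev) + 1L]] <<- e
  genes <- annot$models$genes
  subclonal_vaf <- function() {
    if (stats::runif(1) < profile$subclonal_frac)
      stats::runif(1, 0.05, 0.20) else clonal_vaf(blast)
  }
  # hallmark lesion(s)
  if (identical(profile$hallmark, "t12_21")) {
    etv6 <- genes[genes$symbol == "ETV6", ]
    runx1 <- genes[genes$symbol == "RUNX1", ]
    p1 <- floor(stats::runif(1, etv6$start + 1000, etv6$end - 1000))
    p2 <- floor(stats::runif(1, runx1$start + 1000, runx1$end - 1000))
    add(truth_event(nid(), patient_id, "somatic", "inter_translocation",
                    "chr12", p1, "chr21", p2, "left", "left",
                    vaf = clonal_vaf(blast), hallmark = TRUE))
    if (stats::runif(1) < profile$p_three_way) {
      third <- sample(setdiff(annot$contigs$chrom, c("chr12", "chr21", "chrY")), 1)
      len3 <- annot$contigs$length[annot$contigs$chrom == third]
      add(truth_event(nid(), patient_id, "somatic", "inter_translocation",
                      "chr21", p2 + 50000, third,
                      floor(stats::runif(1, 5e6, len3 - 5e6)),
                      "right", "left", vaf = clonal_vaf(blast),
                      hallmark = TRUE))
    }
  }
  # whole-chromosome gains / losses
  cn_states <- stats::setNames(rep(2L, nrow(annot$contigs)), annot$contigs$chrom)
  for (ch in names(profile$aneuploidy_gain)) {
    spec <- profile$aneuploidy_gain[[ch]]
    if (stats::runif(1) < spec$p) {
      cnv <- if (stats::runif(1) < spec$p_tetra) 4L else 3L
      len <- annot$contigs$length[annot$contigs$chrom == ch]
      add(truth_event(nid(), patient_id, "somatic", "aneuploidy_gain",
                      ch, 0, ch, len, vaf = clonal_vaf(blast),
                      hallmark = TRUE, cn = cnv))
      cn_states[ch] <- cnv
    }
  }
  if (stats::runif(1) < profile$monosomy_x_prob) {
    len <- annot$contigs$length[annot$contigs$chrom == "chrX"]
    add(truth_event(nid(), patient_id, "somatic", "aneuploidy_loss",
                    "chrX", 0, "chrX", len, vaf = clonal_vaf(blast),
                    hallmark = TRUE, cn = 1L))
    cn_states["chrX"] <- 1L
  }
  # whole-chromosome / arm-level CNN-LOH (array-visible only)
  if (stats::runif(1) < profile$cnnloh_whole_prob) {
    ch <- sample(c("chr1", "chr2", "chr9", "chrX"), 1)
    len <- annot$contigs$length[annot$contigs$chrom == ch]
    add(truth_event(nid(), patient_id, "somatic", "cnn_loh", ch, 0, ch, len,
                    vaf = clonal_vaf(blast), cn = 2L))
  }
  if (stats::runif(1) < profile$cnnloh_arm_prob) {
    cen9 <- annot$blacklist[annot$blacklist$name == "chr9_cen", ]
    if (stats::runif(1) < 0.5)
      add(truth_event(nid(), patient_id, "somatic", "cnn_loh", "chr9", 0,
                      "chr9", cen9$start, vaf = clonal_vaf(blast), cn = 2L))
    else
      add(truth_event(nid(), patient_id, "somatic", "cnn_loh", "chr9",
                      cen9$end, "chr9",
                      annot$contigs$length[annot$contigs$chrom == "chr9"],
                      vaf = clonal_vaf(blast), cn = 2L))
  }
  # focal deletions: recurrent-gene panel hits + background
  panel_hit <- names(profile$sv_panel)[
    stats::runif(length(profile$sv_panel)) < profile$sv_panel]
  for (sym in panel_hit) {
    gi <- genes[genes$symbol == sym, ]
    s <- gi$start - floor(stats::runif(1, 2000, 30000))
    e <- gi$end + floor(stats::runif(1, 2000, 30000))
    add(truth_event(nid(), patient_id, "somatic", "deletion", gi$chrom,
                    max(0, s), gi$chrom, e, vaf = subclonal_vaf(),
                    gene = sym))
  }
  n_del <- max(stats::rnbinom(1, size = profile$focal_del_nb["size"],
                              mu = profile$focal_del_nb["mu"]), 1L)
  n_bg <- max(0L, n_del - length(panel_hit))
  for (i in seq_len(n_bg)) {
    sz <- stats::rlnorm(1, profile$del_size$meanlog, profile$del_size$sdlog)
    sz <- floor(min(max(sz, profile$del_size$min), profile$del_size$max))
    sp <- random_span(sz, annot$contigs, annot$blacklist)
    add(truth_event(nid(), patient_id, "somatic", "deletion", sp$chrom,
                    sp$start, sp$chrom, sp$end, vaf = subclonal_vaf()))
  }
  # other focal SV types
  for (tp in names(profile$rates)) {
    n <- stats::rpois(1, profile$rates[[tp]])
    for (i in seq_len(n)) {
      vaf <- subclonal_vaf()
      if (tp == "insertion") {
        sp <- random_span(1, annot$contigs, annot$blacklist)
        e <- truth_event(nid(), patient_id, "somatic", "insertion", sp$chrom,
                         sp$start, sp$chrom, sp$start + 1, vaf = vaf)
        e$size_bp <- floor(stats::runif(1, 700, 5000))
        add(e)
      } else if (tp == "inter_translocation") {
        sp1 <- random_span(1, annot$contigs, annot$blacklist)
        repeat {
          sp2 <- random_span(1, annot$contigs, annot$blacklist)
          if (sp2$chrom != sp1$chrom) break
        }
        add(truth_event(nid(), patient_id, "somatic", "inter_translocation",
                        sp1$chrom, sp1$start, sp2$chrom, sp2$start,
                        sample(c("left", "right"), 1),
                        sample(c("left", "right"), 1), vaf = vaf))
      } else {
        sz <- floor(stats::rlnorm(1, log(120000), 1))
        sz <- min(max(sz, 30000), 4500000)
        sp <- random_span(sz, annot$contigs, annot$blacklist)
        add(truth_event(nid(), patient_id, "somatic", tp, sp$chrom, sp$start,
                        sp$chrom, sp$end, vaf = vaf))
      }
    }
  }
  # large (>= 5 Mb, sub-chromosomal) deletions and duplications
  for (tp in c("deletion", "duplication")) {
    rate <- if (tp == "deletion") profile$large$del_rate else profile$large$dup_rate
    n <- stats::rpois(1, rate)
    for (i in seq_len(n)) {
      if (tp == "deletion" && stats::runif(1) < profile$large$p_12p) {
        s <- floor(stats::runif(1, 0, 3e6))
        e <- s + floor(stats::runif(1, 12e6, 22e6))
        add(truth_event(nid(), patient_id, "somatic", "deletion", "chr12",
                        s, "chr12", min(e, 34000000),
                        vaf = clonal_vaf(blast)))
      } else {
        sz <- floor(stats::runif(1, 5.2e6, 3e7))
        sp <- random_span(sz, annot$contigs, annot$blacklist)
        add(truth_event(nid(), patient_id, "somatic", tp, sp$chrom, sp$start,
                        sp$chrom, sp$end, vaf = clonal_vaf(blast)))
      }
    }
  }
  list(events = do.call(rbind, ev), copy_states = cn_states)
}

simulate_patient_germline <- function(patient_id, annot, n_mean = 40) {
  n <- stats::rpois(1, n_mean)
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    tp <- sample(c("deletion", "insertion", "duplication", "inversion"), 1,
                 prob = c(0.5, 0.35, 0.1, 0.05))
    sz <- floor(min(max(stats::rlnorm(1, log(5000), 1.1), 600), 500000))
    sp <- random_span(max(sz, 1), annot$contigs, annot$blacklist)
    e <- truth_event(sprintf("%s_g%03d", patient_id, i), patient_id,
                     "germline", tp, sp$chrom, sp$start, sp$chrom,
                     if (tp == "insertion") sp$start + 1 else sp$start + sz,
                     vaf = 0.5)
    if (tp == "insertion") e$size_bp <- sz
    ev[[i]] <- e
  }
  if (!n) NULL else do.call(rbind, ev)
}

simulate_patient_snvs <- function(patient_id, profile, blast, annot) {
  genes <- annot$models$genes
  panel_hit <- names(profile$snv_panel)[
    stats::runif(length(profile$snv_panel)) < profile$snv_panel]
  n <- max(stats::rnbinom(1, size = profile$snv_nb["size"],
                          mu = profile$snv_nb["mu"]), 1L)
  n_bg <- max(0L, n - length(panel_hit))
  bases <- c("A", "C", "G", "T")
  mk <- function(i, sym) {
    if (!is.na(sym)) {
      gi <- genes[genes$symbol == sym, ]
      chrom <- gi$chrom
      pos <- floor(stats::runif(1, gi$start + 10, gi$end - 10))
    } else if (stats::runif(1) < 0.5) {
      gi <- genes[sample(nrow(genes), 1), ]
      sym <- gi$symbol
      chrom <- gi$chrom
      pos <- floor(stats::runif(1, gi$start + 10, gi$end - 10))
    } else {
      sp <- random_span(1, annot$contigs, annot$blacklist)
      chrom <- sp$chrom; pos <- sp$start
    }
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    effect <- sample(EFFECT_VOCAB, 1,
                     prob = c(0.6, 0.15, 0.08, 0.07, 0.05, 0.05))
    data.frame(variant_id = sprintf("%s_v%03d", patient_id, i),
               sample_id = paste0(patient_id, "_T"), chrom = chrom,
               pos = pos, ref = ref, alt = alt,
               gene = if (is.na(sym)) NA_character_ else sym,
               effect = effect,
               vaf = max(0.05, min(0.6, blast / 2 + stats::runif(1, -0.1, 0.05))),
               stringsAsFactors = FALSE)
  }
  out <- list()
  i <- 0L
  for (sym in panel_hit) { i <- i + 1L; out[[i]] <- mk(i, sym) }
  for (k in seq_len(n_bg)) { i <- i + 1L; out[[i]] <- mk(i, NA_character_) }
  do.call(rbind, out)
}

# ---- caller emulation ------------------------------------------------------

#' Emulate one platform's caller on a sample's truth events
#'
#' Events of types the platform does not call, events below its minimum
#' size, and events in its blind regions are dropped; the rest are emitted
#' with probability `sensitivity(vaf, size)` using a draw keyed by
#' (event id, platform) and the run seed, so tumor and matched normal emit
#' a shared germline event jointly. Detected breakpoints get Gaussian
#' jitter keyed by (event id, platform, role); for events smaller than
#' four times the jitter SD the jitter is scaled down so calls stay valid.
#' False calls (small deletions at random positions) are appended at the
#' model's false-call rate.
#'
#' @param events truth event data.frame for one sample.
#' @param model a caller model from [default_caller_models()].
#' @param seed integer run seed (also drives the keyed draws).
#' @param sample_id emitted sample id.
#' @param role `"tumor"` or `"normal"` (keys the jitter).
#' @param annot annotation bundle (contigs, cytobands, blacklist, models).
#' @return List with `calls` (SV-call or CN-segment data.frame, depending
#'   on the model kind), and `log` (event_id, emitted, reason).
#' @export
emulate_caller <- function(events, model, seed, sample_id, role, annot) {
  log <- data.frame(event_id = events$event_id,
                    emitted = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(events))
  reason <- rep(NA_character_, nrow(events))
  bad_type <- !events$sv_type %in% model$emits
  reason[bad_type] <- "type_not_called"
  span <- events$sv_type %in% SPAN_TYPES
  blind <- overlaps_regions(
    ifelse(span, events$chrom1, events$chrom1),
    ifelse(span, events$pos1, events$pos1),
    ifelse(span, events$pos2, events$pos1 + 1), model$blind) |
    (!span & overlaps_regions(events$chrom2, events$pos2,
                              events$pos2 + 1, model$blind))
  reason[is.na(reason) & blind] <- "blind_region"
  breakend <- events$sv_type == "inter_translocation"
  for (i in which(is.na(reason))) {
    sens <- caller_sensitivity(model, events$vaf[i], events$size_bp[i],
                               breakend[i])
    if (sens == 0) {
      reason[i] <- if (!breakend[i] && events$size_bp[i] < model$min_size)
        "below_min_size" else "below_vaf_floor"
      next
    }
    u <- keyed_uniform(paste0(events$event_id[i], "|", model$label,
                              "|", model$platform), seed)
    if (u >= sens) reason[i] <- "not_sampled"
  }
  emit <- is.na(reason)
  log$emitted <- emit
  log$reason <- ifelse(emit, "emitted", reason)
  ev <- events[emit, , drop = FALSE]
  if (model$kind %in% c("sv", "cn", "array")) {
    jit <- function(id, which) {
      keyed_normal(paste(id, model$platform, role, which, sep = "|"), seed)
    }
    calls <- ev
    if (nrow(ev)) {
      sdv <- pmin(model$jitter_sd, pmax(ev$size_bp, 1000) / 4)
      sdv[ev$sv_type == "insertion"] <- 50
      j1 <- vapply(seq_len(nrow(ev)), function(i)
        jit(ev$event_id[i], "p1") * sdv[i], numeric(1))
      j2 <- vapply(seq_len(nrow(ev)), function(i)
        jit(ev$event_id[i], "p2") * sdv[i], numeric(1))
      p1 <- pmax(0, round(ev$pos1 + j1))
      p2 <- round(ev$pos2 + j2)
      spn <- ev$sv_type %in% SPAN_TYPES
      swap <- spn & p2 <= p1
      tmp <- p1[swap]; p1[swap] <- pmin(tmp, p2[swap] - 1); p2[swap] <- pmax(tmp, p2[swap] + 1)
      # whole-chromosome events keep their exact bounds
      whole <- ev$sv_type %in% c("aneuploidy_gain", "aneuploidy_loss")
      p1[whole] <- ev$pos1[whole]; p2[whole] <- ev$pos2[whole]
      calls$pos1 <- p1; calls$pos2 <- p2
      sz <- ifelse(spn & ev$sv_type != "insertion", p2 - p1,
                   ifelse(ev$sv_type == "insertion",
                          pmax(500, round(ev$size_bp +
                            vapply(seq_len(nrow(ev)), function(i)
                              jit(ev$event_id[i], "sz") * 50, numeric(1)))),
                          0))
      calls$size_bp <- sz
    }
    # false calls
    nf <- 0L
    if (model$false_rate > 0) {
      uf <- keyed_uniform(paste("nfalse", sample_id, model$label, sep = "|"),
                          seed)
      nf <- stats::qpois(uf, model$false_rate)
    }
    false_rows <- NULL
    if (nf > 0) {
      fr <- lapply(seq_len(nf), function(k) {
        key <- paste("false", sample_id, model$label, k, sep = "|")
        ct <- annot$contigs[annot$contigs$chrom != "chrY", ]
        ch <- ct$chrom[1 + floor(keyed_uniform(paste0(key, ":c"), seed) *
                                   nrow(ct))]
        len <- ct$length[ct$chrom == ch]
        sz <- round(2000 + keyed_uniform(paste0(key, ":s"), seed) * 100000)
        s <- round(keyed_uniform(paste0(key, ":p"), seed) * (len - sz - 2e6)) + 1e6
        truth_event(paste0("FP_", sample_id, "_", model$label, "_", k),
                    sub("_[TN]$", "", sample_id), "false", "deletion",
                    ch, s, ch, s + sz, vaf = 0.3)
      })
      false_rows <- do.call(rbind, fr)
    }
    allrows <- rbind(calls, false_rows)
    if (model$kind == "sv") {
      if (is.null(allrows) || !nrow(allrows)) {
        out <- empty_sv_calls()
      } else {
        out <- sv_calls(call_id = paste0(allrows$event_id, "_", model$label),
                        sample_id = sample_id, sv_type = allrows$sv_type,
                        chrom1 = allrows$chrom1, pos1 = allrows$pos1,
                        chrom2 = allrows$chrom2, pos2 = allrows$pos2,
                        orient1 = allrows$orient1, orient2 = allrows$orient2,
                        size_bp = allrows$size_bp, vaf = allrows$vaf,
                        callers = model$label, hallmark = allrows$hallmark)
      }
    } else {
      if (is.null(allrows) || !nrow(allrows)) {
        out <- data.frame(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          state = character(), n_probes = integer(),
                          cn = integer(), platform = character())
      } else {
        state <- c(deletion = "loss", aneuploidy_loss = "loss",
                   duplication = "gain", aneuploidy_gain = "gain",
                   cnn_loh = "cnn_loh")[allrows$sv_type]
        n_probes <- if (model$kind == "array")
          pmax(1L, as.integer(round((allrows$pos2 - allrows$pos1) /
                                      model$probe_spacing)))
        else 0L
        out <- data.frame(sample_id = sample_id, chrom = allrows$chrom1,
                          start = allrows$pos1, end = allrows$pos2,
                          seg_id = allrows$event_id,
                          state = unname(state), n_probes = n_probes,
                          cn = ifelse(is.na(allrows$cn),
                                      ifelse(state == "loss", 1L,
                                             ifelse(state == "gain", 3L, 2L)),
                                      allrows$cn),
                          platform = model$platform)
      }
    }
    return(list(calls = out, log = log))
  }
  # band-resolution platforms: karyotype and FISH event lists
  if (model$kind == "fish" && nrow(ev)) ev <- ev[ev$hallmark, , drop = FALSE]
  if (!nrow(ev)) {
    out <- data.frame(event_id = character(), sample_id = character(),
                      sv_type = character(), chrom1 = character(),
                      band1 = character(), chrom2 = character(),
                      band2 = character())
    return(list(calls = out, log = log))
  }
  strip <- function(ch, b) sub("^[0-9XY]+", "", b)
  b1 <- band_lookup(annot$cytobands, ev$chrom1, pmax(ev$pos1, 1))
  span <- ev$sv_type %in% SPAN_TYPES
  b2pos <- ifelse(span, pmax(ev$pos2 - 1, 1), pmax(ev$pos2, 1))
  b2 <- band_lookup(annot$cytobands, ev$chrom2, b2pos)
  whole <- ev$sv_type %in% c("aneuploidy_gain", "aneuploidy_loss")
  out <- data.frame(event_id = paste0(ev$event_id, "_", model$label),
                    sample_id = sample_id, sv_type = ev$sv_type,
                    chrom1 = ev$chrom1,
                    band1 = ifelse(whole, "*", strip(ev$chrom1, b1)),
                    chrom2 = ifelse(span, NA_character_, ev$chrom2),
                    band2 = ifelse(whole, NA_character_,
                                   strip(ev$chrom2, b2)),
                    stringsAsFactors = FALSE)
  list(calls = out, log = log)
}

# ---- cohort driver ---------------------------------------------------------

#' Simulate a tumor/normal BCP-ALL cohort with caller emulation
#'
#' Generates `n_per_subtype` ETV6::RUNX1-like and hyperdiploid-like
#' patients (tumor plus matched normal each), draws germline and somatic
#' truth events and SNVs per patient, and runs every caller model on each
#' sample. Deterministic given `seed`. With `out_dir` the emitted call
#' files are written in the package's TSV/VCF dialects.
#'
#' @param n_per_subtype patients per subtype (>= 1).
#' @param seed integer seed for all randomness.
#' @param profiles subtype profiles, see [default_subtype_profiles()].
#' @param caller_models caller models, see [default_caller_models()].
#' @param annot annotation bundle from [load_annotation()].
#' @param out_dir optional output directory for the emitted files.
#' @param array_split fraction of patients assayed on the high-density
#'   array (the rest use the low-density array).
#' @return List with `samples`, `truth` (`events`, `snvs`, `copy_states`),
#'   `calls` (per sample per platform), `emission` (per platform log),
#'   and `files` when written.
#' @export
simulate_cohort <- function(n_per_subtype = 30L, seed = 1L,
                            profiles = default_subtype_profiles(),
                            caller_models = default_caller_models(),
                            annot = load_annotation(),
                            out_dir = NULL, array_split = 0.3) {
  if (n_per_subtype < 1) stop("n_per_subtype must be >= 1")
  set.seed(seed)
  patients <- list()
  k <- 0L
  for (st in names(profiles)) {
    for (i in seq_len(n_per_subtype)) {
      k <- k + 1L
      patients[[k]] <- list(patient_id = sprintf("SIM%03d", k),
                            subtype = st)
    }
  }
  samples <- do.call(rbind, lapply(patients, function(p) {
    data.frame(sample_id = paste0(p$patient_id, c("_T", "_N")),
               patient_id = p$patient_id, subtype = p$subtype,
               role = c("tumor", "normal"),
               blast_fraction = c(stats::runif(1, 0.70, 0.95), 0))
  }))
  # per-patient truth
  events <- list(); snvs <- list(); copy_states <- list()
  for (p in patients) {
    blast <- samples$blast_fraction[samples$patient_id == p$patient_id &
                                      samples$role == "tumor"]
    germ <- simulate_patient_germline(p$patient_id, annot)
    som <- simulate_patient_somatic(p$patient_id, profiles[[p$subtype]],
                                    blast, annot)
    events[[p$patient_id]] <- rbind(germ, som$events)
    copy_states[[p$patient_id]] <- som$copy_states
    snvs[[p$patient_id]] <- simulate_patient_snvs(p$patient_id,
                                                  profiles[[p$subtype]],
                                                  blast, annot)
  }
  truth <- list(events = do.call(rbind, events),
                snvs = do.call(rbind, snvs),
                copy_states = do.call(rbind, copy_states))
  rownames(truth$events) <- rownames(truth$snvs) <- NULL
  # caller emulation
  n_hd_array <- ceiling(array_split * length(patients))
  array_of <- function(pidx) if ((pidx - 1L) %% n_per_subtype <
                                   array_split * n_per_subtype)
    "CytoScanHD" else "CytoSNP12"
  calls <- list()
  emission <- list()
  for (pi in seq_along(patients)) {
    p <- patients[[pi]]
    pid <- p$patient_id
    pev <- truth$events[truth$events$patient_id == pid, , drop = FALSE]
    tum_ev <- pev
    nor_ev <- pev[pev$origin == "germline", , drop = FALSE]
    tid <- paste0(pid, "_T"); nid <- paste0(pid, "_N")
    sc <- list()
    for (m in c("DN", "RVP", "CN")) {
      rt <- emulate_caller(tum_ev, caller_models[[m]], seed, tid, "tumor",
                           annot)
      rn <- emulate_caller(nor_ev, caller_models[[m]], seed, nid, "normal",
                           annot)
      sc[[paste0(m, "_T")]] <- rt$calls
      sc[[paste0(m, "_N")]] <- rn$calls
      emission[[paste(pid, m, sep = "_")]] <-
        cbind(rt$log, platform = m, sample_id = tid)
    }
    am <- caller_models[[array_of(pi)]]
    ra <- emulate_caller(tum_ev, am, seed, tid, "tumor", annot)
    sc$ARRAY_T <- ra$calls
    emission[[paste(pid, "ARRAY", sep = "_")]] <-
      cbind(ra$log, platform = am$platform, sample_id = tid)
    rk <- emulate_caller(tum_ev, caller_models$KARYOTYPE, seed, tid, "tumor",
                         annot)
    sc$KARYOTYPE_T <- rk$calls
    rf <- emulate_caller(tum_ev, caller_models$FISH, seed, tid, "tumor",
                         annot)
    sc$FISH_T <- rf$calls
    calls[[pid]] <- sc
  }
  out <- list(samples = samples, truth = truth, calls = calls,
              emission = do.call(rbind, unname(emission)),
              seed = seed, array_of = vapply(seq_along(patients), array_of,
                                             character(1)))
  if (!is.null(out_dir)) out$files <- write_cohort(out, out_dir)
  out
}

# write the emitted call files in the package dialects
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  add(write_sample_sheet(sim$samples, file.path(out_dir, "samples.tsv")))
  for (pid in names(sim$calls)) {
    sc <- sim$calls[[pid]]
    for (nm in c("DN_T", "DN_N", "RVP_T", "RVP_N")) {
      f <- file.path(out_dir, sprintf("%s.%s.sv.tsv", pid, tolower(nm)))
      add(write_sv_table(sc[[nm]], f))
    }
    for (nm in c("CN_T", "CN_N", "ARRAY_T")) {
      f <- file.path(out_dir, sprintf("%s.%s.seg.tsv", pid, tolower(nm)))
      add(write_cn_segments(sc[[nm]], f))
    }
  }
  kar <- do.call(rbind, lapply(sim$calls, `[[`, "KARYOTYPE_T"))
  fish <- do.call(rbind, lapply(sim$calls, `[[`, "FISH_T"))
  utils::write.table(kar, file.path(out_dir, "karyotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fish, file.path(out_dir, "fish.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add(file.path(out_dir, c("karyotype.tsv", "fish.tsv")))
  add(write_small_variants(sim$truth$snvs, file.path(out_dir, "cohort.vcf"),
                           sample_ids = sim$samples$sample_id[
                             sim$samples$role == "tumor"]))
  tf <- file.path(out_dir, "truth_events.tsv")
  utils::write.table(sim$truth$events, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(tf)
  files
}

#' Load the bundled annotation set
#'
#' @param contigs,cytobands,genes,blacklist file paths (defaults: the
#'   bundled synthetic annotation fixtures).
#' @param promoter_bp promoter window for the gene models.
#' @return List with `contigs`, `cytobands`, `models`, `blacklist`.
#' @export
load_annotation <- function(contigs = leukosv_extdata("contigs"),
                            cytobands = leukosv_extdata("cytobands"),
                            genes = leukosv_extdata("genes"),
                            blacklist = leukosv_extdata("blacklist"),
                            promoter_bp = 2000L) {
  list(contigs = read_contigs(contigs),
       cytobands = read_cytobands(cytobands),
       models = read_gene_models(genes, promoter_bp = promoter_bp),
       blacklist = read_blacklist(blacklist))
}

#' Run merge, germline subtraction and filtering over a simulated cohort
#'
#' Convenience driver for the per-patient pipeline: merge DN/RVP/CN for
#' tumor and matched normal, subtract the normal callset, apply filters.
#'
#' @param sim from [simulate_cohort()].
#' @param config pipeline configuration.
#' @param params matching tolerances.
#' @return List with `somatic` (pass-filter somatic calls, cohort-wide),
#'   `audit` (removed/filtered calls with reasons), and `merged_tumor`
#'   (per-patient merged tumor callsets before subtraction).
#' @export
cohort_somatic <- function(sim, config = pipeline_config(),
                           params = match_params()) {
  annot_bl <- read_blacklist()
  contigs <- read_contigs()
  somatic <- list(); audit <- list(); merged_tumor <- list()
  for (pid in names(sim$calls)) {
    sc <- sim$calls[[pid]]
    mt <- merge_pipelines(sc$DN_T, sc$RVP_T, sc$CN_T, params, config, contigs)
    mn <- merge_pipelines(sc$DN_N, sc$RVP_N, sc$CN_N, params, config, contigs)
    sub <- subtract_germline(mt, mn, params)
    fl <- apply_filters(sub$somatic, config, annot_bl)
    somatic[[pid]] <- fl$kept
    merged_tumor[[pid]] <- mt
    removed <- sub$removed
    if (nrow(removed)) removed$filter_status <- "removed:germline_match"
    audit[[pid]] <- rbind(removed, fl$filtered)
  }
  list(somatic = do.call(rbind, unname(somatic)),
       audit = do.call(rbind, unname(audit)),
       merged_tumor = merged_tumor)
}
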