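#' Path to a bundled synthetic annotation fixture
#'
#' The package ships a small, internally consistent synthetic annotation set
#' on the GRCh38 primary contigs: contig lengths, a cytoband map in UCSC
#' cytoBand layout, gene models (BED12), and an exclusion blacklist
#' (IG/TR loci, centromeres, reference gaps).
#'
#' @param name one of `"contigs"`, `"cytobands"`, `"genes"`, `"blacklist"`.
#' @return File path.
#' @export
leukosv_extdata <- function(name = c("contigs", "cytobands", "genes", "blacklist")) {
  name <- match.arg(name)
  fn <- c(contigs = "contigs_grch38.tsv",
          cytobands = "cytobands_synthetic.tsv",
          genes = "genes_synthetic.bed",
          blacklist = "blacklist_synthetic.bed")[[name]]
  system.file("extdata", fn, package = "leukosv", mustWork = TRUE)
}

#' Read a contig-length table
#'
#' @param path two-column TSV (`chrom`, `length`) with a header.
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_contigs <- function(path = leukosv_extdata("contigs")) {
  ct <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  if (!all(c("chrom", "length") %in% names(ct)))
    stop("contig table needs columns chrom, length")
  if (any(ct$length <= 0)) stop("contig lengths must be positive")
  if (anyDuplicated(ct$chrom)) stop("duplicate contig names")
  ct
}

check_contigs <- function(chrom, contigs, what = "record") {
  bad <- setdiff(unique(chrom), contigs$chrom)
  if (length(bad))
    stop(sprintf("unknown contig(s) in %s: %s", what,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Read a cytoband map (UCSC cytoBand layout)
#'
#' Headerless TSV with columns chrom, start, end, band, stain; coordinates
#' 0-based half-open as in the UCSC table.
#'
#' @param path cytoband file.
#' @return data.frame `chrom`, `start`, `end`, `band`, `stain`.
#' @export
read_cytobands <- function(path = leukosv_extdata("cytobands")) {
  cb <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "band", "stain"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"))
  if (any(cb$start >= cb$end)) stop("cytoband with non-positive length")
  cb[order(cb$chrom, cb$start), ]
}

#' Look up the cytoband containing a position
#'
#' @param cytobands from [read_cytobands()].
#' @param chrom,pos contig and 0-based position.
#' @return Band label like `"12p13.1"` (NA when no band covers the position).
#' @export
band_lookup <- function(cytobands, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  vapply(seq_along(chrom), function(i) {
    hit <- cytobands$chrom == chrom[i] &
      cytobands$start <= pos[i] & cytobands$end > pos[i]
    if (!any(hit)) return(NA_character_)
    paste0(sub("^chr", "", chrom[i]), cytobands$band[which(hit)[1]])
  }, character(1))
}

#' Genomic span of a (possibly coarse) cytoband label
#'
#' A coarse label such as `"p13"` expands to the union of all of its
#' sub-bands (`p13.1`, `p13.2`, ...). `slop` extends the span by whole
#' neighboring bands on each side, which is how band-resolution karyotype
#' events are compared against bp-resolution calls.
#'
#' @param cytobands from [read_cytobands()].
#' @param chrom contig name.
#' @param band band label without the chromosome prefix, e.g. `"q22"`.
#' @param slop number of neighboring bands to add on each side.
#' @return Named list with `start`, `end` (0-based half-open).
#' @export
band_interval <- function(cytobands, chrom, band, slop = 0L) {
  cb <- cytobands[cytobands$chrom == chrom, , drop = FALSE]
  if (!nrow(cb)) stop("unknown contig in cytoband map: ", chrom)
  hit <- which(cb$band == band | startsWith(cb$band, paste0(band, ".")))
  if (!length(hit))
    stop(sprintf("band %s not found on %s", band, chrom))
  lo <- max(1L, min(hit) - as.integer(slop))
  hi <- min(nrow(cb), max(hit) + as.integer(slop))
  list(start = cb$start[lo], end = cb$end[hi])
}

#' Read an exclusion blacklist (BED with a class column)
#'
#' BED4+1: chrom, start, end, name, class with class in
#' `{IG_TR, centromere, gap}`. Coordinates are 0-based half-open (BED).
#' An empty file yields an empty region set.
#'
#' @param path blacklist BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`, `class`.
#' @export
read_blacklist <- function(path = leukosv_extdata("blacklist")) {
  cols <- c("chrom", "start", "end", "name", "class")
  if (file.size(path) == 0)
    return(stats::setNames(data.frame(character(), integer(), integer(),
                                      character(), character(),
                                      stringsAsFactors = FALSE), cols))
  bl <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = cols,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"))
  ok <- c("IG_TR", "centromere", "gap")
  if (any(!bl$class %in% ok))
    stop("blacklist class must be one of ", paste(ok, collapse = ", "))
  bl
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 is parsed with `rtracklayer`; exon blocks become the exon list.
#' GFF3 input must carry `gene` records with a `Name` (or `ID`) attribute
#' and `exon` children. The promoter is derived as a strand-aware window
#' upstream of the 5' gene end.
#'
#' @param path BED12 (`.bed`) or GFF3 (`.gff`/`.gff3`) file.
#' @param promoter_bp promoter window size in bp.
#' @return List of class `leukosv_genes` with elements `genes` (data.frame
#'   `symbol`, `chrom`, `start`, `end`, `strand`, `promoter_start`,
#'   `promoter_end`) and `exons` (data.frame `symbol`, `start`, `end`).
#' @export
read_gene_models <- function(path, promoter_bp = 2000L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gff <- rtracklayer::import(path, format = "gff3")
    gn <- gff[gff$type == "gene"]
    sym <- if (!is.null(gn$Name)) as.character(gn$Name) else as.character(gn$ID)
    genes <- data.frame(symbol = sym,
                        chrom = as.character(GenomicRanges::seqnames(gn)),
                        start = GenomicRanges::start(gn) - 1L,
                        end = GenomicRanges::end(gn),
                        strand = as.character(GenomicRanges::strand(gn)))
    ex <- gff[gff$type == "exon"]
    parent <- sub("^gene:", "", vapply(ex$Parent, function(p) p[1], character(1)))
    exons <- data.frame(symbol = parent,
                        start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(symbol = bed$name,
                        chrom = as.character(GenomicRanges::seqnames(bed)),
                        start = GenomicRanges::start(bed) - 1L,
                        end = GenomicRanges::end(bed),
                        strand = as.character(GenomicRanges::strand(bed)))
    blocks <- bed$blocks
    exons <- do.call(rbind, lapply(seq_along(bed), function(i) {
      b <- blocks[[i]]
      data.frame(symbol = bed$name[i],
                 start = genes$start[i] + IRanges::start(b) - 1L,
                 end = genes$start[i] + IRanges::end(b))
    }))
  }
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene models need explicit +/- strand")
  # validate exons: inside the span, sorted, non-overlapping
  for (s in unique(exons$symbol)) {
    gi <- genes[genes$symbol == s, ]
    ei <- exons[exons$symbol == s, ]
    ei <- ei[order(ei$start), ]
    if (any(ei$start < gi$start) || any(ei$end > gi$end))
      stop("exon outside gene span for ", s)
    if (nrow(ei) > 1 && any(ei$start[-1] < ei$end[-nrow(ei)]))
      stop("overlapping exons for ", s)
  }
  up <- genes$strand == "+"
  genes$promoter_start <- ifelse(up, pmax(0L, genes$start - promoter_bp), genes$end)
  genes$promoter_end <- ifelse(up, genes$start, genes$end + promoter_bp)
  structure(list(genes = genes, exons = exons[order(exons$symbol, exons$start), ]),
            class = "leukosv_genes")
}

# GRanges over gene bodies, optionally unioned with the promoter window
genes_granges <- function(models, include_promoter = TRUE) {
  g <- models$genes
  s <- if (include_promoter) pmin(g$start, g$promoter_start) else g$start
  e <- if (include_promoter) pmax(g$end, g$promoter_end) else g$end
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(s + 1L, e),
                         symbol = g$symbol, strand_chr = g$strand)
}

# GRanges from 0-based half-open columns of a data.frame
df_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(df[[chrom]],
                         IRanges::IRanges(df[[start]] + 1L, df[[end]]))
}
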