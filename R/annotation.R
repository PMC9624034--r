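# Probe manifest / lncRNA GTF ingestion and promoter-window annotation.
#
# All coordinates are 0-based half-open internally. GTF input is 1-based
# inclusive and converted on ingest; the probe manifest is declared 0-based
# (set `one_based = TRUE` in read_manifest() for 1-based extracts).

#' Read a CpG probe manifest
#'
#' Reads a 4-column TSV extract of an Illumina 450K-style manifest
#' (`probe_id`, `chrom`, `pos`, `strand`), one row per interrogated CpG.
#' `pos` is the genomic coordinate of the CpG's cytosine, 0-based by default.
#'
#' @param path path to a tab-separated file with a header line.
#' @param one_based set to `TRUE` if the extract stores 1-based coordinates;
#'   they are converted to the internal 0-based convention.
#' @return data.frame with columns `probe_id`, `chrom`, `pos` (integer,
#'   0-based), `strand`.
#' @export
read_manifest <- function(path, one_based = FALSE) {
  df <- read_tsv_checked(path, required = c("probe_id", "chrom", "pos", "strand"))
  if (nrow(df) == 0L) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num))
  if (length(bad)) {
    stop2("manifest %s: non-integer pos at row %d (value '%s')",
          path, bad[1], as.character(df$pos[bad[1]]))
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) {
    stop2("manifest %s: duplicated probe_id(s): %s", path,
          paste(unique(dup), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop2("manifest %s: strand must be '+' or '-'", path)
  }
  pos <- as.integer(pos_num) - if (one_based) 1L else 0L
  if (any(pos < 0L)) stop2("manifest %s: negative position after conversion", path)
  data.frame(probe_id = as.character(df$probe_id),
             chrom = as.character(df$chrom),
             pos = pos,
             strand = as.character(df$strand),
             stringsAsFactors = FALSE)
}

#' Read lncRNA transcripts from a GENCODE-style GTF
#'
#' Imports `transcript` features whose `gene_type` is in `biotypes` and
#' converts the 1-based inclusive GTF coordinates to 0-based half-open.
#' Reading is delegated to [rtracklayer::import()], so gzipped files work
#' transparently.
#'
#' @param path GTF file (GENCODE attribute dialect).
#' @param biotypes character vector of gene_type values to keep, e.g.
#'   `c("lincRNA", "antisense")`.
#' @return data.frame with columns `gene_id`, `transcript_id`, `gene_name`,
#'   `gene_type`, `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @export
read_gtf_lnc <- function(path,
                         biotypes = c("lincRNA", "antisense",
                                      "processed_transcript", "lncRNA")) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(md))) {
    stop2("GTF %s: missing gene_id/transcript_id attributes", path)
  }
  keep <- as.character(md$type) == "transcript"
  gtype <- if ("gene_type" %in% names(md)) as.character(md$gene_type)
           else rep(NA_character_, length(gr))
  keep <- keep & !is.na(gtype) & gtype %in% biotypes
  gr <- gr[keep]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop2("GTF %s: transcript with unknown strand '%s'", path,
          strand[!strand %in% c("+", "-")][1])
  }
  md <- S4Vectors::mcols(gr)
  out <- data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    gene_name = if ("gene_name" %in% names(md)) as.character(md$gene_name)
                else as.character(md$gene_id),
    gene_type = as.character(md$gene_type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build strand-aware promoter windows around transcript TSSs
#'
#' The promoter of a transcript is the window from `upstream` bp before to
#' `downstream` bp after its transcription start site, in the direction of
#' transcription. For a plus-strand transcript the TSS is `start`; for a
#' minus-strand transcript it is the last transcribed base, `end - 1`.
#' Windows are clipped at the chromosome origin.
#'
#' @param transcripts data.frame as returned by [read_gtf_lnc()].
#' @param upstream,downstream non-negative window extents in bp (defaults
#'   2500 upstream and 1000 downstream of the TSS).
#' @return data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `tss`.
#' @export
promoter_windows <- function(transcripts, upstream = 2500L, downstream = 1000L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0L || downstream < 0L) stop2("upstream/downstream must be >= 0")
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                names(transcripts)))
  if (any(transcripts$start >= transcripts$end)) {
    stop2("transcript with start >= end")
  }
  plus <- transcripts$strand == "+"
  tss <- ifelse(plus, transcripts$start, transcripts$end - 1L)
  # A window covers the genomic positions whose strand-relative offset from
  # the TSS lies in [-upstream, +downstream).
  w_start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  w_end <- ifelse(plus, tss + downstream, tss + upstream + 1L)
  w_start <- pmax(w_start, 0L)
  data.frame(
    gene_id = transcripts$gene_id,
    transcript_id = transcripts$transcript_id %||% transcripts$gene_id,
    chrom = transcripts$chrom,
    start = as.integer(w_start),
    end = as.integer(w_end),
    strand = transcripts$strand,
    tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
}

#' Join CpG probes to promoter windows
#'
#' Emits a (probe_id, gene_id) pair whenever a probe's CpG position falls
#' inside a promoter window on the same chromosome (half-open containment;
#' probe strand is ignored because a CpG is strand-symmetric). A probe may
#' map to several genes and vice versa. With `by = "gene"` (default) pairs
#' are deduplicated across a gene's transcripts, so multi-TSS genes union
#' their promoters; `by = "transcript"` keeps one row per transcript window.
#'
#' @param probes data.frame from [read_manifest()].
#' @param windows data.frame from [promoter_windows()].
#' @param by count pairs per `"gene"` or per `"transcript"`.
#' @return data.frame with columns `probe_id`, `gene_id` (plus
#'   `transcript_id` when `by = "transcript"`), sorted by (gene_id, probe_id).
#' @export
join_probes_to_promoters <- function(probes, windows,
                                     by = c("gene", "transcript")) {
  by <- match.arg(by)
  empty <- data.frame(probe_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(probes) == 0L || nrow(windows) == 0L) return(empty)
  pr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos + 1L, width = 1L))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pr, win, ignore.strand = TRUE)
  )
  if (length(hits) == 0L) return(empty)
  out <- data.frame(
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
    gene_id = windows$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  if (by == "transcript") {
    out$transcript_id <- windows$transcript_id[S4Vectors::subjectHits(hits)]
  }
  out <- unique(out)
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write promoter windows as BED6
#'
#' @param windows data.frame from [promoter_windows()].
#' @param path output file.
#' @export
write_promoters_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_id, 0L, windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
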