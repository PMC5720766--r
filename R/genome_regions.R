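#' @name genome_regions
#' @title Gene annotations and gene-anchored regions
#'
#' @description
#' Functions that turn a Gencode-style GTF into one record per gene (with the
#' outermost TSS/TTS over all transcripts), derive the three region types used
#' throughout the package (TSS flank, gene body, TTS flank), and remove
#' regions hitting a blacklist or excluded chromosomes.
#'
#' Coordinate conventions: GTF input is 1-based inclusive; everything internal
#' (and all BED/bedGraph I/O) is 0-based half-open. The conversion happens
#' once, at parse time. `tss` / `tts` are the 0-based coordinates of the TSS /
#' TTS base itself, stored in genomic coordinates together with the strand.
NULL

#' Parse a GTF into per-gene outermost TSS/TTS records
#'
#' Collapses all transcripts of each gene to a single record whose TSS is the
#' transcription-orientation-most-upstream transcript start (minimum genomic
#' start on `+`, maximum genomic end on `-`) and whose TTS is the symmetric
#' downstream extreme.
#'
#' @param gtf_path path to a GTF file with `transcript` records carrying
#'   `gene_id` and `gene_type` attributes.
#' @param gene_type which gene class to keep: `"protein_coding"` or
#'   `"lincRNA"`.
#' @return a `gene_annotation` data.frame with columns `gene_id`, `gene_type`,
#'   `chrom`, `strand`, `tss`, `tts` (0-based base coordinates).
#' @export
parse_gene_annotation <- function(gtf_path,
                                  gene_type = c("protein_coding", "lincRNA")) {
  gene_type <- match.arg(gene_type)
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) {
      stop("failed to parse GTF '", gtf_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id") %in% colnames(md))) {
    stop("GTF '", gtf_path, "' lacks type/gene_id attributes", call. = FALSE)
  }
  tx <- gr[md$type == "transcript"]
  if (length(tx) == 0L) {
    stop("GTF '", gtf_path, "' contains no transcript records", call. = FALSE)
  }
  txmd <- S4Vectors::mcols(tx)
  gtcol <- if ("gene_type" %in% colnames(txmd)) txmd$gene_type else
    txmd$gene_biotype
  if (is.null(gtcol)) {
    stop("GTF '", gtf_path, "' lacks a gene_type/gene_biotype attribute",
         call. = FALSE)
  }
  tx <- tx[!is.na(gtcol) & gtcol == gene_type]
  if (length(tx) == 0L) {
    stop("no transcripts with gene_type '", gene_type, "' in '", gtf_path,
         "'", call. = FALSE)
  }
  ids <- as.character(S4Vectors::mcols(tx)$gene_id)
  # outermost genomic extent over all transcripts of the gene
  gstart <- tapply(GenomicRanges::start(tx), ids, min)   # 1-based
  gend   <- tapply(GenomicRanges::end(tx), ids, max)     # 1-based
  chrom  <- tapply(as.character(GenomeInfoDb::seqnames(tx)), ids,
                   function(x) x[[1L]])
  strand <- tapply(as.character(GenomicRanges::strand(tx)), ids,
                   function(x) x[[1L]])
  if (any(!strand %in% c("+", "-"))) {
    stop("transcripts without +/- strand in '", gtf_path, "'", call. = FALSE)
  }
  gid <- names(gstart)
  plus <- strand[gid] == "+"
  # 0-based coordinate of the TSS/TTS base, transcription-oriented
  tss <- ifelse(plus, gstart[gid] - 1L, gend[gid] - 1L)
  tts <- ifelse(plus, gend[gid] - 1L, gstart[gid] - 1L)
  out <- data.frame(
    gene_id = gid,
    gene_type = gene_type,
    chrom = as.character(chrom[gid]),
    strand = as.character(strand[gid]),
    tss = as.integer(tss),
    tts = as.integer(tts),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_annotation", "data.frame")
  out
}

REGION_TYPES <- c("tss_flank", "gene_body", "tts_flank")

#' Derive gene-anchored regions
#'
#' Builds one region per gene of the requested type: `tss_flank` =
#' `[tss - flank, tss + flank)`, `gene_body` = `[min(tss, tts),
#' max(tss, tts))`, `tts_flank` = `[tts - flank, tts + flank)`. Regions
#' reaching past a chromosome edge keep their nominal coordinates but are
#' flagged `truncated`; out-of-range portions contribute zero signal
#' downstream, so gene counts never change silently.
#'
#' @param genes a `gene_annotation` data.frame from [parse_gene_annotation()].
#' @param region_type one of `"tss_flank"`, `"gene_body"`, `"tts_flank"`.
#' @param flank flank half-width in bp (default 2000).
#' @param n_bins 1, or 40 (40 only for `tss_flank`).
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   flag truncation at the right edge.
#' @return a `region_set` list with fields `region_type`, `flank`, `n_bins`
#'   and `entries` (gene_id, chrom, start, end, strand, truncated).
#' @export
derive_regions <- function(genes, region_type = REGION_TYPES, flank = 2000L,
                           n_bins = 1L, chrom_lengths = NULL) {
  region_type <- match.arg(region_type)
  stopifnot(n_bins %in% c(1L, 40L))
  if (n_bins == 40L && region_type != "tss_flank") {
    stop("40-bin resolution is only supported for tss_flank regions",
         call. = FALSE)
  }
  start <- switch(region_type,
    tss_flank = genes$tss - flank,
    gene_body = pmin(genes$tss, genes$tts),
    tts_flank = genes$tts - flank
  )
  end <- switch(region_type,
    tss_flank = genes$tss + flank,
    gene_body = pmax(genes$tss, genes$tts),
    tts_flank = genes$tts + flank
  )
  keep <- end > start
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) with zero-length ", region_type,
            " region dropped")
  }
  entries <- data.frame(
    gene_id = genes$gene_id[keep],
    chrom = genes$chrom[keep],
    start = as.integer(start[keep]),
    end = as.integer(end[keep]),
    strand = genes$strand[keep],
    stringsAsFactors = FALSE
  )
  trunc <- entries$start < 0L
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[entries$chrom])
    trunc <- trunc | (!is.na(len) & entries$end > len)
  }
  entries$truncated <- trunc
  structure(
    list(region_type = region_type, flank = as.integer(flank),
         n_bins = as.integer(n_bins), entries = entries),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", x$region_type, "|", nrow(x$entries), "regions |",
      x$n_bins, "bin(s)\n")
  invisible(x)
}

# Internal: region entries as GRanges (coordinates clipped to >= 0 for the
# container; clipped bp carry no signal so results are unchanged).
regions_as_granges <- function(entries) {
  GenomicRanges::GRanges(
    seqnames = entries$chrom,
    ranges = IRanges::IRanges(start = pmax(entries$start, 0L) + 1L,
                              end = pmax(entries$end, pmax(entries$start, 0L))),
    gene_id = entries$gene_id
  )
}

#' Remove blacklisted and excluded-chromosome regions
#'
#' Drops every region overlapping a blacklist interval by at least 1 bp and
#' every region on an excluded chromosome (typically the sex chromosomes).
#' The removed gene ids and reasons are attached as attribute `"removed"`.
#' Filtering is idempotent.
#'
#' @param regions a `region_set`.
#' @param blacklist an interval set: data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed3()]. May be `NULL`.
#' @param excluded_chroms character vector of chromosome names to drop,
#'   default `c("chrX", "chrY")`.
#' @return the filtered `region_set`.
#' @export
filter_regions <- function(regions, blacklist = NULL,
                           excluded_chroms = c("chrX", "chrY")) {
  entries <- regions$entries
  drop <- rep(FALSE, nrow(entries))
  reason <- rep(NA_character_, nrow(entries))
  on_excluded <- entries$chrom %in% excluded_chroms
  drop[on_excluded] <- TRUE
  reason[on_excluded] <- "excluded_chrom"
  if (!is.null(blacklist) && nrow(as.data.frame(blacklist)) > 0L) {
    bl <- as.data.frame(blacklist)
    stopifnot(all(c("chrom", "start", "end") %in% colnames(bl)),
              all(bl$end > bl$start), all(bl$start >= 0))
    blr <- GenomicRanges::GRanges(
      seqnames = bl$chrom,
      ranges = IRanges::IRanges(start = bl$start + 1L, end = bl$end)
    )
    hits <- GenomicRanges::findOverlaps(regions_as_granges(entries), blr,
                                        minoverlap = 1L)
    hit_idx <- unique(S4Vectors::queryHits(hits))
    newly <- setdiff(hit_idx, which(drop))
    drop[hit_idx] <- TRUE
    reason[newly] <- "blacklist"
  }
  removed <- data.frame(gene_id = entries$gene_id[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  regions$entries <- entries[!drop, , drop = FALSE]
  rownames(regions$entries) <- NULL
  attr(regions, "removed") <- removed
  regions
}

#' Read a BED3 file as a 0-based half-open interval table
#'
#' @param path path to a BED file (first three columns used).
#' @return data.frame with `chrom`, `start`, `end` columns.
#' @export
read_bed3 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a two-column chromosome sizes file
#'
#' @param path text file with chromosome name and length columns.
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2L]]), tab[[1L]])
}

# Internal: per-bin coordinates for a region_set. Bins are ordered in genomic
# coordinates (bin 1 = lowest coordinate) regardless of strand; each tss_flank
# bin has width 2*flank/n_bins. Returns a data.frame with one row per
# (gene, bin).
region_bin_table <- function(regions) {
  e <- regions$entries
  nb <- regions$n_bins
  n <- nrow(e)
  if (n == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), bin = integer()))
  }
  width <- e$end - e$start
  if (nb > 1L && any(width %% nb != 0L)) {
    stop("region width not divisible by n_bins", call. = FALSE)
  }
  bw <- width / nb
  idx <- rep(seq_len(n), each = nb)
  bin <- rep(seq_len(nb), times = n)
  start <- e$start[idx] + (bin - 1L) * bw[idx]
  data.frame(
    gene_id = e$gene_id[idx],
    chrom = e$chrom[idx],
    start = as.numeric(start),
    end = as.numeric(start + bw[idx]),
    bin = bin,
    stringsAsFactors = FALSE
  )
}
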