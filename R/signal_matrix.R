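#' @name signal_matrix
#' @title From signal tracks to enrichment matrices
#'
#' @description
#' Tag densities are counted per region/bin from bedGraph or wig tracks
#' ("tags" meaning track signal mass: value times covered bp, divided by the
#' bin width, so raw read-count tracks and pre-computed coverage tracks are
#' handled identically). DNA methylation is additionally normalized by CpG
#' content. Each mark's columns are then quantile-scaled into `[0, 1]` and
#' glued into one enrichment matrix per constellation (cell line, gene type,
#' region type).
NULL

#' Read a bedGraph or wig signal track
#'
#' @param path file path.
#' @param format `"bedGraph"` or `"wig"` (fixed or variable step).
#' @param mark_name,cell_line metadata attached to the track.
#' @param absolute take absolute values on read (signed strand-split
#'   coverage, e.g. minus-strand CAGE); default FALSE, where negative
#'   values are an error.
#' @return a `signal_track`: list with `mark_name`, `cell_line` and `runs`
#'   (data.frame `chrom`, `start`, `end`, `value`; 0-based half-open,
#'   non-overlapping, sorted within chromosome).
#' @export
read_signal_track <- function(path, format = c("bedGraph", "wig"),
                              mark_name = NA_character_,
                              cell_line = NA_character_,
                              absolute = FALSE) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  runs <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE
  )
  if (absolute) runs$value <- abs(runs$value)
  if (any(runs$value < 0)) {
    stop("negative signal values in '", path, "'", call. = FALSE)
  }
  ord <- order(runs$chrom, runs$start)
  if (is.unsorted(ord) && any(ord != seq_along(ord))) {
    warning("track '", path, "' was not sorted; sorting")
  }
  runs <- runs[ord, , drop = FALSE]
  # overlapping runs within a chromosome are ill-defined input
  same <- runs$chrom[-1L] == runs$chrom[-nrow(runs)]
  if (nrow(runs) > 1L && any(same & runs$start[-1L] < runs$end[-nrow(runs)])) {
    stop("overlapping runs in track '", path, "'", call. = FALSE)
  }
  rownames(runs) <- NULL
  structure(list(mark_name = mark_name, cell_line = cell_line, runs = runs),
            class = "signal_track")
}

#' Write a signal track as bedGraph
#'
#' @param track a `signal_track` or a runs data.frame
#'   (`chrom`, `start`, `end`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  runs <- if (inherits(track, "signal_track")) track$runs else track
  runs <- runs[runs$value != 0, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", runs$chrom, as.integer(runs$start),
                   as.integer(runs$end), fmt_num(runs$value, 10))
  writeLines(lines, path)
  invisible(path)
}

#' Count bin-size-normalized tag density per region and bin
#'
#' Each entry is the overlap-weighted signal mass in the bin divided by the
#' bin width: `sum(value * |run intersect bin|) / bin_width`. Gene-body bins
#' vary in width per gene; the division makes densities comparable. Regions on
#' chromosomes absent from the track yield zeros with a warning.
#'
#' @param track a `signal_track`.
#' @param regions a `region_set`.
#' @return numeric matrix, genes x n_bins, rownames = gene ids.
#' @export
count_region_bins <- function(track, regions) {
  bins <- region_bin_table(regions)
  genes <- regions$entries$gene_id
  out <- matrix(0, nrow = length(genes), ncol = regions$n_bins,
                dimnames = list(genes, NULL))
  if (nrow(bins) == 0L) return(out)
  runs <- track$runs
  missing_chr <- setdiff(unique(bins$chrom), unique(runs$chrom))
  if (length(missing_chr) > 0L) {
    warning("track '", track$mark_name, "' has no data for chromosome(s): ",
            paste(missing_chr, collapse = ", "), "; zeros returned")
  }
  runs <- runs[runs$value != 0, , drop = FALSE]
  if (nrow(runs) == 0L) return(out)
  bw <- bins$end - bins$start
  # clip bins at 0 for the container; clipped bp carry no signal
  bstart <- pmax(bins$start, 0)
  bend <- pmax(bins$end, bstart)
  ok <- bend > bstart
  bin_gr <- GenomicRanges::GRanges(
    seqnames = bins$chrom[ok],
    ranges = IRanges::IRanges(start = bstart[ok] + 1, end = bend[ok])
  )
  run_gr <- GenomicRanges::GRanges(
    seqnames = runs$chrom,
    ranges = IRanges::IRanges(start = runs$start + 1, end = runs$end)
  )
  hits <- GenomicRanges::findOverlaps(bin_gr, run_gr)
  if (length(hits) > 0L) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(bin_gr[qi],
                                                         run_gr[si]))
    mass <- ov * runs$value[si]
    bin_row <- which(ok)[qi]
    agg <- rowsum(mass, group = bin_row)
    rows <- as.integer(rownames(agg))
    dens <- agg[, 1L] / bw[rows]
    gene_idx <- match(bins$gene_id[rows], genes)
    out[cbind(gene_idx, bins$bin[rows])] <- as.numeric(dens)
  }
  out
}

#' Count CpG dinucleotides per region and bin
#'
#' A CpG is the forward-strand dinucleotide `CG`; it is assigned to the bin
#' containing its C. The genome may be given as sequences (FASTA /
#' `DNAStringSet`) or as a precomputed CpG position table.
#'
#' @param genome a named `Biostrings::DNAStringSet` (or path to a FASTA), or
#'   `NULL` when `cpg_bed` is given.
#' @param regions a `region_set`.
#' @param cpg_bed optional data.frame (`chrom`, `start`, `end`) of CpG
#'   positions, `start` = 0-based position of the C.
#' @return integer matrix, genes x n_bins.
#' @export
count_cpgs <- function(genome = NULL, regions, cpg_bed = NULL) {
  if (is.null(cpg_bed)) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    stopifnot(inherits(genome, "DNAStringSet"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    pos <- lapply(names(genome), function(chr) {
      m <- Biostrings::matchPattern("CG", genome[[chr]])
      Biostrings::start(m) - 1L  # 0-based position of the C
    })
    names(pos) <- names(genome)
  } else {
    pos <- split(as.integer(cpg_bed$start), cpg_bed$chrom)
  }
  bins <- region_bin_table(regions)
  genes <- regions$entries$gene_id
  out <- matrix(0L, nrow = length(genes), ncol = regions$n_bins,
                dimnames = list(genes, NULL))
  if (nrow(bins) == 0L) return(out)
  need <- setdiff(unique(bins$chrom), names(pos))
  if (is.null(cpg_bed) && length(need) > 0L) {
    stop("no sequence for chromosome(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (chr in intersect(unique(bins$chrom), names(pos))) {
    p <- sort(pos[[chr]])
    if (length(p) == 0L) next
    sel <- which(bins$chrom == chr)
    # count of positions in [start, end): C at the last base of a bin stays
    # in that bin even if the G spills into the next one
    n_in <- findInterval(bins$end[sel] - 1e-9, p) -
      findInterval(bins$start[sel] - 1e-9, p)
    gene_idx <- match(bins$gene_id[sel], genes)
    out[cbind(gene_idx, bins$bin[sel])] <- as.integer(n_in)
  }
  out
}

#' Normalize methylation density by CpG count
#'
#' Entrywise `meth / cpg` where the CpG count is positive, 0 by convention
#' where a bin contains no CpG (keeps the output bounded and scalable).
#'
#' @param meth,cpg matrices of identical shape (methylation density, CpG
#'   counts).
#' @return matrix of the same shape.
#' @export
normalize_methylation <- function(meth, cpg) {
  stopifnot(all(dim(meth) == dim(cpg)))
  out <- meth
  out[] <- ifelse(cpg > 0, meth / pmax(cpg, 1), 0)
  dimnames(out) <- dimnames(meth)
  out
}

#' Quantile-scale one mark's columns into [0, 1]
#'
#' Pools all of the mark's bins, takes the empirical `q` and `1 - q` quantiles
#' (R's default linear-interpolation quantile, type 7), maps everything at or
#' below the lower quantile to 0, at or above the upper quantile to 1, and
#' scales linearly in between. A constant mark cannot be scaled and becomes
#' all zeros with a warning.
#'
#' @param raw numeric matrix (genes x bins of one mark) or vector.
#' @param q clip fraction at each extreme, default 0.01 (0.05 supported as
#'   the alternative normalization).
#' @return object of the same shape with values in `[0, 1]`.
#' @export
quantile_scale <- function(raw, q = 0.01) {
  stopifnot(q > 0, q < 0.5)
  v <- as.numeric(raw)
  lo <- unname(quantile(v, q, type = 7, names = FALSE))
  hi <- unname(quantile(v, 1 - q, type = 7, names = FALSE))
  out <- raw
  if (hi <= lo) {
    warning("constant mark block: all values set to 0")
    out[] <- 0
  } else {
    out[] <- pmin(pmax((raw - lo) / (hi - lo), 0), 1)
  }
  out
}

# Column key for a mark metadata row: methylation flavors get distinct keys.
mark_key <- function(mark_name, methylation_flavor = "none") {
  ifelse(methylation_flavor == "none", mark_name,
         paste0(mark_name, ".", methylation_flavor))
}

#' Assemble scaled per-mark blocks into an enrichment matrix
#'
#' @param per_mark named list of scaled matrices (genes x n_bins each, equal
#'   rownames), names = mark keys in the order of `meta`.
#' @param meta data.frame with `mark_name`, `mark_type`,
#'   `methylation_flavor` (one row per column block; DNA methylation
#'   contributes two rows, `absolute` and `cpg_normalized`).
#' @param constellation list with `cell_line`, `gene_type`, `region_type`.
#' @return an `enrichment_matrix`: list with `values` (genes x (marks x
#'   bins)), `marks` (meta plus `key`), `n_bins`, `constellation`.
#' @export
assemble_matrix <- function(per_mark, meta, constellation) {
  stopifnot(is.list(per_mark), nrow(meta) == length(per_mark))
  meta$key <- mark_key(meta$mark_name, meta$methylation_flavor)
  if (!is.null(names(per_mark)) && !identical(names(per_mark), meta$key)) {
    per_mark <- per_mark[meta$key]
  }
  genes <- rownames(per_mark[[1L]])
  n_bins <- ncol(per_mark[[1L]])
  for (blk in per_mark) {
    if (!identical(rownames(blk), genes)) {
      stop("gene lists differ between mark blocks", call. = FALSE)
    }
    stopifnot(ncol(blk) == n_bins)
  }
  values <- do.call(cbind, per_mark)
  colnames(values) <- if (n_bins == 1L) meta$key else
    paste0(rep(meta$key, each = n_bins), ":", rep(seq_len(n_bins),
                                                  times = nrow(meta)))
  structure(
    list(values = values, marks = meta, n_bins = as.integer(n_bins),
         constellation = constellation),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cc <- x$constellation
  cat("enrichment_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "columns (", nrow(x$marks), "mark columns x", x$n_bins, "bins )\n")
  cat("  constellation:", cc$cell_line, "/", cc$gene_type, "/",
      cc$region_type, "\n")
  invisible(x)
}

# Column indices of one mark key inside an enrichment matrix.
mark_col_idx <- function(em, key) {
  i <- match(key, em$marks$key)
  if (is.na(i)) stop("mark '", key, "' not in matrix", call. = FALSE)
  (i - 1L) * em$n_bins + seq_len(em$n_bins)
}

#' Persist / load an enrichment matrix as TSV + JSON sidecar
#'
#' @param em an `enrichment_matrix`.
#' @param path base path; writes `<path>.tsv` (values) and `<path>.json`
#'   (mark metadata and constellation).
#' @return base path, invisibly.
#' @export
write_enrichment_matrix <- function(em, path) {
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE)
  write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- list(marks = em$marks, n_bins = em$n_bins,
               constellation = em$constellation)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_enrichment_matrix
#' @export
read_enrichment_matrix <- function(path) {
  tab <- read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene_id
  structure(
    list(values = values, marks = as.data.frame(side$marks),
         n_bins = as.integer(side$n_bins),
         constellation = as.list(side$constellation)),
    class = "enrichment_matrix"
  )
}
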