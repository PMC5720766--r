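#' @name world_files
#' @title World file emission and matrix construction
#'
#' @description
#' A generated world can be materialized on disk (GTF, per-mark bedGraph
#' tracks, CpG BED, blacklist BED, CAGE strand tracks, chromosome sizes,
#' optional synthetic FASTA) and pushed through the real file pipeline with
#' [build_enrichment_matrix()], or converted to enrichment matrices directly
#' in memory with [world_matrices()]. Track synthesis writes bin-constant
#' runs, so the overlap-weighted counter inverts the emission exactly and the
#' two routes agree to numerical precision.
NULL

METH_MARK <- "DNAme"

# GTF 1-based inclusive lines for one world
world_gtf_lines <- function(world) {
  g <- world$genes
  ntx <- g$n_transcripts
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gstart0 <- min(g$tss[i], g$tts[i])
    gend0 <- max(g$tss[i], g$tts[i]) + 1L
    attr_g <- sprintf('gene_id "%s"; gene_type "%s";', g$gene_id[i],
                      g$gene_type[i])
    lines <- c(lines, sprintf(
      "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom[i], gstart0 + 1L, gend0, g$strand[i], attr_g))
    for (t in seq_len(ntx[i])) {
      # first transcript spans the gene; later ones are nested so the
      # outermost TSS/TTS stay the gene bounds
      ts <- gstart0 + (t - 1L) * 100L
      te <- gend0 - (t - 1L) * 50L
      lines <- c(lines, sprintf(
        '%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s transcript_id "%s.t%d";',
        g$chrom[i], ts + 1L, te, g$strand[i], attr_g, g$gene_id[i], t))
    }
  }
  lines
}

# deterministic CpG positions: counts per bin spread evenly inside the bin
world_cpg_positions <- function(world) {
  g <- world$genes
  counts <- world$cpg
  rows <- list()
  for (i in seq_len(nrow(g))) {
    flank_start <- g$tss[i] - WORLD_FLANK
    for (b in seq_len(WORLD_NBINS)) {
      k <- counts[i, b]
      if (k == 0L) next
      bs <- flank_start + (b - 1L) * WORLD_BINW
      pos <- bs + floor((seq_len(k) - 0.5) * WORLD_BINW / k)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom[i], start = as.integer(pos),
        end = as.integer(pos + 2L), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# bedGraph runs for per-gene x bin densities over the TSS flanks
bin_density_runs <- function(world, dens, sign = 1) {
  g <- world$genes
  n <- nrow(g)
  flank_start <- g$tss - WORLD_FLANK
  idx <- rep(seq_len(n), each = WORLD_NBINS)
  bin <- rep(seq_len(WORLD_NBINS), times = n)
  start <- flank_start[idx] + (bin - 1L) * WORLD_BINW
  data.frame(
    chrom = g$chrom[idx],
    start = as.integer(start),
    end = as.integer(start + WORLD_BINW),
    value = sign * as.numeric(t(dens)),
    stringsAsFactors = FALSE
  )
}

write_world_files <- function(world, dir, write_fasta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world$config
  files <- list(dir = dir)
  files$gtf <- file.path(dir, "genes.gtf")
  writeLines(world_gtf_lines(world), files$gtf)
  files$chrom_sizes <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", names(world$chrom_lengths),
                     world$chrom_lengths), files$chrom_sizes)
  files$blacklist <- file.path(dir, "blacklist.bed")
  writeLines(sprintf("%s\t%d\t%d", world$blacklist$chrom,
                     world$blacklist$start, world$blacklist$end),
             files$blacklist)
  cpg_pos <- world_cpg_positions(world)
  files$cpg_bed <- file.path(dir, "cpg.bed")
  writeLines(sprintf("%s\t%d\t%d", cpg_pos$chrom, cpg_pos$start,
                     cpg_pos$end), files$cpg_bed)
  files$tracks <- list()
  for (cell in world$cell_lines) {
    cw <- world$cells[[cell]]
    files$tracks[[cell]] <- list()
    for (mk in names(cw$bins)) {
      p <- file.path(dir, sprintf("%s_%s.bedGraph", cell, mk))
      runs <- bin_density_runs(world, cw$bins[[mk]])
      writeLines(sprintf("%s\t%d\t%d\t%.17g", runs$chrom, runs$start,
                         runs$end, runs$value), p)
      files$tracks[[cell]][[mk]] <- p
    }
    if (!is.null(cw$meth)) {
      p <- file.path(dir, sprintf("%s_%s.bedGraph", cell, METH_MARK))
      runs <- bin_density_runs(world, cw$meth$dens)
      writeLines(sprintf("%s\t%d\t%d\t%.17g", runs$chrom, runs$start,
                         runs$end, runs$value), p)
      files$tracks[[cell]][[METH_MARK]] <- p
    }
    # CAGE: middle two bins only; minus strand written signed (negative), as
    # strand-split coverage files often are
    n <- cfg$n_genes
    g <- world$genes
    mk_cage <- function(cols, sign) {
      starts <- c(g$tss - WORLD_FLANK + 19L * WORLD_BINW,
                  g$tss - WORLD_FLANK + 20L * WORLD_BINW)
      data.frame(chrom = rep(g$chrom, 2L), start = as.integer(starts),
                 end = as.integer(starts + WORLD_BINW),
                 value = sign * as.numeric(cw$cage[, cols]),
                 stringsAsFactors = FALSE)
    }
    plus <- mk_cage(c("plus20", "plus21"), 1)
    minus <- mk_cage(c("minus20", "minus21"), -1)
    for (nm in c("plus", "minus")) {
      runs <- get(nm)
      runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
      runs <- runs[runs$value != 0, , drop = FALSE]
      p <- file.path(dir, sprintf("%s_cage_%s.bedGraph", cell, nm))
      writeLines(sprintf("%s\t%d\t%d\t%.17g", runs$chrom, runs$start,
                         runs$end, runs$value), p)
      files[[paste0("cage_", nm)]][[cell]] <- p
    }
  }
  if (write_fasta) {
    total <- sum(world$chrom_lengths)
    if (total > 5e6) {
      stop("FASTA emission is only supported for small worlds", call. = FALSE)
    }
    seqs <- lapply(names(world$chrom_lengths), function(chr) {
      x <- rep("A", world$chrom_lengths[[chr]])
      p <- cpg_pos[cpg_pos$chrom == chr, , drop = FALSE]
      x[p$start + 1L] <- "C"
      x[p$start + 2L] <- "G"
      paste(x, collapse = "")
    })
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- names(world$chrom_lengths)
    files$fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(dss, files$fasta)
  }
  files$truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(n_genes = cfg$n_genes, marks = cfg$marks,
         target_r = cfg$target_r, seed = cfg$seed,
         blacklist_genes = world$blacklist_genes),
    files$truth_json, auto_unbox = TRUE, digits = NA)
  files
}

# genes surviving the blacklist filter (the worlds have no sex chromosomes)
world_kept_genes <- function(world, filtered = TRUE) {
  if (filtered) setdiff(world$genes$gene_id, world$blacklist_genes)
  else world$genes$gene_id
}

#' Enrichment matrices straight from a world's planted densities
#'
#' Performs the same arithmetic as the file pipeline — per-bin densities,
#' CpG normalization for methylation, blacklist filtering, per-mark quantile
#' scaling, assembly — without the disk round trip. On worlds written to
#' disk, [build_enrichment_matrix()] over the emitted files reproduces this
#' result to numerical precision.
#'
#' @param world a `world`.
#' @param cell_line one of `world$cell_lines`.
#' @param n_bins 1 or 40.
#' @param q quantile-scaling clip fraction.
#' @param filtered drop blacklist-hit genes (default TRUE).
#' @return an `enrichment_matrix`.
#' @export
world_matrices <- function(world, cell_line = world$cell_lines[1L],
                           n_bins = 1L, q = 0.01, filtered = TRUE) {
  stopifnot(cell_line %in% world$cell_lines, n_bins %in% c(1L, 40L))
  cw <- world$cells[[cell_line]]
  keep <- world_kept_genes(world, filtered)
  shrink <- function(dens) {
    dens <- dens[keep, , drop = FALSE]
    if (n_bins == 1L) {
      matrix(rowMeans(dens), ncol = 1L, dimnames = list(keep, NULL))
    } else {
      dens
    }
  }
  marks <- world$config$marks
  meta <- data.frame(mark_name = marks$name, mark_type = marks$mark_type,
                     methylation_flavor = "none", stringsAsFactors = FALSE)
  blocks <- lapply(marks$name, function(mk)
    quantile_scale(shrink(cw$bins[[mk]]), q = q))
  if (!is.null(cw$meth)) {
    cpg_counts <- world$cpg[keep, , drop = FALSE]
    meth_dens <- cw$meth$dens[keep, , drop = FALSE]
    if (n_bins == 1L) {
      abs_raw <- matrix(rowMeans(meth_dens), ncol = 1L,
                        dimnames = list(keep, NULL))
      cpg_raw <- matrix(rowSums(cpg_counts), ncol = 1L,
                        dimnames = list(keep, NULL))
    } else {
      abs_raw <- meth_dens
      cpg_raw <- cpg_counts
    }
    norm_raw <- normalize_methylation(abs_raw, cpg_raw)
    meta <- rbind(meta, data.frame(
      mark_name = METH_MARK, mark_type = "epigenetic_mark",
      methylation_flavor = c("absolute", "cpg_normalized"),
      stringsAsFactors = FALSE))
    blocks <- c(blocks, list(quantile_scale(abs_raw, q = q),
                             quantile_scale(norm_raw, q = q)))
  }
  names(blocks) <- mark_key(meta$mark_name, meta$methylation_flavor)
  assemble_matrix(blocks, meta,
                  constellation = list(cell_line = cell_line,
                                       gene_type = "protein_coding",
                                       region_type = "tss_flank"))
}

#' Raw expression readout of a world
#'
#' @param world a `world`.
#' @param cell_line cell line name.
#' @param filtered restrict to blacklist-surviving genes.
#' @return named numeric vector of raw GEx values.
#' @export
world_raw_gex <- function(world, cell_line = world$cell_lines[1L],
                          filtered = TRUE) {
  keep <- world_kept_genes(world, filtered)
  gex <- world$cells[[cell_line]]$expression$raw_gex
  setNames(gex, world$genes$gene_id)[keep]
}

#' Build an enrichment matrix from files (the full pipeline)
#'
#' Parses the annotation, derives and filters the regions, counts every
#' track, CpG-normalizes methylation, quantile-scales per mark, and
#' assembles the constellation matrix.
#'
#' @param gtf_path gene annotation (GTF).
#' @param manifest data.frame with columns `mark_name`, `mark_type`, `path`,
#'   and optionally `format` (default bedGraph) and `is_methylation`
#'   (logical; that track gets the absolute + CpG-normalized column pair).
#' @param cell_line,gene_type,region_type the constellation.
#' @param n_bins 1 or 40 (40 only for `tss_flank`).
#' @param flank flank half-width, default 2000.
#' @param q quantile clip fraction, default 0.01.
#' @param blacklist_path optional blacklist BED.
#' @param excluded_chroms chromosomes to drop, default sex chromosomes.
#' @param chrom_sizes_path optional chromosome sizes file (truncation flags).
#' @param cpg_bed_path,genome_fasta CpG source for methylation
#'   normalization (one of the two required when the manifest contains a
#'   methylation track).
#' @return an `enrichment_matrix`.
#' @export
build_enrichment_matrix <- function(gtf_path, manifest, cell_line,
                                    gene_type = "protein_coding",
                                    region_type = "tss_flank",
                                    n_bins = 1L, flank = 2000L, q = 0.01,
                                    blacklist_path = NULL,
                                    excluded_chroms = c("chrX", "chrY"),
                                    chrom_sizes_path = NULL,
                                    cpg_bed_path = NULL,
                                    genome_fasta = NULL) {
  stopifnot(all(c("mark_name", "mark_type", "path") %in% colnames(manifest)))
  if (is.null(manifest$format)) manifest$format <- "bedGraph"
  if (is.null(manifest$is_methylation)) manifest$is_methylation <- FALSE
  genes <- parse_gene_annotation(gtf_path, gene_type)
  chrom_lengths <- if (!is.null(chrom_sizes_path)) {
    read_chrom_sizes(chrom_sizes_path)
  } else NULL
  regions <- derive_regions(genes, region_type, flank = flank,
                            n_bins = n_bins, chrom_lengths = chrom_lengths)
  blacklist <- if (!is.null(blacklist_path)) read_bed3(blacklist_path)
  else NULL
  regions <- filter_regions(regions, blacklist, excluded_chroms)
  cpg_counts <- NULL
  if (any(manifest$is_methylation)) {
    if (is.null(cpg_bed_path) && is.null(genome_fasta)) {
      stop("methylation track needs cpg_bed_path or genome_fasta",
           call. = FALSE)
    }
    cpg_counts <- if (!is.null(cpg_bed_path)) {
      count_cpgs(regions = regions, cpg_bed = read_bed3(cpg_bed_path))
    } else {
      count_cpgs(genome = genome_fasta, regions = regions)
    }
  }
  meta_rows <- list()
  blocks <- list()
  for (i in seq_len(nrow(manifest))) {
    mk <- manifest$mark_name[i]
    track <- read_signal_track(manifest$path[i], format = manifest$format[i],
                               mark_name = mk, cell_line = cell_line)
    raw <- count_region_bins(track, regions)
    if (isTRUE(manifest$is_methylation[i])) {
      norm <- normalize_methylation(raw, cpg_counts)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        mark_name = mk, mark_type = manifest$mark_type[i],
        methylation_flavor = "absolute", stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- quantile_scale(raw, q = q)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        mark_name = mk, mark_type = manifest$mark_type[i],
        methylation_flavor = "cpg_normalized", stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- quantile_scale(norm, q = q)
    } else {
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        mark_name = mk, mark_type = manifest$mark_type[i],
        methylation_flavor = "none", stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- quantile_scale(raw, q = q)
    }
  }
  meta <- do.call(rbind, meta_rows)
  names(blocks) <- mark_key(meta$mark_name, meta$methylation_flavor)
  assemble_matrix(blocks, meta,
                  constellation = list(cell_line = cell_line,
                                       gene_type = gene_type,
                                       region_type = region_type))
}
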