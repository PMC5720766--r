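# Shared fixtures: small worlds are expensive enough to build once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small world written to disk, with methylation, used by the pipeline and
# region tests.
small_disk_world <- function() {
  cached("small_disk_world", function() {
    dir <- file.path(tempdir(), "epc_small_world")
    cfg <- world_config(
      n_genes = 60, marks = default_marks(4), genes_per_chrom = 30,
      include_methylation = TRUE,
      expression = list(link = "linear", n_marks = 3, target_r = 0.9,
                        knot = 0.25, zero_fraction = 0),
      seed = 5
    )
    w <- generate_world(cfg, dir = dir, write_fasta = TRUE)
    w
  })
}

world_manifest <- function(w, cell = "cellA") {
  f <- w$files
  marks <- w$config$marks
  has_meth <- !is.null(w$cells[[cell]]$meth)
  nm <- names(f$tracks[[cell]])
  data.frame(
    mark_name = nm,
    mark_type = c(marks$mark_type, if (has_meth) "epigenetic_mark"),
    path = unlist(f$tracks[[cell]], use.names = FALSE),
    is_methylation = nm == "DNAme",
    stringsAsFactors = FALSE
  )
}

# Build a 1-bin enrichment_matrix directly from a genes x marks value matrix
# (for model-level tests that do not need the track machinery).
make_em <- function(values, mark_types = NULL, cell_line = "cellT",
                    meth_mark = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  }
  nm <- colnames(values)
  if (is.null(mark_types)) {
    mark_types <- rep(c("epigenetic_mark", "transcription_factor"),
                      length.out = ncol(values))
  }
  flav <- rep("none", ncol(values))
  if (!is.null(meth_mark)) {
    # meth_mark: name appearing twice in values as <name>.absolute /
    # <name>.cpg_normalized columns
    flav[nm == paste0(meth_mark, ".absolute")] <- "absolute"
    flav[nm == paste0(meth_mark, ".cpg_normalized")] <- "cpg_normalized"
    nm[flav != "none"] <- meth_mark
  }
  meta <- data.frame(mark_name = nm, mark_type = mark_types,
                     methylation_flavor = flav, stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(ncol(values)), function(j)
    matrix(values[, j], ncol = 1L, dimnames = list(rownames(values), NULL)))
  names(blocks) <- epicompress:::mark_key(meta$mark_name,
                                          meta$methylation_flavor)
  assemble_matrix(blocks, meta,
                  constellation = list(cell_line = cell_line,
                                       gene_type = "protein_coding",
                                       region_type = "tss_flank"))
}

# A tiny gene annotation for region-geometry tests.
toy_genes <- function() {
  structure(
    data.frame(
      gene_id = c("gA", "gB", "gC"),
      gene_type = "protein_coding",
      chrom = c("chr1", "chr1", "chrX"),
      strand = c("+", "-", "+"),
      tss = c(10000L, 25000L, 7000L),
      tts = c(14000L, 21000L, 9000L),
      stringsAsFactors = FALSE
    ),
    class = c("gene_annotation", "data.frame")
  )
}
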