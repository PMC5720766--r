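test_that("bedGraph and wig tracks load as 0-based runs", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t2.0", bg)
  tr <- read_signal_track(bg, "bedGraph")
  expect_equal(tr$runs,
               data.frame(chrom = "chr1", start = 0L, end = 100L, value = 2,
                          stringsAsFactors = FALSE))
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=100 span=100",
               "1.5", "2.5", "3.5"), wig)
  tw <- read_signal_track(wig, "wig")
  expect_equal(tw$runs$start, c(0L, 100L, 200L))
  expect_equal(tw$runs$end, c(100L, 200L, 300L))
  expect_equal(tw$runs$value, c(1.5, 2.5, 3.5))
  # negative values are an error unless magnitudes are requested
  neg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t-2.0", neg)
  expect_error(read_signal_track(neg, "bedGraph"), "negative")
  expect_equal(read_signal_track(neg, "bedGraph", absolute = TRUE)$runs$value,
               2)
})

test_that("tracks round-trip through write_bedgraph", {
  runs <- data.frame(chrom = "chr1",
                     start = c(0L, 250L, 1000L),
                     end = c(100L, 300L, 1500L),
                     value = c(0.125, 3.75, 1 / 3))
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(runs, p)
  back <- read_signal_track(p, "bedGraph")
  expect_equal(back$runs$start, runs$start)
  expect_equal(back$runs$end, runs$end)
  expect_equal(back$runs$value, runs$value, tolerance = 1e-9)
})

test_that("bin counting is overlap-weighted, bin-size normalized", {
  g <- toy_genes()[1, ] # tss 10000, region [8000, 12000)
  r40 <- derive_regions(g, "tss_flank", n_bins = 40)
  # uniform value 1 over the whole region: every bin density 1
  tr <- structure(list(mark_name = "u", cell_line = "c",
                       runs = data.frame(chrom = "chr1", start = 8000L,
                                         end = 12000L, value = 1)),
                  class = "signal_track")
  m <- count_region_bins(tr, r40)
  expect_equal(as.numeric(m), rep(1, 40))
  # value 5 covering exactly bin 20 ([9900,10000))
  tr2 <- structure(list(mark_name = "b20", cell_line = "c",
                        runs = data.frame(chrom = "chr1", start = 9900L,
                                          end = 10000L, value = 5)),
                   class = "signal_track")
  m2 <- count_region_bins(tr2, r40)
  expect_equal(unname(m2[1, 20]), 5)
  expect_equal(sum(m2), 5)
  # missing chromosome: zeros with warning
  g2 <- g
  g2$chrom <- "chr7"
  suppressWarnings(
    expect_warning(mz <- count_region_bins(tr, derive_regions(g2, "tss_flank",
                                                              n_bins = 40)),
                   "no data"))
  expect_equal(sum(mz), 0)
})

test_that("bin counting matches a per-base brute-force oracle", {
  set.seed(42)
  g <- toy_genes()[1:2, ]
  r40 <- derive_regions(g, "tss_flank", n_bins = 40)
  # random sparse runs straddling bin boundaries
  starts <- sort(sample(7900:26000, 60))
  runs <- data.frame(chrom = "chr1", start = starts,
                     end = starts + sample(5:450, 60, replace = TRUE),
                     value = round(runif(60, 0, 4), 3))
  runs <- runs[c(TRUE, diff(runs$start) > 460), ] # keep non-overlapping
  tr <- structure(list(mark_name = "r", cell_line = "c", runs = runs),
                  class = "signal_track")
  m <- count_region_bins(tr, r40)
  # oracle: literal per-base accumulation
  base_val <- numeric(30000)
  for (i in seq_len(nrow(runs))) {
    base_val[(runs$start[i] + 1):runs$end[i]] <-
      base_val[(runs$start[i] + 1):runs$end[i]] + runs$value[i]
  }
  for (gi in 1:2) {
    st <- g$tss[gi] - 2000
    for (b in 1:40) {
      expect_equal(unname(m[gi, b]),
                   sum(base_val[(st + (b - 1) * 100 + 1):(st + b * 100)]) /
                     100,
                   tolerance = 1e-9)
    }
  }
})

test_that("CpG counting: dimer definition, boundary assignment, oracle", {
  fa <- tempfile(fileext = ".fa")
  # CpGs at 0-based positions 1, 3 ("ACGCGT") then padding
  writeLines(c(">chrT", paste0("ACGCGT", strrep("A", 194))), fa)
  g <- structure(data.frame(gene_id = "t", gene_type = "protein_coding",
                            chrom = "chrT", strand = "+", tss = 3L, tts = 150L,
                            stringsAsFactors = FALSE),
                 class = c("gene_annotation", "data.frame"))
  r1 <- derive_regions(g, "gene_body", n_bins = 1)
  cc <- count_cpgs(genome = fa, regions = r1)
  expect_equal(as.integer(cc), 1L) # only the CpG whose C is at pos 3
  # C on the last base of a bin stays in that bin
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">chrT", paste0(strrep("A", 99), "CG", strrep("A", 3899))),
             fa2)
  g2 <- structure(data.frame(gene_id = "t", gene_type = "protein_coding",
                             chrom = "chrT", strand = "+", tss = 2000L,
                             tts = 3000L, stringsAsFactors = FALSE),
                  class = c("gene_annotation", "data.frame"))
  r40 <- derive_regions(g2, "tss_flank", n_bins = 40)
  cc2 <- count_cpgs(genome = fa2, regions = r40)
  expect_equal(unname(cc2[1, 1]), 1L) # C at 0-based 99 = last base of bin 1
  expect_equal(sum(cc2), 1L)
  # regex oracle on the generator genome
  w <- small_disk_world()
  regions <- derive_regions(
    structure(w$genes, class = c("gene_annotation", "data.frame")),
    "tss_flank", n_bins = 40)
  counted <- count_cpgs(genome = w$files$fasta, regions = regions)
  seqs <- Biostrings::readDNAStringSet(w$files$fasta)
  for (gi in c(1, 17, 42)) {
    chr <- as.character(seqs[[w$genes$chrom[gi]]])
    st <- w$genes$tss[gi] - 2000
    # regex oracle: 0-based positions of the C of every CG dimer
    hits <- gregexpr("CG", chr, fixed = TRUE)[[1]]
    hits <- hits[hits != -1] - 1
    oracle <- vapply(1:40, function(b)
      sum(hits >= st + (b - 1) * 100 & hits < st + b * 100), numeric(1))
    expect_equal(as.numeric(counted[w$genes$gene_id[gi], ]), oracle)
  }
})

test_that("methylation normalization and the degenerate CpG-zero rule", {
  meth <- matrix(c(4, 0, 2), 1)
  cpg <- matrix(c(8, 0, 0), 1)
  out <- normalize_methylation(meth, cpg)
  expect_equal(as.numeric(out), c(0.5, 0, 0))
})

test_that("quantile scaling clips at the documented type-7 quantiles", {
  x <- matrix(0:99, ncol = 1)
  sc <- quantile_scale(x, q = 0.01)
  lo <- unname(quantile(0:99, 0.01, type = 7)) # 0.99
  hi <- unname(quantile(0:99, 0.99, type = 7)) # 98.01
  expect_equal(sc[1, 1], 0)   # 0 below lo
  expect_equal(sc[100, 1], 1) # 99 above hi
  expect_equal(sc[50, 1], (49 - lo) / (hi - lo), tolerance = 1e-12)
  expect_equal(range(sc), c(0, 1))
  # rank order preserved
  set.seed(1)
  y <- matrix(rexp(500), ncol = 5)
  sy <- quantile_scale(y, 0.05)
  # monotone: sorting by raw value sorts the scaled values (ties from clipping)
  expect_true(all(diff(as.numeric(sy)[order(as.numeric(y))]) >= 0))
  expect_true(all(sy >= 0 & sy <= 1))
  expect_true(mean(sy == 0) >= 0.05 - 1e-9)
  expect_true(mean(sy == 1) >= 0.05 - 1e-9)
  # constant block: zeros with warning
  expect_warning(z <- quantile_scale(matrix(3, 5, 2)), "constant")
  expect_equal(as.numeric(z), rep(0, 10))
})

test_that("matrix assembly orders columns per mark and checks gene lists", {
  vals <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  meta <- data.frame(
    mark_name = c("a", "b", "meth", "meth"),
    mark_type = "epigenetic_mark",
    methylation_flavor = c("none", "none", "absolute", "cpg_normalized"),
    stringsAsFactors = FALSE
  )
  blocks <- lapply(1:4, function(j) vals[, j, drop = FALSE])
  names(blocks) <- epicompress:::mark_key(meta$mark_name,
                                          meta$methylation_flavor)
  em <- assemble_matrix(blocks, meta, list(cell_line = "c",
                                           gene_type = "protein_coding",
                                           region_type = "tss_flank"))
  expect_equal(ncol(em$values), 4L)
  expect_equal(colnames(em$values),
               c("a", "b", "meth.absolute", "meth.cpg_normalized"))
  # width = marks x bins for multi-bin blocks
  blocks40 <- list(a = matrix(runif(400), 10, 40,
                              dimnames = list(rownames(vals), NULL)),
                   b = matrix(runif(400), 10, 40,
                              dimnames = list(rownames(vals), NULL)))
  em40 <- assemble_matrix(blocks40, meta[1:2, ],
                          list(cell_line = "c", gene_type = "protein_coding",
                               region_type = "tss_flank"))
  expect_equal(ncol(em40$values), 80L)
  # mismatched gene lists error
  bad <- blocks
  rownames(bad[[2]]) <- rev(rownames(bad[[2]]))
  expect_error(assemble_matrix(bad, meta, list()), "gene lists")
})

test_that("enrichment matrices persist through TSV + JSON sidecar", {
  w <- small_disk_world()
  em <- world_matrices(w)
  base <- tempfile()
  write_enrichment_matrix(em, base)
  back <- read_enrichment_matrix(base)
  expect_equal(back$values, em$values, tolerance = 1e-12)
  expect_equal(back$marks$key, em$marks$key)
  expect_equal(back$constellation, em$constellation)
})
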