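#' @name synthetic_data
#' @title Synthetic multi-cell-line worlds with planted structure
#'
#' @description
#' Generates complete worlds — gene annotation, per-mark signal tracks, CpG
#' positions, blacklist, CAGE strand tracks — with a planted latent-factor
#' correlation structure, so that every pipeline stage has ground truth:
#'
#' * per cell line, each gene carries a latent state vector `z` (iid standard
#'   normal, `latent_dim` components);
#' * each mark has a sparse unit-norm loading vector `w` and a gene-level
#'   activity `s = z'w + noise`; the noise standard deviation is derived from
#'   the configured theoretical CV correlation `target_r` through the
#'   variance partition `var(signal) / var(total) = target_r^2`;
#' * `shared`-rule marks reuse their loadings in every cell line (the
#'   "activating" regime), `cell_specific` marks redraw them per cell-line
#'   family (the "silencing" regime);
#' * an optional hub mark loads uniformly on all latent factors, making it
#'   the most informative single predictor;
#' * bin-level signal around the TSS is a fixed per-mark peak profile scaled
#'   by the (shifted-positive) activity, plus optional half-normal flanking
#'   background noise that dilutes 1-bin summaries without touching the
#'   middle two bins;
#' * expression is exponential in a linear (or hinge) combination of the
#'   measured middle-two-bin signal, written as CAGE plus/minus tracks whose
#'   middle-two-bin mass sums to `GEx`;
#' * DNA methylation, when enabled, has a CpG-density-coupled absolute track
#'   and a planted methylated fraction recoverable by CpG normalization.
#'
#' Everything is reproducible bit-for-bit from `(config, seed)`.
NULL

#' Default mark panel for a synthetic world
#'
#' @param n_marks number of marks.
#' @param n_cell_specific how many of them follow cell-line-specific rules
#'   (the rest are shared-rule).
#' @param hub add a densely loading hub mark as the first mark?
#' @return data.frame with `name`, `mark_type`, `rule_class`, `hub`.
#' @export
default_marks <- function(n_marks = 20L, n_cell_specific = 0L, hub = FALSE) {
  stopifnot(n_marks >= 2L, n_cell_specific <= n_marks)
  types <- rep(c("epigenetic_mark", "transcription_factor", "coregulator",
                 "chromatin_remodeler"), length.out = n_marks)
  rule <- rep("shared", n_marks)
  if (n_cell_specific > 0L) {
    rule[seq(n_marks - n_cell_specific + 1L, n_marks)] <- "cell_specific"
  }
  data.frame(
    name = sprintf("mark%02d", seq_len(n_marks)),
    mark_type = types,
    rule_class = rule,
    hub = c(hub, rep(FALSE, n_marks - 1L)),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic world
#'
#' @param n_genes number of genes.
#' @param marks data.frame as from [default_marks()].
#' @param n_cell_lines number of cell lines.
#' @param families integer vector (length `n_cell_lines`) assigning cell
#'   lines to families; cell-specific marks share loadings within a family
#'   and redraw them across families. Default: every cell line its own
#'   family.
#' @param latent_dim dimension of the shared latent program (the block all
#'   shared-rule marks load on). Small relative to the panel so that the
#'   variance-partition prediction ceiling is attainable.
#' @param specific_latent_dim dimension of the cell-specific latent program
#'   (the block cell-specific marks load on, with per-family signed
#'   loadings).
#' @param loading_sparsity probability that a loading component is non-zero.
#' @param target_r desired theoretical cross-validated Pearson r for
#'   predicting a mark from the others (sets each mark's noise sd through
#'   the variance partition).
#' @param hub_noise_factor multiplier on the noise sd of hub marks ("one
#'   mark drives all": the hub is measured more faithfully than the marks it
#'   drives).
#' @param flank_noise_sd sd (relative to the activity sd) of the half-normal
#'   per-bin background added outside the planted peak; 0 disables it.
#' @param include_methylation add a DNA methylation mark (absolute +
#'   CpG-normalized columns)?
#' @param cpg_density expected CpGs per bp in promoter bins.
#' @param meth_coupling slope linking the methylation latent activity to the
#'   methylated fraction (logistic link).
#' @param expression list: `link` (`"linear"` or `"hinge"`), `n_marks` (how
#'   many marks drive expression), `target_r` (theoretical CV r of the
#'   expression model), `knot` (hinge knot on the standardized predictor),
#'   `zero_fraction` (fraction of genes floored to zero expression).
#'   Default: linear link over the first `min(6, n_marks)` marks, target r
#'   0.9, no zeros.
#' @param cell_cor correlation of a gene's latent state across cell lines
#'   (gene states are partially conserved between cell types; this is what
#'   makes the same-mark-other-cell-line baseline informative). Transfers
#'   and intra-cell-line analyses are unaffected by it.
#' @param genes_per_chrom gene slots per chromosome (10 kb each).
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated `world_config` list.
#' @export
world_config <- function(n_genes = 2000L,
                         marks = default_marks(),
                         n_cell_lines = 1L,
                         families = seq_len(n_cell_lines),
                         latent_dim = 2L,
                         specific_latent_dim = 3L,
                         loading_sparsity = 0.5,
                         target_r = 0.9,
                         hub_noise_factor = 0.5,
                         flank_noise_sd = 0,
                         include_methylation = FALSE,
                         cpg_density = 0.02,
                         meth_coupling = 1.5,
                         expression = NULL,
                         cell_cor = 0.7,
                         genes_per_chrom = 1000L,
                         seed = 1L) {
  if (is.null(expression)) {
    expression <- list(link = "linear", n_marks = min(6L, nrow(marks)),
                       target_r = 0.9, knot = 0.25, zero_fraction = 0)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), marks = marks,
    n_cell_lines = as.integer(n_cell_lines),
    families = as.integer(families),
    latent_dim = as.integer(latent_dim),
    specific_latent_dim = as.integer(specific_latent_dim),
    loading_sparsity = loading_sparsity, target_r = target_r,
    hub_noise_factor = hub_noise_factor,
    flank_noise_sd = flank_noise_sd,
    include_methylation = isTRUE(include_methylation),
    cpg_density = cpg_density, meth_coupling = meth_coupling,
    expression = expression, cell_cor = cell_cor,
    genes_per_chrom = as.integer(genes_per_chrom),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 20L) stop("config: need at least 20 genes", call. = FALSE)
  if (nrow(marks) < 2L) stop("config: need at least 2 marks", call. = FALSE)
  if (!all(c("name", "mark_type", "rule_class") %in% colnames(marks))) {
    stop("config: marks needs name/mark_type/rule_class columns",
         call. = FALSE)
  }
  if (anyDuplicated(marks$name)) stop("config: duplicate mark names",
                                      call. = FALSE)
  if (is.null(marks$hub)) cfg$marks$hub <- FALSE
  if (!(target_r > 0 && target_r < 1)) {
    stop("config: target_r must be in (0, 1)", call. = FALSE)
  }
  if (length(cfg$families) != cfg$n_cell_lines) {
    stop("config: families must have one entry per cell line", call. = FALSE)
  }
  if (!(loading_sparsity > 0 && loading_sparsity <= 1)) {
    stop("config: loading_sparsity must be in (0, 1]", call. = FALSE)
  }
  if (!(cell_cor >= 0 && cell_cor <= 1)) {
    stop("config: cell_cor must be in [0, 1]", call. = FALSE)
  }
  ex <- cfg$expression
  if (!ex$link %in% c("linear", "hinge")) {
    stop("config: expression link must be linear or hinge", call. = FALSE)
  }
  if (ex$n_marks > nrow(marks)) {
    stop("config: expression n_marks exceeds mark panel", call. = FALSE)
  }
  class(cfg) <- "world_config"
  cfg
}

# geometry constants: one 10 kb slot per gene, TSS flank +/- 2 kb, 40 bins
WORLD_SLOT <- 10000L
WORLD_FLANK <- 2000L
WORLD_NBINS <- 40L
WORLD_BINW <- 100L

# Per-mark bin profile over the 40 TSS bins. Flat: every bin carries the
# gene-level activity, so the 1-bin summary is exactly the activity and
# pooled per-mark quantile scaling treats all bins exchangeably (a peaked
# profile would park the middle bins in the clipped top 1%). Bin-level
# structure enters through the flank-noise field and the CAGE emission.
mark_profile <- function(mark_index) {
  rep(1 / WORLD_NBINS, WORLD_NBINS)
}

#' Generate a synthetic world
#'
#' Builds the complete in-memory truth (latents, loadings, activities,
#' per-bin densities, expression, methylation) and optionally writes the
#' world to disk as GTF + bedGraph tracks + CpG BED (+ optional FASTA) +
#' blacklist BED + CAGE tracks + chromosome sizes, all deterministic under
#' the config seed.
#'
#' @param config a `world_config`.
#' @param dir output directory for files, or `NULL` for in-memory only.
#' @param write_fasta also emit the genome FASTA (only sensible for small
#'   worlds; the sequence plants exactly the configured CpGs).
#' @return a `world`: list with `config`, `genes`, `blacklist`,
#'   `blacklist_genes`, `cpg` (per-gene x bin counts and positions),
#'   `cells` (per cell line: activities `s`, per-mark bin densities,
#'   methylated fraction, expression truth, CAGE bin masses), `files`.
#' @export
generate_world <- function(config, dir = NULL, write_fasta = FALSE) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  seed <- cfg$seed
  n <- cfg$n_genes
  marks <- cfg$marks
  nm <- nrow(marks)
  d <- cfg$latent_dim
  cells <- sprintf("cell%s", LETTERS[seq_len(cfg$n_cell_lines)])

  # ---- gene layout ----------------------------------------------------
  n_chroms <- ceiling(n / cfg$genes_per_chrom)
  chrom_of <- rep(sprintf("chr%d", seq_len(n_chroms)),
                  each = cfg$genes_per_chrom)[seq_len(n)]
  slot_in_chrom <- (seq_len(n) - 1L) %% cfg$genes_per_chrom
  layout <- with_seed(child_seed(seed, "layout"), {
    len <- sample(seq(2000L, 6000L, by = 100L), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ntx <- sample(1:3, n, replace = TRUE)
    list(len = len, strand = strand, ntx = ntx)
  })
  gstart <- slot_in_chrom * WORLD_SLOT + WORLD_FLANK  # 0-based gene start
  gend <- gstart + layout$len                          # 0-based half-open
  tss <- ifelse(layout$strand == "+", gstart, gend - 1L)
  tts <- ifelse(layout$strand == "+", gend - 1L, gstart)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    gene_type = "protein_coding",
    chrom = chrom_of, strand = layout$strand,
    tss = as.integer(tss), tts = as.integer(tts),
    n_transcripts = layout$ntx,
    stringsAsFactors = FALSE
  )
  chrom_lengths <- setNames(
    rep(cfg$genes_per_chrom * WORLD_SLOT, n_chroms),
    sprintf("chr%d", seq_len(n_chroms))
  )

  # ---- blacklist: overlaps the TSS flank of a fixed 2% of genes --------
  n_bl <- max(1L, round(0.02 * n))
  bl_idx <- with_seed(child_seed(seed, "blacklist"),
                      sort(sample.int(n, n_bl)))
  blacklist <- data.frame(
    chrom = genes$chrom[bl_idx],
    start = as.integer(genes$tss[bl_idx] - WORLD_FLANK - 50L),
    end = as.integer(genes$tss[bl_idx] - WORLD_FLANK + 50L),
    stringsAsFactors = FALSE
  )
  blacklist$start <- pmax(blacklist$start, 0L)

  # ---- CpG positions in TSS-flank bins ---------------------------------
  cpg <- with_seed(child_seed(seed, "cpg"), {
    counts <- matrix(
      stats::rpois(n * WORLD_NBINS, cfg$cpg_density * WORLD_BINW) + 1L,
      nrow = n
    )
    counts
  })
  rownames(cpg) <- genes$gene_id

  # ---- per-mark noise sd from the variance partition -------------------
  sd_noise <- sqrt(1 / cfg$target_r^2 - 1)  # unit-variance signal
  hub_f <- cfg$hub_noise_factor %||% 0.5
  sd_noise_marks <- sd_noise * ifelse(marks$hub, hub_f, 1)
  sd_act <- sqrt(1 + sd_noise^2)

  # ---- loadings --------------------------------------------------------
  # Shared-rule and cell-specific marks live on separate latent blocks: the
  # shared program occupies dims 1..d, the cell-specific program (when such
  # marks exist) dims d+1..2d. This keeps the rules of shared marks
  # genuinely cell-line-independent: their models draw no information from
  # the unstable marks.
  has_specific <- any(marks$rule_class == "cell_specific") ||
    cfg$include_methylation
  d_sp <- cfg$specific_latent_dim %||% 3L
  d_total <- if (has_specific) d + d_sp else d
  block_of <- function(rule) {
    if (rule == "cell_specific" && has_specific) d + seq_len(d_sp) else
      seq_len(d)
  }
  # one random sparse unit loading vector on a latent block; shared-rule
  # loadings are nonnegative (a coherent activating program), cell-specific
  # ones are signed so the rules of different families can truly differ
  rand_loading <- function(block, signed = FALSE) {
    nz <- which(runif(length(block)) < cfg$loading_sparsity)
    if (length(nz) == 0L) nz <- sample.int(length(block), 1L)
    w <- numeric(d_total)
    v <- rnorm(length(nz))
    w[block[nz]] <- if (signed) v else abs(v)
    w / sqrt(sum(w^2))
  }
  # cell-specific rules must actually differ across families: redraw until
  # the cosine to every earlier family's loading is at most 0.5 (best draw
  # kept if 60 tries never get there)
  draw_dissimilar <- function(prev, block) {
    best <- NULL
    best_cos <- Inf
    for (i in 1:60) {
      w <- rand_loading(block, signed = TRUE)
      mc <- if (length(prev) == 0L) 0 else
        max(vapply(prev, function(p) abs(sum(p * w)), numeric(1)))
      if (mc < best_cos) {
        best <- w
        best_cos <- mc
      }
      if (mc <= 0.5) break
    }
    best
  }
  fams <- unique(cfg$families)
  per_mark <- lapply(seq_len(nm), function(m) {
    if (isTRUE(marks$hub[m])) {
      hubw <- numeric(d_total)
      hubw[seq_len(d)] <- 1 / sqrt(d)
      return(setNames(rep(list(hubw), length(fams)), as.character(fams)))
    }
    if (marks$rule_class[m] == "shared") {
      w <- with_seed(child_seed(seed, "load", marks$name[m], "shared"),
                     rand_loading(block_of("shared")))
      return(setNames(rep(list(w), length(fams)), as.character(fams)))
    }
    out <- list()
    for (f in fams) {
      out[[as.character(f)]] <- with_seed(
        child_seed(seed, "load", marks$name[m], "fam", f),
        draw_dissimilar(out, block_of("cell_specific")))
    }
    out
  })
  loadings <- lapply(seq_len(cfg$n_cell_lines), function(ci) {
    W <- vapply(seq_len(nm), function(m)
      per_mark[[m]][[as.character(cfg$families[ci])]], numeric(d_total))
    W <- matrix(W, nrow = d_total)  # d_total = 1 would simplify to a vector
    colnames(W) <- marks$name
    W
  })
  names(loadings) <- cells

  # ---- per-cell-line data ----------------------------------------------
  ex <- cfg$expression
  ex_marks <- marks$name[seq_len(ex$n_marks)]
  cells_out <- list()
  # gene states are partially conserved across cell lines: z_c is a mixture
  # of a common component and a cell-line-private one with cor = cell_cor
  rho <- cfg$cell_cor %||% 0.7
  Z0 <- with_seed(child_seed(seed, "latent0"),
                  matrix(rnorm(n * d_total), n, d_total))
  for (ci in seq_len(cfg$n_cell_lines)) {
    cell <- cells[ci]
    Z <- sqrt(rho) * Z0 +
      sqrt(1 - rho) * with_seed(child_seed(seed, "latent", cell),
                                matrix(rnorm(n * d_total), n, d_total))
    S <- Z %*% loadings[[ci]]
    S <- S + with_seed(child_seed(seed, "marknoise", cell),
                       sweep(matrix(rnorm(n * nm), n, nm), 2L,
                             sd_noise_marks, `*`))
    colnames(S) <- marks$name
    amp <- pmax(S + 6 * sd_act, 0)
    bins <- list()
    for (m in seq_len(nm)) {
      prof <- mark_profile(m)
      dens <- outer(amp[, m], prof * WORLD_NBINS)  # keeps 1-bin mean = amp*mean(prof)*40/40
      if (cfg$flank_noise_sd > 0) {
        bg <- with_seed(child_seed(seed, "flank", cell, marks$name[m]),
                        matrix(abs(rnorm(n * WORLD_NBINS,
                                         sd = cfg$flank_noise_sd * sd_act)),
                               n, WORLD_NBINS))
        dens <- dens + bg
      }
      rownames(dens) <- genes$gene_id
      bins[[marks$name[m]]] <- dens
    }
    # methylation: latent activity with a cell-specific rule, logistic
    # fraction, absolute mass coupled to CpG counts
    meth <- NULL
    if (cfg$include_methylation) {
      # methylation follows a cell-specific (silencing-like) rule
      w_meth <- with_seed(child_seed(seed, "load", "DNAme",
                                     paste0("fam", cfg$families[ci])),
                          rand_loading(block_of("cell_specific")))
      s_meth <- as.numeric(Z %*% w_meth) +
        with_seed(child_seed(seed, "methnoise", cell),
                  rnorm(n, sd = sd_noise))
      frac <- stats::plogis(cfg$meth_coupling * s_meth)
      # methylated-CpG mass per bin; density = mass / bin width
      meth_dens <- (frac * cpg) / WORLD_BINW
      rownames(meth_dens) <- genes$gene_id
      meth <- list(s = s_meth, frac = frac, dens = meth_dens)
    }
    # expression: link on the measured middle-two-bin signal
    mid <- vapply(ex_marks, function(mk)
      bins[[mk]][, 20L] + bins[[mk]][, 21L], numeric(n))
    mid_z <- scale(mid)
    beta <- with_seed(child_seed(seed, "exprbeta"),
                      runif(ex$n_marks, 0.5, 1.5))
    act <- if (ex$link == "linear") {
      as.numeric(mid_z %*% beta)
    } else {
      as.numeric(pmax(mid_z - ex$knot, 0) %*% beta)
    }
    sd_e <- sd(act) * sqrt(1 / ex$target_r^2 - 1)
    lnGEx <- act + with_seed(child_seed(seed, "exprnoise", cell),
                             rnorm(n, sd = sd_e))
    raw_gex <- exp(lnGEx)
    zf <- ex$zero_fraction %||% 0
    if (zf > 0) {
      raw_gex[raw_gex <= quantile(raw_gex, zf, type = 7)] <- 0
    }
    # split GEx over the four middle strand bins (densities; the readout
    # sums densities, so the parts sum to GEx)
    split4 <- with_seed(child_seed(seed, "cagesplit", cell), {
      p <- matrix(runif(n * 4, 0.1, 1), n, 4)
      p / rowSums(p)
    })
    cage <- split4 * raw_gex
    colnames(cage) <- c("plus20", "plus21", "minus20", "minus21")
    rownames(cage) <- genes$gene_id
    cells_out[[cell]] <- list(
      Z = Z, loadings = loadings[[ci]], s = S, amp = amp, bins = bins,
      meth = meth, expression = list(activity = act, raw_gex = raw_gex,
                                     beta = beta, link = ex$link),
      cage = cage
    )
  }

  world <- structure(
    list(config = cfg, cell_lines = cells, genes = genes,
         chrom_lengths = chrom_lengths, blacklist = blacklist,
         blacklist_genes = genes$gene_id[bl_idx], cpg = cpg,
         sd_noise = sd_noise, sd_noise_marks = sd_noise_marks,
         cells = cells_out, files = NULL),
    class = "world"
  )
  if (!is.null(dir)) {
    world$files <- write_world_files(world, dir, write_fasta = write_fasta)
  }
  world
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.world <- function(x, ...) {
  cat("synthetic world:", x$config$n_genes, "genes,",
      nrow(x$config$marks), "marks,", x$config$n_cell_lines,
      "cell line(s), target_r =", x$config$target_r, "\n")
  invisible(x)
}

#' Summarize a world's planted structure
#'
#' Reports the theoretical per-mark prediction ceiling, the loading cosine
#' similarity of each mark across cell-line pairs, and the expected winner of
#' the first greedy-selection round (the mark maximizing the median
#' single-predictor correlation under the true covariance).
#'
#' @param world a `world` from [generate_world()].
#' @return a `world_report` list with `r_star`, `loading_similarity`,
#'   `expected_first_selection`, printed in a human-readable form.
#' @export
world_report <- function(world) {
  cfg <- world$config
  marks <- cfg$marks
  if (nrow(marks) == 0L) stop("world has no marks", call. = FALSE)
  sdm <- world$sd_noise_marks %||% rep(world$sd_noise, nrow(marks))
  r_star <- setNames(1 / sqrt(1 + sdm^2), marks$name)
  # true mark-mark covariance per cell line -> expected round-1 winner
  winners <- vapply(world$cell_lines, function(cell) {
    W <- world$cells[[cell]]$loadings
    C <- crossprod(W) + diag(sdm^2, nrow(marks))
    R <- stats::cov2cor(C)
    score <- vapply(seq_len(nrow(marks)), function(j)
      median(abs(R[j, -j])), numeric(1))
    marks$name[which.max(score)]
  }, character(1))
  sim <- NULL
  if (cfg$n_cell_lines >= 2L) {
    pairs <- utils::combn(world$cell_lines, 2L)
    sim <- apply(pairs, 2L, function(pr) {
      Wa <- world$cells[[pr[1L]]]$loadings
      Wb <- world$cells[[pr[2L]]]$loadings
      vapply(seq_len(ncol(Wa)), function(m)
        sum(Wa[, m] * Wb[, m]) /
          sqrt(sum(Wa[, m]^2) * sum(Wb[, m]^2)), numeric(1))
    })
    rownames(sim) <- marks$name
    colnames(sim) <- apply(pairs, 2L, paste, collapse = "-")
  }
  structure(list(r_star = r_star, loading_similarity = sim,
                 expected_first_selection = winners),
            class = "world_report")
}

#' @export
print.world_report <- function(x, ...) {
  cat("world_report\n")
  cat("  theoretical r*:", fmt_num(x$r_star[1L], 3), "(all marks)\n")
  cat("  expected first selection:",
      paste(unique(x$expected_first_selection), collapse = ", "), "\n")
  if (!is.null(x$loading_similarity)) {
    cat("  median cross-cell loading cosine:",
        fmt_num(median(x$loading_similarity), 3), "\n")
  }
  invisible(x)
}

#' Fixed study-condition worlds
#'
#' Convenience constructors for the three planted-structure scenarios the
#' package's analyses revolve around, with their conditions fixed in one
#' place:
#'
#' * `hub_world_config()`: "one mark drives all" — a one-dimensional shared
#'   program, every mark loading on it, and a hub mark measured with half the
#'   noise of the rest, making it deterministically the most informative
#'   single predictor.
#' * `transfer_world_config()`: three cell lines with 10 shared-rule and 5
#'   cell-specific marks — the activating/silencing transfer dichotomy.
#' * `expression_world_config()`: a 6-mark world whose expression is
#'   exponential in a link of the measured middle-two-bin signal. The
#'   `linear`-link variant adds flanking background noise (2.5 activity sds)
#'   that dilutes 1-bin summaries while leaving the +/- 100 bp window
#'   informative — the resolution contrast. The `hinge`-link variant drops
#'   the background and plants a threshold effect (impact only beyond a
#'   binding strength) — the MARS-versus-linear contrast.
#'
#' @param seed master seed.
#' @param n_genes number of genes.
#' @param n_marks,n_shared,n_specific,n_cell_lines panel sizes.
#' @param link expression link, `"linear"` or `"hinge"`.
#' @return a `world_config`.
#' @name study_worlds
NULL

#' @rdname study_worlds
#' @export
hub_world_config <- function(seed = 1L, n_genes = 1000L, n_marks = 10L) {
  world_config(n_genes = n_genes,
               marks = default_marks(n_marks, hub = TRUE),
               latent_dim = 1L, loading_sparsity = 1,
               seed = seed)
}

#' @rdname study_worlds
#' @export
transfer_world_config <- function(seed = 1L, n_genes = 1500L,
                                  n_shared = 10L, n_specific = 5L,
                                  n_cell_lines = 3L) {
  world_config(n_genes = n_genes,
               marks = default_marks(n_shared + n_specific,
                                     n_cell_specific = n_specific),
               n_cell_lines = n_cell_lines,
               seed = seed)
}

#' @rdname study_worlds
#' @export
expression_world_config <- function(seed = 1L, link = "linear",
                                    n_genes = if (link == "linear") 2000L
                                              else 1200L,
                                    n_marks = 6L) {
  world_config(n_genes = n_genes,
               marks = default_marks(n_marks),
               flank_noise_sd = if (link == "linear") 2.5 else 0,
               expression = list(link = link, n_marks = 6L, target_r = 0.9,
                                 knot = 0.25, zero_fraction = 0),
               seed = seed)
}
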