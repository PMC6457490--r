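#' Configuration for the synthetic two-strain tiling-array design
#'
#' The generator emulates a two-strain (complemented vs deletion mutant),
#' dye-swapped, duplicate time-course design on a fixed-step tiling array:
#' ChIP IP-vs-mock log2 ratios and expression cDNA-vs-gDNA log2 ratios at
#' three sampling times (14, 18, 35 h by default), two biological
#' replicates per strain labelled in opposite Cy-dye orientations.
#'
#' @param genome_length chromosome length in bp.
#' @param n_genes number of gene models to place.
#' @param probe_spacing tiling step in bp (start-to-start).
#' @param probe_length probe length in bp.
#' @param strains character of length 2: the complemented (tag-expressing)
#'   strain first, the deletion strain second. Enrichment spikes are added
#'   only to the first strain's ChIP ratios.
#' @param replicates_per_strain biological replicates per strain
#'   (>= 2; the candidate-probe rule needs paired replicates).
#' @param timepoints sampling times in hours.
#' @param noise_sd sd of i.i.d. Gaussian noise on the log2 scale.
#' @param dye_bias half-range of the per-array additive dye-bias offset,
#'   applied on the raw (Cy5/Cy3) orientation scale; the per-array offset
#'   is drawn uniformly from `[-dye_bias, dye_bias]`.
#' @param flag_rate probability that a probe/channel/sample is QC-flagged.
#' @param baseline_sd sd of the per-probe (ChIP) and per-gene (expression)
#'   baseline shared by all arrays of an assay. The baseline models
#'   probe-specific hybridization efficiency; it cancels exactly in the
#'   between-strain contrast and keeps per-array median absolute values
#'   positive even at `noise_sd = 0`.
#' @param rng_seed integer seed; identical (config, truth, seed) give
#'   bit-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, n_genes = 60L,
                       probe_spacing = 80L, probe_length = 60L,
                       strains = c("3xF", "dAbsA2"),
                       replicates_per_strain = 2L,
                       timepoints = c(14, 18, 35),
                       noise_sd = 0.3, dye_bias = 0.2, flag_rate = 0.01,
                       baseline_sd = 0.5, rng_seed = 1L) {
  if (probe_spacing < 1) stop("probe_spacing must be >= 1")
  if (genome_length < 10 * probe_spacing)
    stop("genome_length must be >= 10 * probe_spacing")
  if (length(strains) != 2L || anyDuplicated(strains))
    stop("strains must be exactly two distinct labels")
  if (replicates_per_strain < 2L)
    stop("replicates_per_strain must be >= 2 (paired-replicate candidate rule)")
  if (noise_sd < 0 || dye_bias < 0 || baseline_sd < 0)
    stop("noise_sd, dye_bias and baseline_sd must be >= 0")
  if (flag_rate < 0 || flag_rate > 1) stop("flag_rate must be in [0, 1]")
  structure(list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    probe_spacing = as.integer(probe_spacing),
    probe_length = as.integer(probe_length),
    strains = as.character(strains),
    replicates_per_strain = as.integer(replicates_per_strain),
    timepoints = as.numeric(timepoints), noise_sd = noise_sd,
    dye_bias = dye_bias, flag_rate = flag_rate, baseline_sd = baseline_sd,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Ground-truth binding regions
#'
#' @param center bp position of the (major) peak center.
#' @param shape `"monophasic"` or `"biphasic"`.
#' @param amplitude log2 enrichment at the major apex (> 0).
#' @param width Gaussian sigma in bp.
#' @param peak_separation bp between major and minor apex (biphasic only).
#' @param amplitude_ratio minor/major amplitude, in (0, 1] (biphasic only).
#' @param active_timepoints list-column (or single vector, recycled) of
#'   timepoints at which the region is bound.
#' @return data.frame of class `true_regions`, one row per region.
#' @export
true_regions <- function(center, shape, amplitude, width,
                         peak_separation = NA_real_,
                         amplitude_ratio = NA_real_,
                         active_timepoints = list(c(14, 18, 35))) {
  n <- length(center)
  if (!is.list(active_timepoints)) active_timepoints <- list(active_timepoints)
  df <- data.frame(center = center, shape = rep_len(shape, n),
                   amplitude = rep_len(amplitude, n),
                   width = rep_len(width, n),
                   peak_separation = rep_len(peak_separation, n),
                   amplitude_ratio = rep_len(amplitude_ratio, n),
                   stringsAsFactors = FALSE)
  df$active_timepoints <- rep_len(active_timepoints, n)
  if (!all(df$shape %in% c("monophasic", "biphasic")))
    stop("shape must be 'monophasic' or 'biphasic'")
  if (any(df$amplitude <= 0)) stop("amplitude must be > 0")
  bi <- df$shape == "biphasic"
  if (any(bi & (is.na(df$peak_separation) | df$peak_separation <= 0)))
    stop("biphasic regions require peak_separation > 0")
  if (any(bi & (is.na(df$amplitude_ratio) | df$amplitude_ratio <= 0 |
                df$amplitude_ratio > 1)))
    stop("biphasic regions require amplitude_ratio in (0, 1]")
  class(df) <- c("true_regions", class(df))
  df
}

#' Ground-truth differential expression
#'
#' @param gene_id gene identifier (must exist in the generated annotation).
#' @param timepoint hours at which the effect is present.
#' @param log2_effect signed log2 effect; positive = higher in the
#'   complemented strain.
#' @return data.frame of class `true_de`.
#' @export
true_de <- function(gene_id, timepoint, log2_effect) {
  df <- data.frame(gene_id = gene_id, timepoint = timepoint,
                   log2_effect = log2_effect, stringsAsFactors = FALSE)
  class(df) <- c("true_de", class(df))
  df
}

#' Evaluate a spike profile at probe positions
#'
#' Monophasic regions are a single Gaussian
#' `amplitude * exp(-(p - center)^2 / (2 width^2))`; biphasic regions add a
#' second Gaussian of amplitude `amplitude * amplitude_ratio` centered
#' `peak_separation` bp downstream — the asymmetric two-summit geometry
#' with the larger peak first.
#'
#' @param region one row of [true_regions()] (or an equivalent list).
#' @param probe_positions sorted ascending bp positions.
#' @return numeric vector of log2 enrichment, one value per position.
#' @export
spike_profile <- function(region, probe_positions) {
  if (is.data.frame(region)) region <- as.list(region[1L, ])
  if (is.null(region$width) || region$width <= 0) stop("width must be > 0")
  if (is.unsorted(probe_positions))
    stop("probe_positions must be sorted ascending")
  g <- function(mu, a)
    a * exp(-(probe_positions - mu)^2 / (2 * region$width^2))
  y <- g(region$center, region$amplitude)
  if (identical(region$shape, "biphasic"))
    y <- y + g(region$center + region$peak_separation,
               region$amplitude * region$amplitude_ratio)
  y
}

#' Deterministic gene models for a simulation config
#'
#' Genes of 900 bp are laid head-to-tail with 700 bp gaps. Genes 5 and 6
#' form a divergent (head-to-head) pair sharing an intergenic region,
#' mirroring divergent-promoter loci; all other genes are on the plus
#' strand. The layout is purely arithmetic in the config, so the
#' annotation can be inspected before choosing ground-truth DE genes.
#'
#' @param config a [sim_config()].
#' @return A [genome_annotation()] data.frame.
#' @export
sim_annotation <- function(config) {
  pitch <- 1600L
  gene_len <- 900L
  n_fit <- max(0L, (config$genome_length - 1000L) %/% pitch)
  n <- min(config$n_genes, n_fit)
  start <- 1001L + (seq_len(n) - 1L) * pitch
  end <- start + gene_len - 1L
  strand <- rep("+", n)
  if (n >= 5L) strand[5L] <- "-"   # genes 5 (-) and 6 (+) are divergent
  genome_annotation(data.frame(
    gene_id = sprintf("SCO%04d", 1000L + seq_len(n)),
    chrom = "chr", start = start, end = end, strand = strand,
    stringsAsFactors = FALSE))
}

#' Default ground-truth binding regions for a config
#'
#' Twelve regions (8 monophasic, 4 biphasic) at amplitude 2.0 log2, sigma
#' 120 bp, biphasic separation 600 bp and amplitude ratio 0.5, spread
#' evenly so neighbouring regions cannot be merged by 1 kb clustering. One
#' region sits inside a gene body and one in the divergent intergenic
#' region, mirroring gene-internal and bidirectional-promoter binding.
#'
#' @param config a [sim_config()].
#' @return A [true_regions()] data.frame with 12 rows.
#' @export
default_true_regions <- function(config) {
  ann <- sim_annotation(config)
  centers <- round(seq(0.06, 0.94, length.out = 12) * config$genome_length)
  gap_mid <- if (nrow(ann) >= 6L) round((ann$end[5L] + ann$start[6L]) / 2)
  # move one region into the divergent intergenic gap, but only when that
  # keeps it well clear of its neighbours (no merging under 1 kb linkage)
  if (!is.null(gap_mid) && min(abs(centers[-2L] - gap_mid)) > 2500)
    centers[2L] <- gap_mid
  shape <- rep("monophasic", 12L)
  shape[c(3L, 6L, 9L, 12L)] <- "biphasic"
  true_regions(center = centers, shape = shape, amplitude = 2.0, width = 120,
               peak_separation = ifelse(shape == "biphasic", 600, NA_real_),
               amplitude_ratio = ifelse(shape == "biphasic", 0.5, NA_real_),
               active_timepoints = list(config$timepoints))
}

sim_sample_sheet <- function(config, assay) {
  grid <- expand.grid(replicate = seq_len(config$replicates_per_strain),
                      strain = config$strains,
                      timepoint = config$timepoints,
                      stringsAsFactors = FALSE)
  # replicates labelled in opposite Cy-dye orientations
  dye <- ifelse(grid$replicate %% 2L == 1L, "Cy5", "Cy3")
  data.frame(
    sample_id = sprintf("%s_%gh_%s_r%d", assay, grid$timepoint,
                        gsub("[^A-Za-z0-9]", "", grid$strain),
                        grid$replicate),
    strain = grid$strain, timepoint = grid$timepoint,
    replicate = grid$replicate, assay = assay, ip_dye = dye,
    stringsAsFactors = FALSE)
}

#' Simulate a ground-truthed two-strain tiling-array dataset
#'
#' Generates paired ChIP (IP vs mock) and expression (cDNA vs gDNA)
#' bundles for the full design in `config`. Enrichment spikes are added
#' only to the complemented strain's oriented ChIP ratios at each region's
#' active timepoints; expression effects are realized on all probes
#' overlapping the gene's coding region. Gaussian noise (`noise_sd`) is
#' added everywhere on the log2 scale, per-array dye-bias offsets are
#' applied on the raw `log2(Cy5/Cy3)` orientation, and QC flags are drawn
#' independently at `flag_rate`. Identical inputs and seed give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @param truth_regions a [true_regions()] data.frame (ChIP ground truth).
#' @param truth_de a [true_de()] data.frame (expression ground truth).
#' @return list with elements `chip` and `expression` (signal bundles),
#'   `annotation`, `truth_regions` (with derived `start`/`end` spans) and
#'   `truth_de`.
#' @export
simulate_dataset <- function(config,
                             truth_regions = default_true_regions(config),
                             truth_de = true_de(character(), numeric(),
                                                numeric())) {
  stopifnot(inherits(config, "sim_config"))
  ann <- sim_annotation(config)
  last3 <- function(r) r$center +
    ifelse(r$shape == "biphasic", r$peak_separation, 0) + 3 * r$width
  if (nrow(truth_regions)) {
    lo <- truth_regions$center - 3 * truth_regions$width
    hi <- last3(truth_regions)
    bad <- which(lo < 1 | hi > config$genome_length)
    if (length(bad))
      stop("truth region ", bad[1L], " (center ",
           truth_regions$center[bad[1L]], ") lies outside the genome")
  }
  if (nrow(truth_de) && !all(truth_de$gene_id %in% ann$gene_id))
    stop("truth_de references gene_id absent from the generated annotation")

  starts <- seq.int(1L, config$genome_length - config$probe_length + 1L,
                    by = config$probe_spacing)
  probes <- data.frame(
    probe_id = sprintf("P%06d", seq_along(starts)), chrom = "chr",
    start = starts, end = starts + config$probe_length - 1L,
    stringsAsFactors = FALSE)
  mid <- (probes$start + probes$end) / 2
  np <- nrow(probes)

  # per-gene probe membership (probe overlaps the coding span)
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(probes$start, probes$end),
    IRanges::IRanges(ann$start, ann$end))
  ov_probe <- S4Vectors::queryHits(ov)
  ov_gene <- S4Vectors::subjectHits(ov)

  chip_samples <- sim_sample_sheet(config, "chip")
  expr_samples <- sim_sample_sheet(config, "expression")

  withr::with_seed(config$rng_seed, {
    chip_base <- rnorm(np, 0, config$baseline_sd)
    gene_base <- rnorm(nrow(ann), 0, 1)
    inter_base <- rnorm(np, 0, config$baseline_sd)

    # expression baseline per probe: mean over overlapping genes, else
    # the intergenic per-probe baseline
    expr_base <- inter_base
    if (length(ov_probe)) {
      agg <- tapply(gene_base[ov_gene], ov_probe, mean)
      expr_base[as.integer(names(agg))] <- as.numeric(agg)
    }

    make_bundle <- function(samples, oriented_truth) {
      ns <- nrow(samples)
      oriented <- oriented_truth +
        matrix(rnorm(np * ns, 0, config$noise_sd), np, ns)
      sign <- ifelse(samples$ip_dye == "Cy5", 1, -1)
      raw <- sweep(oriented, 2L, sign, `*`)
      raw <- sweep(raw, 2L, runif(ns, -config$dye_bias, config$dye_bias), `+`)
      flags <- array(rbinom(np * ns * 2L, 1L, config$flag_rate) == 1L,
                     c(np, ns, 2L))
      signal_bundle(probes, samples, raw, flags)
    }

    chip_truth <- matrix(chip_base, np, nrow(chip_samples))
    for (i in seq_len(nrow(truth_regions))) {
      r <- truth_regions[i, ]
      prof <- spike_profile(r, mid)
      on <- chip_samples$strain == config$strains[1L] &
        chip_samples$timepoint %in% r$active_timepoints[[1L]]
      chip_truth[, on] <- chip_truth[, on] + prof
    }
    chip <- make_bundle(chip_samples, chip_truth)

    expr_truth <- matrix(expr_base, np, nrow(expr_samples))
    for (i in seq_len(nrow(truth_de))) {
      d <- truth_de[i, ]
      gi <- match(d$gene_id, ann$gene_id)
      pr <- ov_probe[ov_gene == gi]
      # effect enters through the per-gene value, diluted on probes
      # shared with an overlapping neighbour
      w <- 1 / tabulate(ov_probe, np)[pr]
      on <- expr_samples$strain == config$strains[1L] &
        expr_samples$timepoint == d$timepoint
      expr_truth[pr, on] <- expr_truth[pr, on] + d$log2_effect * w
    }
    expression <- make_bundle(expr_samples, expr_truth)
  })

  tr <- truth_regions
  if (nrow(tr)) {
    tr$start <- pmax(1, round(tr$center - 3 * tr$width))
    tr$end <- pmin(config$genome_length, round(last3(tr)))
    tr$chrom <- "chr"
  }
  list(chip = chip, expression = expression, annotation = ann,
       truth_regions = tr, truth_de = truth_de)
}

#' Write ground-truth tables
#'
#' Region truth is written both as a TSV (all generator fields) and as a
#' BED file (0-based half-open), the same interval convention the caller
#' emits, so truth and calls can be diffed directly.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "truth_regions.tsv")
  bed <- file.path(dir, "truth_regions.bed")
  de <- file.path(dir, "truth_de.tsv")
  tr <- sim$truth_regions
  tr$active_timepoints <- vapply(tr$active_timepoints, paste,
                                 character(1L), collapse = ",")
  write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(tr$chrom, tr$start - 1L, tr$end,
                       paste0("truth_", seq_len(nrow(tr)), "|", tr$shape),
                       0L, ".")
  write.table(bed_df[order(bed_df[[2L]]), ], bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$truth_de, de, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tsv, bed, de))
}
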