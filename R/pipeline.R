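with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

resolve_bundle <- function(x, samples_path = NULL) {
  if (inherits(x, "signal_bundle")) return(x)
  if (is.character(x)) {
    if (is.null(samples_path))
      stop("a sample sheet path is required when signals are given as a path")
    return(read_signal_table(x, samples_path))
  }
  stop("signals must be a signal_bundle or a file path")
}

resolve_annotation <- function(x) {
  if (inherits(x, "genome_annotation")) return(x)
  if (is.data.frame(x)) return(genome_annotation(x))
  if (is.character(x)) {
    if (!file.exists(x)) stop("annotation path does not exist: ", x)
    return(read_annotation(x))
  }
  stop("annotation must be a genome_annotation, data.frame or file path")
}

# QC-filter one timepoint and return oriented values with individually
# flagged (both-channel) observations set to missing
filter_and_orient <- function(bundle, timepoint) {
  report <- with_stage("qc-filter", apply_flag_filter(bundle, timepoint))
  b <- subset_bundle(bundle, timepoint = timepoint)
  b <- drop_probes(b, report$excluded_probe_ids)
  oriented <- with_stage("orient", orient_bundle(b))
  flagged <- report$flagged[b$probes$probe_id, , drop = FALSE]
  oriented[flagged[, colnames(oriented), drop = FALSE]] <- NA_real_
  list(bundle = b, oriented = oriented, report = report)
}

rep_matrix <- function(mat, samples, strain) {
  cols <- which(samples$strain == strain)
  cols <- cols[order(samples$replicate[cols])]
  mat[, cols, drop = FALSE]
}

write_manifest <- function(out_dir, stage_params) {
  path <- file.path(out_dir, "manifest.json")
  stage_params$package <- "tilebind"
  stage_params$version <- as.character(utils::packageVersion("tilebind"))
  jsonlite::write_json(stage_params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the ChIP binding-region pipeline
#'
#' Stages, in order, per timepoint: QC flag filter, dye-orientation
#' correction, scale normalization, dye-balanced strain averaging,
#' strain-contrast enrichment calling, genomic clustering into binding
#' regions, gene annotation, and peak-shape classification. If `out_dir`
#' is given, writes per timepoint a regions BED6, a probe report TSV, a
#' per-locus profile TSV (probe position, per-strain enrichment average,
#' between-strain ratio) and a run manifest JSON.
#'
#' @param signals a [signal_bundle()] (ChIP assay) or signal-table path.
#' @param annotation a [genome_annotation()] or GFF3/TSV path.
#' @param samples_path sample-sheet path when `signals` is a path.
#' @param out_dir optional output directory.
#' @param timepoints timepoints to process (default: all in the bundle).
#' @param complemented label of the complemented strain (default: first
#'   strain in the sample table).
#' @param params a [cluster_params()].
#' @param promoter_window,smooth_window,min_prominence_frac,min_summit_frac
#'   see [annotate_regions()] and [classify_peak_shape()].
#' @return Named list (one element per timepoint) with `regions`,
#'   `enrichment` (the [call_enriched_probes()] result), `filter_report`
#'   and `probe_table`.
#' @export
run_chip_pipeline <- function(signals, annotation, samples_path = NULL,
                              out_dir = NULL, timepoints = NULL,
                              complemented = NULL,
                              params = cluster_params(),
                              promoter_window = 300, smooth_window = 3L,
                              min_prominence_frac = 0.25,
                              min_summit_frac = 0.3) {
  bundle <- resolve_bundle(signals, samples_path)
  ann <- resolve_annotation(annotation)
  if (is.null(timepoints)) timepoints <- sort(unique(bundle$samples$timepoint))
  if (is.null(complemented)) complemented <- bundle$samples$strain[1L]
  other <- setdiff(unique(bundle$samples$strain), complemented)
  if (length(other) != 1L)
    stop("expected exactly two strains; complemented = ", complemented)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  out <- lapply(timepoints, function(tp) {
    fo <- filter_and_orient(bundle, tp)
    norm <- with_stage("scale-normalize", scale_normalize(fo$oriented))
    avg <- with_stage("strain-average", strain_average(norm,
                                                       fo$bundle$samples))
    eps <- with_stage("enrich", call_enriched_probes(
      rep_matrix(norm, fo$bundle$samples, complemented),
      rep_matrix(norm, fo$bundle$samples, other)))
    probes <- fo$bundle$probes
    probe_table <- cbind(probes, avg, eps$probes)
    probe_table$midpoint <- (probes$start + probes$end) / 2
    enr <- probe_table[eps$probes$is_enriched, , drop = FALSE]
    regions <- with_stage("cluster", cluster_regions(enr, params))
    regions <- with_stage("annotate",
                          annotate_regions(regions, ann, promoter_window))
    spacing <- if (nrow(probes) > 1L)
      median(diff(sort(probe_table$midpoint))) else 80
    if (nrow(regions)) {
      regions$summits <- ""
      for (i in seq_len(nrow(regions))) {
        cls <- with_stage("classify", classify_peak_shape(
          regions[i, ], probe_table,
          probe_spacing = spacing, smooth_window = smooth_window,
          min_prominence_frac = min_prominence_frac,
          min_summit_frac = min_summit_frac,
          flank = params$max_gap))
        regions$shape[i] <- cls$shape
        regions$summits[i] <- paste(cls$summits, collapse = ",")
      }
    }
    if (!is.null(out_dir)) {
      tag <- paste0(tp, "h")
      write_regions_bed(regions,
                        file.path(out_dir, paste0("regions_", tag, ".bed")))
      write.table(probe_table,
                  file.path(out_dir, paste0("probes_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prof_rows <- rep(FALSE, nrow(probe_table))
      for (i in seq_len(nrow(regions)))
        prof_rows <- prof_rows |
          (probe_table$midpoint >= regions$start[i] - params$max_gap &
             probe_table$midpoint <= regions$end[i] + params$max_gap)
      prof <- probe_table[prof_rows,
                          c("probe_id", "midpoint", complemented, other,
                            "fold_change")]
      names(prof)[5L] <- "between_strain_ratio"
      write.table(prof,
                  file.path(out_dir, paste0("profile_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(timepoint = tp, regions = regions, enrichment = eps,
         filter_report = fo$report, probe_table = probe_table)
  })
  names(out) <- paste0(timepoints, "h")
  if (!is.null(out_dir))
    write_manifest(out_dir, list(
      pipeline = "chip", timepoints = timepoints,
      complemented = complemented, max_gap = params$max_gap,
      min_probes = params$min_probes, cluster_mode = params$mode,
      promoter_window = promoter_window, smooth_window = smooth_window,
      min_prominence_frac = min_prominence_frac))
  out
}

#' Run the expression / differential-expression pipeline
#'
#' Stages, in order, per timepoint: QC flag filter, dye-orientation
#' correction, global median centering within array, scale normalization
#' across arrays, per-gene averaging of good probes, Rank Product
#' differential expression, DE selection at the pfp cutoff, and DE counts
#' within configured gene-id clusters. If `out_dir` is given, writes per
#' timepoint a gene-level matrix TSV and a DE TSV, plus a counts summary
#' keyed by (timepoint, cluster, direction) and a manifest.
#'
#' @inheritParams run_chip_pipeline
#' @param n_permutations,seed,pfp_cutoff Rank Product parameters; the
#'   timepoint at index i uses `seed + i - 1`.
#' @param gene_clusters named list of `c(lo_id, hi_id)` inclusive gene-id
#'   ranges to count DE genes in (e.g. antibiotic biosynthetic clusters).
#' @param exclusions gene ids excluded from cluster counts (e.g. the
#'   deleted gene itself, whose apparent differential expression is an
#'   artifact of the deletion).
#' @return Named list per timepoint with `gene_matrix`, `rank_product`,
#'   `de` (up/down lists) and `counts`; plus attribute `counts_summary`,
#'   a long data.frame over all timepoints.
#' @export
run_expression_pipeline <- function(signals, annotation,
                                    samples_path = NULL, out_dir = NULL,
                                    timepoints = NULL, complemented = NULL,
                                    n_permutations = 1000L, seed = 1L,
                                    pfp_cutoff = 0.15,
                                    gene_clusters = list(
                                      act = c("SCO5071", "SCO5092"),
                                      cda = c("SCO3210", "SCO3249")),
                                    exclusions = "SCO3226") {
  bundle <- resolve_bundle(signals, samples_path)
  ann <- resolve_annotation(annotation)
  if (is.null(timepoints)) timepoints <- sort(unique(bundle$samples$timepoint))
  if (is.null(complemented)) complemented <- bundle$samples$strain[1L]
  other <- setdiff(unique(bundle$samples$strain), complemented)
  if (length(other) != 1L)
    stop("expected exactly two strains; complemented = ", complemented)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary_rows <- list()
  out <- lapply(seq_along(timepoints), function(ti) {
    tp <- timepoints[ti]
    fo <- filter_and_orient(bundle, tp)
    centered <- with_stage("median-center", median_center(fo$oriented))
    norm <- with_stage("scale-normalize", scale_normalize(centered))
    genes <- with_stage("gene-average",
                        gene_signals(norm, fo$bundle$probes, ann))
    rp <- with_stage("rank-product", rank_product_test(
      rep_matrix(genes, fo$bundle$samples, complemented),
      rep_matrix(genes, fo$bundle$samples, other),
      n_permutations = n_permutations, seed = seed + ti - 1L))
    de <- with_stage("select-de", select_de(rp, pfp_cutoff))
    counts <- list()
    for (cl in names(gene_clusters))
      for (dir in c("up", "down")) {
        cnt <- with_stage("count-in-cluster", count_in_cluster(
          de[[dir]], gene_clusters[[cl]][1L], gene_clusters[[cl]][2L],
          exclusions))
        counts[[paste(cl, dir, sep = "_")]] <- cnt
        summary_rows[[length(summary_rows) + 1L]] <<-
          data.frame(timepoint = tp, cluster = cl, direction = dir,
                     n_genes = cnt, stringsAsFactors = FALSE)
      }
    if (!is.null(out_dir)) {
      tag <- paste0(tp, "h")
      write_matrix_tsv(genes, file.path(out_dir,
                                        paste0("genes_", tag, ".tsv")))
      write_de_table(rp, file.path(out_dir, paste0("de_", tag, ".tsv")))
    }
    list(timepoint = tp, gene_matrix = genes, rank_product = rp, de = de,
         counts = counts)
  })
  names(out) <- paste0(timepoints, "h")
  counts_summary <- if (length(summary_rows))
    do.call(rbind, summary_rows)
  else data.frame(timepoint = numeric(), cluster = character(),
                  direction = character(), n_genes = integer())
  attr(out, "counts_summary") <- counts_summary
  if (!is.null(out_dir)) {
    write.table(counts_summary, file.path(out_dir, "counts_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, list(
      pipeline = "expression", timepoints = timepoints,
      complemented = complemented, n_permutations = n_permutations,
      seed = seed, pfp_cutoff = pfp_cutoff,
      gene_clusters = gene_clusters, exclusions = exclusions))
  }
  out
}
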