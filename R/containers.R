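#' Construct a SignalBundle
#'
#' A `signal_bundle` holds probe-level two-colour data: a probe table, a
#' sample (array) table, the raw `log2(Cy5/Cy3)` matrix and per-channel QC
#' flags. Internal genomic coordinates are 1-based inclusive throughout the
#' package; conversion to 0-based half-open happens only on BED output.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`,
#'   `end` (1-based inclusive). Probe ids must be unique and `start <= end`.
#' @param samples data.frame with columns `sample_id`, `strain`,
#'   `timepoint`, `replicate`, `assay` (`"chip"` or `"expression"`) and
#'   `ip_dye` (`"Cy3"`/`"Cy5"`), the dye carrying the IP (ChIP) or cDNA
#'   (expression) channel. `(strain, timepoint, replicate, assay)` must be
#'   unique.
#' @param values numeric matrix, probes x samples, of raw `log2(Cy5/Cy3)`.
#' @param flags logical array, probes x samples x 2 channels
#'   (`Cy3`, `Cy5`).
#' @return An object of class `signal_bundle`.
#' @export
signal_bundle <- function(probes, samples, values, flags) {
  req_p <- c("probe_id", "chrom", "start", "end")
  if (!all(req_p %in% names(probes)))
    stop("probe table must have columns: ", paste(req_p, collapse = ", "))
  req_s <- c("sample_id", "strain", "timepoint", "replicate", "assay", "ip_dye")
  if (!all(req_s %in% names(samples)))
    stop("sample table must have columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         probes$probe_id[duplicated(probes$probe_id)][1L])
  if (any(probes$start > probes$end))
    stop("probe with start > end: ",
         probes$probe_id[which(probes$start > probes$end)[1L]])
  key <- with(samples, paste(strain, timepoint, replicate, assay))
  if (anyDuplicated(key))
    stop("duplicate (strain, timepoint, replicate, assay) in sample table")
  if (!all(samples$ip_dye %in% c("Cy3", "Cy5")))
    stop("ip_dye must be 'Cy3' or 'Cy5'")
  values <- as.matrix(values)
  if (nrow(values) != nrow(probes) || ncol(values) != nrow(samples))
    stop("values matrix must be probes x samples (",
         nrow(probes), " x ", nrow(samples), ")")
  if (is.null(dim(flags)) || length(dim(flags)) != 3L ||
      !all(dim(flags) == c(nrow(probes), nrow(samples), 2L)))
    stop("flags must be a probes x samples x 2 logical array")
  dimnames(values) <- list(probes$probe_id, samples$sample_id)
  dimnames(flags) <- list(probes$probe_id, samples$sample_id, c("Cy3", "Cy5"))
  structure(
    list(probes = probes, samples = samples,
         values = values, flags = array(as.logical(flags), dim(flags),
                                        dimnames(flags))),
    class = "signal_bundle")
}

#' @export
print.signal_bundle <- function(x, ...) {
  cat("signal_bundle:", nrow(x$probes), "probes x", nrow(x$samples),
      "samples\n")
  cat("  assays:", paste(unique(x$samples$assay), collapse = ", "),
      "| timepoints:", paste(sort(unique(x$samples$timepoint)),
                             collapse = ", "), "h\n")
  cat("  strains:", paste(unique(x$samples$strain), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a SignalBundle by sample
#'
#' @param bundle a [signal_bundle()].
#' @param timepoint optional timepoint (hours) to keep.
#' @param assay optional assay (`"chip"` or `"expression"`) to keep.
#' @param strain optional strain label to keep.
#' @return A `signal_bundle` restricted to the matching samples.
#' @export
subset_bundle <- function(bundle, timepoint = NULL, assay = NULL,
                          strain = NULL) {
  keep <- rep(TRUE, nrow(bundle$samples))
  if (!is.null(timepoint)) {
    if (!timepoint %in% bundle$samples$timepoint)
      stop("timepoint ", timepoint, " not present in bundle")
    keep <- keep & bundle$samples$timepoint == timepoint
  }
  if (!is.null(assay)) keep <- keep & bundle$samples$assay == assay
  if (!is.null(strain)) keep <- keep & bundle$samples$strain == strain
  signal_bundle(bundle$probes, bundle$samples[keep, , drop = FALSE],
                bundle$values[, keep, drop = FALSE],
                bundle$flags[, keep, , drop = FALSE])
}

#' Drop probes from a SignalBundle
#'
#' @param bundle a [signal_bundle()].
#' @param probe_ids character vector of probe ids to remove.
#' @return The bundle without those probes.
#' @export
drop_probes <- function(bundle, probe_ids) {
  keep <- !(bundle$probes$probe_id %in% probe_ids)
  signal_bundle(bundle$probes[keep, , drop = FALSE], bundle$samples,
                bundle$values[keep, , drop = FALSE],
                bundle$flags[keep, , , drop = FALSE])
}

#' Validate a genome annotation table
#'
#' Gene models on a single bacterial chromosome: columns `gene_id`,
#' `chrom`, `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`).
#' Overlapping genes are allowed (divergent pairs are expected).
#'
#' @param genes data.frame of gene models.
#' @return The validated data.frame, sorted by `start`, with class
#'   `genome_annotation` prepended.
#' @export
genome_annotation <- function(genes) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  bad <- which(genes$start > genes$end)
  if (length(bad))
    stop("gene with start > end: ", genes$gene_id[bad[1L]])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- unique(c("genome_annotation", class(genes)))
  genes
}
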