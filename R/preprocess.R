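#' Probe QC exclusion by feature flags
#'
#' A probe counts as "flagged" in a sample iff both channels are flagged.
#' Within one timepoint (2 strains x replicates), a probe is excluded if
#' it is flagged in one or more samples in both strains, or in more than
#' two samples. When both rules apply the reported reason is
#' `both_strains` (fixed precedence, deterministic reporting).
#'
#' @param bundle a [signal_bundle()] (one assay).
#' @param timepoint the timepoint (hours) to evaluate; must be present.
#' @return A list of class `flag_filter_report` with `excluded_probe_ids`,
#'   a `reasons` data.frame (`probe_id`, `reason`), and the logical
#'   probe x sample `flagged` matrix used.
#' @export
apply_flag_filter <- function(bundle, timepoint) {
  if (!timepoint %in% bundle$samples$timepoint)
    stop("timepoint ", timepoint, " not present in bundle")
  b <- subset_bundle(bundle, timepoint = timepoint)
  flagged <- b$flags[, , 1L, drop = FALSE][, , 1L] &
    b$flags[, , 2L, drop = FALSE][, , 1L]
  flagged <- matrix(flagged, nrow(b$probes), nrow(b$samples),
                    dimnames = list(b$probes$probe_id, b$samples$sample_id))
  strains <- unique(b$samples$strain)
  per_strain <- vapply(strains, function(s)
    rowSums(flagged[, b$samples$strain == s, drop = FALSE]) > 0,
    logical(nrow(flagged)))
  both_strains <- rowSums(per_strain) == length(strains) &
    length(strains) > 1L
  more_than_two <- rowSums(flagged) > 2L
  excluded <- both_strains | more_than_two
  reasons <- data.frame(
    probe_id = b$probes$probe_id[excluded],
    reason = ifelse(both_strains[excluded], "both_strains", "more_than_two"),
    stringsAsFactors = FALSE)
  structure(list(excluded_probe_ids = reasons$probe_id, reasons = reasons,
                 flagged = flagged, timepoint = timepoint),
            class = "flag_filter_report")
}

#' Orient raw log ratios toward the IP/cDNA channel
#'
#' Raw values are `log2(Cy5/Cy3)`. If the IP (ChIP) or cDNA (expression)
#' channel was labelled with Cy5 the value is already `log2(IP/mock)` /
#' `log2(cDNA/gDNA)`; if it was labelled with Cy3 the sign is flipped.
#' This is the orientation correction behind a dye-balanced average of
#' dye-swapped replicates.
#'
#' @param raw_log2 numeric vector (or matrix column) of `log2(Cy5/Cy3)`.
#' @param ip_dye `"Cy5"` or `"Cy3"`, recycled along `raw_log2`.
#' @return Oriented log2 ratios (positive = IP/cDNA enriched).
#' @export
orient_ratio <- function(raw_log2, ip_dye) {
  if (!all(ip_dye %in% c("Cy3", "Cy5")))
    stop("unknown dye label: ", paste(setdiff(ip_dye, c("Cy3", "Cy5")),
                                      collapse = ", "))
  raw_log2 * ifelse(ip_dye == "Cy5", 1, -1)
}

#' Orient all samples of a bundle
#'
#' @param bundle a [signal_bundle()].
#' @return probe x sample matrix of oriented log2 ratios.
#' @export
orient_bundle <- function(bundle) {
  sweep(bundle$values, 2L, ifelse(bundle$samples$ip_dye == "Cy5", 1, -1), `*`)
}

#' Scale normalization across arrays
#'
#' Each array (column) is rescaled so its median absolute value equals
#' the geometric mean of the per-array median absolute values
#' (`limma::normalizeMedianAbsValues`). After normalization,
#' `median(|x|)` is identical across arrays to within 1e-9.
#'
#' @param mat oriented log2 matrix, probes x arrays; missing values
#'   allowed.
#' @return The normalized matrix, with attributes `scale_factors` and
#'   `medians` (the pre-normalization per-array `median(|x|)`).
#' @export
scale_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1L) stop("need at least one array")
  m_a <- apply(abs(mat), 2L, median, na.rm = TRUE)
  if (any(!is.finite(m_a) | m_a == 0))
    stop("degenerate array (median absolute value 0) at column ",
         which(!is.finite(m_a) | m_a == 0)[1L])
  out <- limma::normalizeMedianAbsValues(mat)
  g <- exp(mean(log(m_a)))
  attr(out, "medians") <- m_a
  attr(out, "scale_factors") <- g / m_a
  out
}

#' Global median centering within each array
#'
#' Subtracts each array's median ("global median within array"); the
#' per-array median of the result is 0. For expression matrices this is
#' applied before [scale_normalize()].
#'
#' @param mat log2 matrix, probes x arrays.
#' @return The centered matrix, with attribute `centers`.
#' @export
median_center <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1L || nrow(mat) == 0L) stop("empty array")
  ctr <- apply(mat, 2L, median, na.rm = TRUE)
  if (any(!is.finite(ctr))) stop("array with no finite values")
  out <- sweep(mat, 2L, ctr, `-`)
  attr(out, "centers") <- ctr
  out
}

#' Dye-balanced per-strain averaging of replicates
#'
#' Arithmetic mean over a strain's replicates of oriented, normalized
#' values; because replicates are labelled in opposite dye orientations
#' this is the Cy-dye balanced average. A probe missing in one replicate
#' averages over the remaining ones; a probe missing everywhere stays
#' missing.
#'
#' @param mat probe x sample matrix (oriented, normalized).
#' @param samples sample table aligned with `mat` columns.
#' @return probe x strain matrix of means.
#' @export
strain_average <- function(mat, samples) {
  strains <- unique(samples$strain)
  out <- vapply(strains, function(s) {
    cols <- which(samples$strain == s)
    if (length(cols) == 0L) stop("zero replicates for strain ", s)
    v <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(nrow(mat)))
  colnames(out) <- strains
  out
}
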