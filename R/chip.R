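#' Clustering parameters for binding-region calling
#'
#' @param max_gap maximum bp between consecutive enriched-probe midpoints
#'   for them to join one cluster (gap-linkage mode), or the maximum
#'   cluster span (span mode). Default 1000 (1 kb contiguity).
#' @param min_probes minimum enriched probes per region (default 2).
#' @param mode `"gap"` (single-linkage with max inter-probe gap; default)
#'   or `"span"` (greedy left-to-right clusters whose total midpoint span
#'   stays within `max_gap`), the alternative reading of 1 kb contiguity.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(max_gap = 1000, min_probes = 2L,
                           mode = c("gap", "span")) {
  if (max_gap <= 0) stop("max_gap must be > 0")
  if (min_probes < 1L) stop("min_probes must be >= 1")
  structure(list(max_gap = max_gap, min_probes = as.integer(min_probes),
                 mode = match.arg(mode)), class = "cluster_params")
}

#' Call enriched probes from the two-strain contrast
#'
#' A probe is a candidate iff its value in the complemented strain exceeds
#' its value in the deletion strain in every replicate pair (strict `>`,
#' paired by replicate index). Its fold change is the difference of
#' strain-averaged values (complemented minus deleted). A candidate is
#' enriched iff its fold change is larger than the data-derived threshold
#' `mean + 1.0 * sd` of the fold changes over all candidates (sample sd,
#' n - 1). Probes with a missing value in any replicate are ineligible as
#' candidates.
#'
#' @param comp probe x replicate matrix for the complemented strain.
#' @param del probe x replicate matrix for the deletion strain (same
#'   replicate count, paired by column index).
#' @return list of class `enriched_probe_set`: `probes` data.frame
#'   (`fold_change`, `is_candidate`, `is_enriched`), `fc_mean`, `fc_sd`,
#'   `threshold`, `n_candidates`.
#' @export
call_enriched_probes <- function(comp, del) {
  comp <- as.matrix(comp); del <- as.matrix(del)
  if (!all(dim(comp) == dim(del)))
    stop("complemented and deleted replicate matrices must be the same shape")
  complete <- stats::complete.cases(comp) & stats::complete.cases(del)
  is_candidate <- complete & rowSums(comp > del) == ncol(comp)
  fold_change <- rowMeans(comp) - rowMeans(del)
  n_cand <- sum(is_candidate)
  if (n_cand < 2L) {
    warning("fewer than 2 candidate probes; sd undefined, no enrichment calls")
    fc_mean <- fc_sd <- threshold <- NA_real_
    is_enriched <- rep(FALSE, nrow(comp))
  } else {
    fc_mean <- mean(fold_change[is_candidate])
    fc_sd <- sd(fold_change[is_candidate])
    threshold <- fc_mean + 1.0 * fc_sd
    is_enriched <- is_candidate & fold_change > threshold
  }
  structure(list(
    probes = data.frame(fold_change = fold_change,
                        is_candidate = is_candidate,
                        is_enriched = is_enriched,
                        row.names = rownames(comp)),
    fc_mean = fc_mean, fc_sd = fc_sd, threshold = threshold,
    n_candidates = n_cand), class = "enriched_probe_set")
}

#' Cluster enriched probes into binding regions
#'
#' Gap-linkage (default): consecutive enriched probes (by midpoint) join
#' one cluster iff their midpoint gap is `<= max_gap`; a gap exactly equal
#' to `max_gap` joins. Clusters with at least `min_probes` members become
#' regions spanning min(start) to max(end) of member probes. Regions are
#' returned sorted and non-overlapping.
#'
#' @param enriched data.frame of enriched probes with columns `probe_id`,
#'   `chrom`, `start`, `end`, `fold_change`.
#' @param params a [cluster_params()].
#' @return data.frame of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `max_fold_change`, `probe_ids` (comma-joined), `shape`
#'   (`"unclassified"` until [classify_peak_shape()]).
#' @export
cluster_regions <- function(enriched, params = cluster_params()) {
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), max_fold_change = numeric(),
                      probe_ids = character(), shape = character(),
                      stringsAsFactors = FALSE)
  if (is.null(enriched) || nrow(enriched) == 0L) return(empty)
  mid <- (enriched$start + enriched$end) / 2
  o <- order(mid)
  enriched <- enriched[o, , drop = FALSE]
  mid <- mid[o]
  if (params$mode == "gap") {
    new_cluster <- c(TRUE, diff(mid) > params$max_gap)
  } else {
    # span mode: greedy left-to-right, cluster midpoint span <= max_gap
    new_cluster <- logical(length(mid))
    anchor <- mid[1L]; new_cluster[1L] <- TRUE
    for (i in seq_along(mid)[-1L]) {
      if (mid[i] - anchor > params$max_gap) {
        new_cluster[i] <- TRUE
        anchor <- mid[i]
      }
    }
  }
  cl <- cumsum(new_cluster)
  keep <- as.integer(names(which(table(cl) >= params$min_probes)))
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(k) which(cl == k))
  out <- data.frame(
    region_id = sprintf("region_%03d", seq_along(keep)),
    chrom = vapply(rows, function(r) enriched$chrom[r[1L]], ""),
    start = vapply(rows, function(r) min(enriched$start[r]), numeric(1)),
    end = vapply(rows, function(r) max(enriched$end[r]), numeric(1)),
    n_probes = lengths(rows),
    max_fold_change = vapply(rows, function(r)
      max(enriched$fold_change[r]), numeric(1)),
    probe_ids = vapply(rows, function(r)
      paste(enriched$probe_id[r], collapse = ","), ""),
    shape = "unclassified", stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Annotate binding regions with genes and a location class
#'
#' `overlapping_genes` are all genes whose span intersects the region.
#' `location_class` is `gene_internal` if at least 50% of the region lies
#' inside a single gene; otherwise `promoter_proximal` if the region
#' intersects the `promoter_window` bp immediately upstream of a gene
#' start on its coding strand; otherwise `intergenic`.
#'
#' @param regions output of [cluster_regions()].
#' @param annotation a [genome_annotation()].
#' @param promoter_window upstream window in bp (default 300).
#' @return `regions` with `overlapping_genes` (comma-joined) and
#'   `location_class` columns.
#' @export
annotate_regions <- function(regions, annotation, promoter_window = 300) {
  if (nrow(regions) == 0L) {
    regions$overlapping_genes <- character(0L)
    regions$location_class <- character(0L)
    return(regions)
  }
  if (nrow(annotation) && !all(regions$chrom %in% annotation$chrom))
    stop("unknown chromosome: ",
         setdiff(regions$chrom, annotation$chrom)[1L])
  rr <- IRanges::IRanges(regions$start, regions$end)
  gr <- IRanges::IRanges(annotation$start, annotation$end)
  ov <- IRanges::findOverlaps(rr, gr)
  ov_by_region <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  up_start <- ifelse(annotation$strand == "+",
                     annotation$start - promoter_window, annotation$end)
  up_end <- ifelse(annotation$strand == "+",
                   annotation$start, annotation$end + promoter_window)
  up <- IRanges::IRanges(pmax(1, up_start), up_end)
  prox <- IRanges::countOverlaps(rr, up) > 0
  regions$overlapping_genes <- ""
  regions$location_class <- "intergenic"
  rw <- regions$end - regions$start + 1
  for (i in seq_len(nrow(regions))) {
    hits <- ov_by_region[[as.character(i)]]
    internal <- FALSE
    if (!is.null(hits)) {
      regions$overlapping_genes[i] <-
        paste(annotation$gene_id[hits], collapse = ",")
      inside <- pmin(regions$end[i], annotation$end[hits]) -
        pmax(regions$start[i], annotation$start[hits]) + 1
      internal <- any(inside / rw[i] >= 0.5)
    }
    regions$location_class[i] <-
      if (internal) "gene_internal"
      else if (prox[i]) "promoter_proximal"
      else "intergenic"
  }
  regions
}

moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(x[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Classify a binding region's peak shape
#'
#' The fold-change profile over the region (extended by `flank` bp on
#' both sides) is smoothed by a centered moving average (default window 3
#' probes, shrinking at the edges). Summit heights are measured above the
#' local background — the median of the smoothed window, dominated by
#' flanking probes — which removes residual constant offsets such as
#' imperfect dye-bias cancellation between the strains. Candidate summits
#' are interior local maxima whose background-corrected height is at
#' least `min_summit_frac` of the region's tallest summit — a relative
#' bar, because shape is a morphological judgement about an
#' already-enriched region, and the minor summit of a genuinely biphasic
#' peak may sit near the enrichment threshold itself. A region is biphasic iff at least two candidate
#' summits survive a prominence test — the trough between two retained
#' maxima must drop below `(1 - min_prominence_frac)` times the smaller
#' maximum — and the retained maxima are at least two probe spacings
#' apart. Otherwise it is monophasic. Summits are the positions of the
#' retained maxima, major summit first. This classification formalizes
#' what is otherwise a visual judgement of tiling-array peak morphology;
#' its parameters are validated against synthetic ground truth.
#'
#' @param region one row of a [cluster_regions()] data.frame.
#' @param profile data.frame of all (QC-retained) probes with `midpoint`
#'   and `fold_change`, covering at least the extended region.
#' @param probe_spacing bp between consecutive probe midpoints.
#' @param smooth_window moving-average window in probes (default 3).
#' @param min_prominence_frac required relative trough depth (default
#'   0.25).
#' @param min_summit_frac minimum summit height as a fraction of the
#'   major summit (default 0.3).
#' @param flank bp by which to extend the region on both sides (default
#'   1000, the clustering gap).
#' @return list with `shape` (`"monophasic"`, `"biphasic"` or
#'   `"unclassified"`) and `summits` (bp, major first).
#' @export
classify_peak_shape <- function(region, profile,
                                probe_spacing = 80,
                                smooth_window = 3L,
                                min_prominence_frac = 0.25,
                                min_summit_frac = 0.3,
                                flank = 1000) {
  sel <- profile$midpoint >= region$start - flank &
    profile$midpoint <= region$end + flank
  p <- profile[sel, , drop = FALSE]
  p <- p[order(p$midpoint), , drop = FALSE]
  if (nrow(p) == 0L || all(is.na(p$fold_change)))
    return(list(shape = "unclassified", summits = numeric(0L)))
  s <- moving_average(p$fold_change, smooth_window)
  n <- length(s)
  # heights are measured above the local background (median of the
  # smoothed window, dominated by flanking probes); this removes any
  # residual constant offset of the fold-change profile, e.g. imperfect
  # dye-bias cancellation between the two strains
  bg <- median(s, na.rm = TRUE)
  h <- s - bg
  is_max <- vapply(seq_len(n), function(i) {
    # window boundary points cannot be summits
    i > 1L && i < n && isTRUE(s[i] > s[i - 1L] && s[i] >= s[i + 1L])
  }, logical(1))
  peaks <- which(is_max & !is.na(h) &
                   h >= min_summit_frac * max(h, na.rm = TRUE))
  if (length(peaks) == 0L)   # degenerate: use global max of the profile
    peaks <- which.max(s)
  # prominence merge: drop the smaller of any adjacent pair whose
  # separating trough is too shallow or which sit too close together
  repeat {
    if (length(peaks) < 2L) break
    merged <- FALSE
    for (j in seq_len(length(peaks) - 1L)) {
      a <- peaks[j]; b <- peaks[j + 1L]
      trough <- min(h[a:b], na.rm = TRUE)
      small <- min(h[a], h[b])
      sep_ok <- (p$midpoint[b] - p$midpoint[a]) >= 2 * probe_spacing
      deep_ok <- trough < (1 - min_prominence_frac) * small
      if (!(sep_ok && deep_ok)) {
        peaks <- peaks[-(j + if (h[a] >= h[b]) 1L else 0L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(s[peaks], decreasing = TRUE)][1:2]
    list(shape = "biphasic", summits = p$midpoint[top2])
  } else {
    list(shape = "monophasic", summits = p$midpoint[peaks[which.max(s[peaks])]])
  }
}
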