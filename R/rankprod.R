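#' Summarize probe signals to per-gene expression
#'
#' The representative expression signal for a gene is the arithmetic mean,
#' per sample, of all good-quality probes whose interval intersects the
#' gene's coding span. A probe spanning two overlapping genes contributes
#' to both means. A gene with zero good probes is missing (NA).
#'
#' @param mat normalized probe x sample matrix (QC-excluded probes
#'   already removed; individually flagged values set to NA upstream).
#' @param probes probe table aligned with `mat` rows (`probe_id`,
#'   `start`, `end`).
#' @param annotation a [genome_annotation()]; must be non-empty.
#' @return gene x sample matrix with attribute `n_probes` (good probes
#'   per gene).
#' @export
gene_signals <- function(mat, probes, annotation) {
  if (nrow(annotation) == 0L) stop("annotation is empty")
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(annotation$start, annotation$end),
    IRanges::IRanges(probes$start, probes$end))
  out <- matrix(NA_real_, nrow(annotation), ncol(mat),
                dimnames = list(annotation$gene_id, colnames(mat)))
  hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  n_probes <- integer(nrow(annotation))
  for (g in names(hits)) {
    i <- as.integer(g)
    rows <- hits[[g]]
    v <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    out[i, ] <- v
    n_probes[i] <- length(rows)
  }
  attr(out, "n_probes") <- setNames(n_probes, annotation$gene_id)
  out
}

rp_from_ranks <- function(rank_mat) {
  # geometric mean across the K comparisons, in log space
  exp(rowMeans(log(rank_mat)))
}

pairwise_diffs <- function(groupA, groupB) {
  G <- nrow(groupA)
  K <- ncol(groupA) * ncol(groupB)
  diffs <- matrix(NA_real_, G, K)
  k <- 0L
  for (i in seq_len(ncol(groupA)))
    for (j in seq_len(ncol(groupB))) {
      k <- k + 1L
      diffs[, k] <- groupA[, i] - groupB[, j]
    }
  diffs
}

direction_ranks <- function(diffs, sign_) {
  # rank 1 = most extreme in this direction; ties = average rank
  apply(diffs * sign_, 2L, function(d) rank(-d))
}

#' Rank Product differential expression with permutation pfp
#'
#' Unpaired two-class Rank Product: all `K = nA * nB` pairwise log
#' differences `A_i - B_j` are formed; within each comparison genes are
#' ranked (rank 1 = most extreme in the tested direction, ties averaged)
#' and each gene's RP is the geometric mean of its K ranks.
#'
#' Significance is estimated from `n_permutations` null datasets obtained
#' by permuting gene labels independently within every replicate array
#' and recomputing all K comparisons. Because the pairwise comparisons
#' share replicates (`A_1 - B_1` and `A_1 - B_2` both contain replicate
#' `A_1`), their ranks are positively dependent; permuting arrays rather
#' than per-comparison ranks preserves that dependence, which is what
#' keeps the pfp estimate calibrated under the null. Each null dataset
#' contributes its RP values in both directions, and the per-array
#' permutations are assigned in a canonical column order, so results are
#' exactly invariant under swapping the two groups. `E_g` is the average
#' count of null RP values at or below `RP_g`, and `pfp_g = E_g /
#' rank_g` where `rank_g` is the gene's position in ascending RP order.
#' pfp values are smoothed by a cumulative minimum from the largest RP
#' downward so pfp is monotone in rank. Both directions (`"up"` = higher
#' in group A, i.e. the complemented strain; `"down"` = lower) are
#' tested. Deterministic given `seed`.
#'
#' @param groupA gene x replicate matrix (complemented strain).
#' @param groupB gene x replicate matrix (deletion strain), same genes.
#' @param n_permutations number of null permutation datasets (default
#'   1000).
#' @param seed integer RNG seed (mandatory; recorded in the result).
#' @return list of class `rank_product_result`: `table` (one row per gene
#'   per direction: `gene_id`, `direction`, `RP`, `rank`, `pfp`),
#'   `n_genes`, `K`, `n_permutations`, `seed`, `dropped` (genes removed
#'   listwise for missing values).
#' @export
rank_product_test <- function(groupA, groupB, n_permutations = 1000L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) != nrow(groupB))
    stop("groupA and groupB must have the same genes")
  ids <- rownames(groupA)
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_len(nrow(groupA)))
  ok <- stats::complete.cases(groupA) & stats::complete.cases(groupB)
  dropped <- ids[!ok]
  groupA <- groupA[ok, , drop = FALSE]
  groupB <- groupB[ok, , drop = FALSE]
  ids <- ids[ok]
  G <- nrow(groupA)
  if (G < 2L) stop("need at least 2 genes with complete values")
  nA <- ncol(groupA); nB <- ncol(groupB)
  K <- nA * nB
  diffs <- pairwise_diffs(groupA, groupB)

  # canonical column order: permutations are drawn per array in an order
  # determined by the array values only, not by group membership, so a
  # group swap reuses the very same null datasets
  cols <- cbind(groupA, groupB)
  sig <- apply(cols, 2L, function(v)
    paste(sprintf("%.17g", v), collapse = ","))
  canon <- order(sig)
  null_sorted <- withr::with_seed(seed, {
    pool <- lapply(seq_len(n_permutations), function(b) {
      perms <- vector("list", nA + nB)
      for (ci in canon) perms[[ci]] <- sample.int(G)
      pcols <- vapply(seq_len(nA + nB),
                      function(ci) cols[perms[[ci]], ci], numeric(G))
      nd <- pairwise_diffs(pcols[, seq_len(nA), drop = FALSE],
                           pcols[, nA + seq_len(nB), drop = FALSE])
      c(rp_from_ranks(direction_ranks(nd, +1)),
        rp_from_ranks(direction_ranks(nd, -1)))
    })
    sort(unlist(pool, use.names = FALSE))
  })

  one_direction <- function(sign_) {
    rp <- rp_from_ranks(direction_ranks(diffs, sign_))
    pos <- rank(rp, ties.method = "first")
    e <- findInterval(rp, null_sorted) / (2 * n_permutations)
    pfp <- e / pos
    ord <- order(rp)
    pfp[ord] <- rev(cummin(rev(pfp[ord])))
    data.frame(gene_id = ids,
               direction = if (sign_ > 0) "up" else "down",
               RP = rp, rank = pos, pfp = pfp, stringsAsFactors = FALSE)
  }
  tab <- rbind(one_direction(+1), one_direction(-1))
  rownames(tab) <- NULL
  structure(list(table = tab, n_genes = G, K = K,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), dropped = dropped),
            class = "rank_product_result")
}

#' @export
print.rank_product_result <- function(x, ...) {
  cat("rank_product_result:", x$n_genes, "genes, K =", x$K,
      "comparisons,", x$n_permutations, "permutations (seed",
      paste0(x$seed, ")\n"))
  invisible(x)
}

#' Select differentially expressed genes at a pfp cutoff
#'
#' A gene is listed in a direction iff its pfp is strictly below the
#' cutoff in that direction; a gene significant in both directions is
#' listed only in the one with the smaller pfp (smaller RP, then "up",
#' break exact ties).
#'
#' @param result a [rank_product_test()] result.
#' @param pfp_cutoff cutoff in (0, 1]; default 0.15.
#' @return list with character vectors `up` and `down` (ordered by RP).
#' @export
select_de <- function(result, pfp_cutoff = 0.15) {
  if (pfp_cutoff <= 0 || pfp_cutoff > 1) stop("pfp_cutoff must be in (0, 1]")
  tab <- result$table
  sig <- tab[tab$pfp < pfp_cutoff, , drop = FALSE]
  if (nrow(sig)) {
    # at most one direction per gene
    sig <- sig[order(sig$gene_id, sig$pfp, sig$RP,
                     match(sig$direction, c("up", "down"))), , drop = FALSE]
    sig <- sig[!duplicated(sig$gene_id), , drop = FALSE]
    sig <- sig[order(sig$RP), , drop = FALSE]
  }
  list(up = sig$gene_id[sig$direction == "up"],
       down = sig$gene_id[sig$direction == "down"])
}

parse_gene_number <- function(gene_id) {
  m <- regmatches(gene_id, regexec("^([A-Za-z]+)([0-9]+)$", gene_id))
  bad <- which(lengths(m) != 3L)
  if (length(bad))
    stop("malformed gene id: ", gene_id[bad[1L]])
  as.numeric(vapply(m, `[`, "", 3L))
}

#' Count DE genes inside a gene-id range
#'
#' Counts listed genes whose numeric id suffix (SCO-style identifiers)
#' falls in the inclusive range, minus an exclusion set (by default the
#' deleted gene itself would be excluded by the caller).
#'
#' @param de_list character vector of gene ids.
#' @param range_lo,range_hi gene ids bounding the cluster (inclusive).
#' @param exclusions character vector of gene ids to ignore.
#' @return integer count.
#' @export
count_in_cluster <- function(de_list, range_lo, range_hi,
                             exclusions = character()) {
  de_list <- setdiff(de_list, exclusions)
  if (length(de_list) == 0L) return(0L)
  n <- parse_gene_number(de_list)
  lo <- parse_gene_number(range_lo)
  hi <- parse_gene_number(range_hi)
  sum(n >= lo & n <= hi)
}
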