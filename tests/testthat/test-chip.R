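test_that("enrichment caller reproduces the hand-computed worked example", {
  fc <- c(0.2, 0.4, 0.6, 0.8, 3.0)
  comp <- cbind(fc, fc)          # both replicates above the deletion strain
  del <- matrix(0, 5, 2)
  eps <- call_enriched_probes(comp, del)
  expect_true(all(eps$probes$is_candidate))
  expect_equal(eps$probes$fold_change, fc)
  expect_equal(eps$fc_mean, 1.0)
  expect_equal(eps$fc_sd, 1.1401754, tolerance = 1e-7)   # n-1 sd
  expect_equal(eps$threshold, 2.1401754, tolerance = 1e-7)
  expect_identical(which(eps$probes$is_enriched), 5L)
})

test_that("candidate rule is strict and paired by replicate index", {
  comp <- rbind(c(1.0, 0.2), c(1.0, 0.6))
  del <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  suppressWarnings(eps <- call_enriched_probes(comp, del))
  expect_identical(unname(eps$probes$is_candidate), c(FALSE, TRUE))
  # equal values in one replicate (strict ">") disqualify
  suppressWarnings(
    eps2 <- call_enriched_probes(rbind(c(1, 0.5), c(1, 1)),
                                 rbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_identical(unname(eps2$probes$is_candidate), c(FALSE, TRUE))
})

test_that("degenerate candidate sets yield no enrichment calls", {
  eps <- call_enriched_probes(matrix(1, 4, 2), matrix(0, 4, 2))
  expect_identical(eps$fc_sd, 0)                 # identical fold changes
  expect_false(any(eps$probes$is_enriched))      # strict > threshold
  expect_warning(call_enriched_probes(rbind(c(1, 1)), rbind(c(0, 0))),
                 "fewer than 2 candidate")
  # probes with missing replicate values are never candidates
  comp <- rbind(c(2, NA), c(2, 2), c(1, 1))
  del <- matrix(0, 3, 2)
  eps3 <- call_enriched_probes(comp, del)
  expect_identical(unname(eps3$probes$is_candidate), c(FALSE, TRUE, TRUE))
})

test_that("threshold is equivariant under constant fold-change shifts", {
  set.seed(12)
  for (i in 1:20) {
    del <- matrix(rnorm(40), 20, 2)
    comp <- del + matrix(abs(rnorm(40)) + 0.1, 20, 2)  # all candidates
    cc <- abs(rnorm(1, 0, 3))   # positive shift preserves candidacy
    a <- call_enriched_probes(comp, del)
    b <- call_enriched_probes(comp + cc, del)
    expect_equal(b$threshold, a$threshold + cc)
    expect_identical(b$probes$is_enriched, a$probes$is_enriched)
  }
})

test_that("gap-linkage clustering matches the worked examples", {
  r <- cluster_regions(enr_df(c(100, 600, 1090)))
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_probes, 3L)
  expect_equal(c(r$start, r$end), c(70, 1120))

  r2 <- cluster_regions(enr_df(c(100, 600, 2000)))
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$probe_ids, "e01,e02")

  # gap exactly max_gap joins (<= boundary)
  r3 <- cluster_regions(enr_df(c(1000, 2000)))
  expect_identical(r3$n_probes, 2L)

  expect_identical(nrow(cluster_regions(enr_df(numeric(0)))), 0L)
})

test_that("clustering equals brute-force transitive closure on random instances", {
  set.seed(101)
  mismatches <- 0L
  for (i in 1:1000) {
    n <- sample(0:30, 1)
    mid <- sort(sample.int(12000, n))
    gap <- sample(c(250, 500, 1000), 1)
    minp <- sample(1:3, 1)
    got <- cluster_regions(enr_df(mid), cluster_params(gap, minp))
    want <- brute_force_clusters(mid, gap, minp)
    ids <- sprintf("e%02d", seq_along(mid))
    got_mids <- lapply(seq_len(nrow(got)), function(j)
      sort(mid[match(strsplit(got$probe_ids[j], ",")[[1]], ids)]))
    if (!isTRUE(all.equal(got_mids, want)))
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("region annotation assigns genes and location classes", {
  ann <- genome_annotation(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr", start = c(250L, 5000L),
    end = c(900L, 6000L), strand = "+", stringsAsFactors = FALSE))
  reg <- function(s, e) data.frame(region_id = "r1", chrom = "chr",
                                   start = s, end = e,
                                   max_fold_change = 1, shape = "u",
                                   n_probes = 2L, probe_ids = "",
                                   stringsAsFactors = FALSE)
  # intersects [gene start - 300, gene start] but <50% inside the gene
  a <- annotate_regions(reg(100, 300), ann, promoter_window = 300)
  expect_identical(a$location_class, "promoter_proximal")
  expect_identical(a$overlapping_genes, "gA")
  b <- annotate_regions(reg(5100, 5400), ann)
  expect_identical(b$location_class, "gene_internal")
  c_ <- annotate_regions(reg(2000, 2400), ann)
  expect_identical(c_$location_class, "intergenic")
  expect_identical(c_$overlapping_genes, "")
  # minus-strand promoter is downstream of the gene end
  ann2 <- genome_annotation(data.frame(gene_id = "gC", chrom = "chr",
                                       start = 1000L, end = 2000L,
                                       strand = "-"))
  d <- annotate_regions(reg(2050, 2150), ann2, promoter_window = 300)
  expect_identical(d$location_class, "promoter_proximal")
  bad <- reg(1, 10); bad$chrom <- "chrX"
  expect_error(annotate_regions(bad, ann), "unknown chromosome")
})

test_that("peak-shape classifier separates mono- and biphasic spikes", {
  mid <- seq(40, 12000, by = 80)
  bi <- true_regions(center = 6000, shape = "biphasic", amplitude = 2,
                     width = 120, peak_separation = 600,
                     amplitude_ratio = 0.5)
  prof <- data.frame(midpoint = mid, fold_change = spike_profile(bi, mid))
  region <- data.frame(start = 5700, end = 6900)
  cls <- classify_peak_shape(region, prof,
                             probe_spacing = 80)
  expect_identical(cls$shape, "biphasic")
  expect_lte(abs(cls$summits[1] - 6000), 80)      # major summit first
  expect_lte(abs(cls$summits[2] - 6600), 80)

  mono <- true_regions(center = 6000, shape = "monophasic", amplitude = 2,
                       width = 120)
  prof2 <- data.frame(midpoint = mid, fold_change = spike_profile(mono, mid))
  cls2 <- classify_peak_shape(region, prof2,
                              probe_spacing = 80)
  expect_identical(cls2$shape, "monophasic")
  expect_length(cls2$summits, 1L)
  expect_lte(abs(cls2$summits - 6000), 80)
})

test_that("shallow troughs are merged into one peak", {
  mid <- seq(100, 1300, by = 100)
  # two maxima 1.0 and 0.9 with a trough at 0.8 > 0.75 * 0.9: monophasic
  fc <- c(0.1, 0.2, 0.5, 1.0, 0.8, 0.9, 0.5, 0.2, 0.1, 0, 0, 0, 0)
  region <- data.frame(start = 300, end = 900)
  cls <- classify_peak_shape(region, data.frame(midpoint = mid,
                                                fold_change = fc),
                             probe_spacing = 100,
                             smooth_window = 1L)
  expect_identical(cls$shape, "monophasic")
  expect_identical(cls$summits, 400)
  # deepen the trough below the prominence bound: biphasic
  fc2 <- fc; fc2[5] <- 0.3
  cls2 <- classify_peak_shape(region, data.frame(midpoint = mid,
                                                 fold_change = fc2),
                              probe_spacing = 100,
                              smooth_window = 1L)
  expect_identical(cls2$shape, "biphasic")
  expect_identical(cls2$summits, c(400, 600))
  # all-missing profile is unclassified
  cls3 <- classify_peak_shape(region,
                              data.frame(midpoint = mid,
                                         fold_change = NA_real_))
  expect_identical(cls3$shape, "unclassified")
})

test_that("enriched probes are always a subset of candidates", {
  set.seed(55)
  for (i in 1:25) {
    comp <- matrix(rnorm(60, 0.3), 30, 2)
    del <- matrix(rnorm(60), 30, 2)
    eps <- call_enriched_probes(comp, del)
    expect_true(all(!eps$probes$is_enriched | eps$probes$is_candidate))
    # contrast asymmetry: candidates cannot exist in both directions
    rev <- call_enriched_probes(del, comp)
    expect_false(any(eps$probes$is_candidate & rev$probes$is_candidate))
  }
})
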