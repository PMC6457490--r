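# Fixtures are built in code; no binary data ships with the package.

# Minimal hand-built bundle: n probes, 2 strains x 2 reps, one timepoint.
tiny_bundle <- function(values, flags = NULL, assay = "chip",
                        timepoint = 14) {
  n <- nrow(values)
  probes <- data.frame(probe_id = sprintf("p%02d", seq_len(n)),
                       chrom = "chr", start = seq_len(n) * 100L - 99L,
                       end = seq_len(n) * 100L - 40L,
                       stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("A_r1", "A_r2", "B_r1", "B_r2"),
    strain = c("A", "A", "B", "B"), timepoint = timepoint,
    replicate = c(1L, 2L, 1L, 2L), assay = assay,
    ip_dye = c("Cy5", "Cy3", "Cy5", "Cy3"), stringsAsFactors = FALSE)
  if (is.null(flags)) flags <- array(FALSE, c(n, 4L, 2L))
  signal_bundle(probes, samples, values, flags)
}

# An empty ground-truth region set (for configs whose genome is too
# small for the 12-region default layout).
no_regions <- function() {
  true_regions(numeric(0), character(0), numeric(0), numeric(0))
}

# Enriched-probe table from midpoints (probes 60 bp wide).
enr_df <- function(mid, fc = rep(1, length(mid))) {
  data.frame(probe_id = sprintf("e%02d", seq_along(mid)),
             chrom = rep("chr", length(mid)),
             start = mid - 30, end = mid + 30, fold_change = fc,
             stringsAsFactors = FALSE)
}

# Independent oracle for single-linkage clustering: transitive closure
# over all probe pairs with midpoint distance <= max_gap, then size filter.
brute_force_clusters <- function(mid, max_gap, min_probes) {
  n <- length(mid)
  if (n == 0L) return(list())
  adj <- abs(outer(mid, mid, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  cl <- split(seq_len(n), comp)
  cl <- cl[lengths(cl) >= min_probes]
  unname(lapply(cl, function(i) sort(mid[i])))
}

# Power study at the study's design scale: a 2000-gene synthetic
# experiment with 50 DE genes at |log2FC| = 1.5 and probe-level noise
# sd 0.4, analysed by the full expression pipeline.
rp_power_run <- function(rng_seed, rp_seed, n_de = 50L,
                         n_permutations = 1000L) {
  cfg <- sim_config(genome_length = 3210000L, n_genes = 2000L,
                    noise_sd = 0.4, timepoints = 14, rng_seed = rng_seed)
  ann <- sim_annotation(cfg)
  de_ids <- ann$gene_id[round(seq(1, nrow(ann), length.out = n_de))]
  eff <- rep(c(1.5, -1.5), length.out = n_de)
  sim <- simulate_dataset(cfg, truth_regions = true_regions(
    numeric(0), character(0), numeric(0), numeric(0)),
    truth_de = true_de(de_ids, 14, eff))
  res <- run_expression_pipeline(sim$expression, sim$annotation,
                                 complemented = cfg$strains[1],
                                 timepoints = 14,
                                 n_permutations = n_permutations,
                                 seed = rp_seed)[[1]]
  up_true <- de_ids[eff > 0]
  dn_true <- de_ids[eff < 0]
  called <- c(res$de$up, res$de$down)
  correct <- sum(res$de$up %in% up_true) + sum(res$de$down %in% dn_true)
  list(sensitivity = sum(de_ids %in% called) / n_de,
       precision = if (length(called)) correct / length(called) else NA,
       n_called = length(called))
}

# Zero-noise fixture with DE genes chosen so per-array medians and
# median-absolute-value order statistics are untouched by the effects
# (baselines far from the relevant cutoffs), making non-DE differences
# exactly tied.
noise_free_sim <- function(rng_seed = 3, timepoint = 18) {
  cfg <- sim_config(noise_sd = 0, flag_rate = 0, dye_bias = 0,
                    rng_seed = rng_seed)
  base <- simulate_dataset(cfg)
  e <- run_expression_pipeline(base$expression, base$annotation,
                               complemented = cfg$strains[1],
                               timepoints = timepoint,
                               n_permutations = 10, seed = 1)
  gm <- rowMeans(e[[1]]$gene_matrix)
  up <- names(sort(gm, decreasing = TRUE))[1:3]
  dn <- names(sort(gm))[1:2]
  stopifnot(all(gm[up] > 1.2), all(gm[dn] < -1.2))
  truth <- true_de(c(up, dn), timepoint, c(1.8, 1.5, 1.2, -1.5, -1.2))
  sim <- simulate_dataset(cfg, truth_de = truth)
  list(cfg = cfg, sim = sim, up = up, down = dn, timepoint = timepoint)
}
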