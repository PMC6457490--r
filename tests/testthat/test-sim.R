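test_that("spike profiles follow the one- and two-Gaussian geometry", {
  mono <- true_regions(center = 5000, shape = "monophasic",
                       amplitude = 2.0, width = 120)
  pos <- seq(3000, 8000, by = 80)
  y <- spike_profile(mono, pos)
  expect_true(all(y >= 0))
  expect_equal(spike_profile(mono, 5000), 2.0)
  expect_lt(spike_profile(mono, 5000 + 10 * 120), 2.0 * 1e-20)

  bi <- true_regions(center = 5000, shape = "biphasic", amplitude = 2.0,
                     width = 120, peak_separation = 600,
                     amplitude_ratio = 0.5)
  # oracle: evaluate the two-Gaussian sum directly at the minor apex
  at_minor <- 2.0 * exp(-600^2 / (2 * 120^2)) + 2.0 * 0.5
  expect_equal(spike_profile(bi, 5600), at_minor)
  expect_equal(spike_profile(bi, 5600), 1.0, tolerance = 1e-5)

  expect_error(spike_profile(true_regions(5000, "monophasic", 2, 120)[
    , c("center", "shape", "amplitude")], 5000), "width")
  expect_error(spike_profile(mono, c(5000, 4000)), "sorted")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(replicates_per_strain = 1), "replicates")
  expect_error(sim_config(probe_spacing = 0), "probe_spacing")
  expect_error(sim_config(genome_length = 500, probe_spacing = 80),
               "genome_length")
  expect_error(sim_config(flag_rate = 1.5), "flag_rate")
  expect_error(sim_config(strains = c("a", "a")), "distinct")
})

test_that("generator rejects truth outside its bounds", {
  cfg <- sim_config(genome_length = 10000)
  bad <- true_regions(center = 9990, shape = "monophasic",
                      amplitude = 2, width = 120)
  expect_error(simulate_dataset(cfg, bad), "outside the genome")
  expect_error(simulate_dataset(cfg, no_regions(),
                                truth_de = true_de("nope", 14, 1)),
               "absent from the generated annotation")
})

test_that("same config and seed give bit-identical datasets", {
  cfg <- sim_config(genome_length = 20000, n_genes = 10, rng_seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$chip$values, b$chip$values)
  expect_identical(a$chip$flags, b$chip$flags)
  expect_identical(a$expression$values, b$expression$values)
  cfg2 <- sim_config(genome_length = 20000, n_genes = 10, rng_seed = 12)
  expect_false(identical(simulate_dataset(cfg2)$chip$values, a$chip$values))
})

test_that("design structure: dye swap, spike only in complemented strain", {
  cfg <- sim_config(genome_length = 20000, n_genes = 10, noise_sd = 0,
                    flag_rate = 0, dye_bias = 0, rng_seed = 5)
  tr <- true_regions(center = 10000, shape = "monophasic", amplitude = 2,
                     width = 120)
  sim <- simulate_dataset(cfg, tr)
  s <- sim$chip$samples
  for (tp in cfg$timepoints)
    for (st in cfg$strains) {
      dyes <- s$ip_dye[s$timepoint == tp & s$strain == st]
      expect_setequal(dyes, c("Cy5", "Cy3"))
    }
  oriented <- orient_bundle(sim$chip)
  comp <- oriented[, s$strain == cfg$strains[1] & s$timepoint == 14]
  del <- oriented[, s$strain == cfg$strains[2] & s$timepoint == 14]
  mid <- (sim$chip$probes$start + sim$chip$probes$end) / 2
  delta <- rowMeans(comp) - rowMeans(del)
  expect_equal(delta, spike_profile(tr, mid), ignore_attr = TRUE)
})

test_that("zero-noise spikes are identified exactly at the threshold", {
  cfg <- sim_config(noise_sd = 0, flag_rate = 0, dye_bias = 0, rng_seed = 9)
  sim <- simulate_dataset(cfg)
  s <- sim$chip$samples
  oriented <- orient_bundle(sim$chip)
  # on oriented zero-noise data the fold change equals the spike exactly
  eps <- call_enriched_probes(
    oriented[, s$strain == cfg$strains[1] & s$timepoint == 14],
    oriented[, s$strain == cfg$strains[2] & s$timepoint == 14])
  mid <- (sim$chip$probes$start + sim$chip$probes$end) / 2
  spike <- rowSums(vapply(seq_len(nrow(sim$truth_regions)), function(i)
    spike_profile(sim$truth_regions[i, ], mid),
    numeric(length(mid))))
  expect_identical(unname(eps$probes$is_enriched),
                   unname(spike > eps$threshold))
  # and the full pipeline's called regions each contain their center
  res <- run_chip_pipeline(sim$chip, sim$annotation,
                           complemented = cfg$strains[1],
                           timepoints = 14)[["14h"]]
  for (cc in sim$truth_regions$center)
    expect_true(any(res$regions$start <= cc & res$regions$end >= cc))
})

test_that("label swap turns enrichment into depletion at spiked loci", {
  cfg <- sim_config(rng_seed = 42, strains = c("del_strain", "comp_strain"))
  tr <- default_true_regions(cfg)
  sim <- simulate_dataset(cfg, tr)   # spike goes to strains[1]
  res <- run_chip_pipeline(sim$chip, sim$annotation,
                           complemented = "comp_strain",
                           timepoints = 14)[["14h"]]
  hit <- vapply(tr$center, function(cc)
    any(res$regions$start <= cc & res$regions$end >= cc), logical(1))
  expect_identical(sum(hit), 0L)
  # strict inequalities cannot hold both ways: no probe is a candidate in
  # both contrast directions
  fwd <- run_chip_pipeline(sim$chip, sim$annotation,
                           complemented = "del_strain",
                           timepoints = 14)[["14h"]]
  expect_false(any(fwd$enrichment$probes$is_candidate &
                     res$enrichment$probes$is_candidate))
})

test_that("truth tables are written as TSV and BED", {
  cfg <- sim_config(genome_length = 20000, n_genes = 10, rng_seed = 2)
  tr <- true_regions(center = c(5000, 12000),
                     shape = c("monophasic", "biphasic"),
                     amplitude = 2, width = 120,
                     peak_separation = c(NA, 600),
                     amplitude_ratio = c(NA, 0.5))
  sim <- simulate_dataset(cfg, tr, true_de(sim_annotation(cfg)$gene_id[1],
                                           14, 1.5))
  dir <- withr::local_tempdir()
  paths <- write_truth(sim, dir)
  expect_true(all(file.exists(paths)))
  bed <- read.delim(file.path(dir, "truth_regions.bed"), header = FALSE)
  expect_identical(nrow(bed), 2L)
  expect_equal(bed$V2, sim$truth_regions$start - 1L)
  expect_equal(bed$V3, sim$truth_regions$end)
})
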