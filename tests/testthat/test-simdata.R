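test_that("sim_config validates its invariants", {
  expect_error(sim_config(migration = 0.6), "migration")
  expect_error(sim_config(founders = 200, deme_size = 100), "founders")
  expect_error(sim_config(class_probs = c(0.5, 0.5, 0.5)), "class_probs")
  expect_error(sim_config(origin = c(9, 1), grid_height = 8), "origin")
  expect_error(sim_config(sample_per_deme = 1000), "sample_per_deme")
  expect_error(simulate_expansion(quick_config(lgm_epoch = 10000)),
               "final generation")
})

test_that("identical config and seed give identical output", {
  s1 <- simulate_expansion(quick_config(seed = 9))
  s2 <- simulate_expansion(quick_config(seed = 9))
  expect_identical(s1$data$genotypes, s2$data$genotypes)
  expect_identical(s1$data$variants, s2$data$variants)
  expect_identical(s1$data$samples, s2$data$samples)
  expect_identical(s1$presence_lgm$values, s2$presence_lgm$values)
  expect_identical(s1$diagnostics, s2$diagnostics)
  s3 <- simulate_expansion(quick_config(seed = 10))
  expect_false(identical(s1$data$genotypes, s3$data$genotypes))
})

test_that("simulated output satisfies its structural invariants", {
  sim <- simulate_expansion(quick_config(seed = 41))
  gs <- sim$data
  # every genotype column appears in the variant table exactly once
  expect_equal(ncol(gs$genotypes), nrow(gs$variants))
  expect_false(any(duplicated(paste(gs$variants$chrom, gs$variants$pos))))
  expect_false(is.unsorted(order(gs$variants$chrom, gs$variants$pos)))
  # no site monomorphic in the sample
  mono <- apply(gs$genotypes, 2, function(x) all(x == 0) || all(x == 2))
  expect_false(any(mono))
  # every sampled individual maps to a colonized deme
  expect_true(all(sim$presence_final$values == 1))
  # presence at the refuge epoch is a subset of the final colonized set
  expect_true(all(sim$presence_lgm$values <= sim$presence_final$values))
  # refuge snapshot taken at the default epoch contains only the origin
  expect_equal(sum(sim$presence_lgm$values), 1)
  expect_equal(refuge_center(sim$presence_lgm),
               c(lon = sim$origin_lonlat[["lon"]],
                 lat = sim$origin_lonlat[["lat"]]))
})

test_that("allele counts are conserved in expectation under pure drift", {
  # single standing locus at frequency 0.5, one generation, no mutation
  freqs <- vapply(1:500, function(s) {
    sim <- simulate_expansion(sim_config(
      grid_width = 1, grid_height = 1, deme_size = 50, founders = 1,
      migration = 0, colonization_interval = 1, post_expansion = 1,
      burn_in = 0, mu = 0, ancestral_Ne = 0, n_standing = 1,
      standing_freq = 0.5, sample_per_deme = 50,
      drop_monomorphic = FALSE, seed = s))
    derived_freqs(sim$data)
  }, numeric(1))
  drift <- mean(freqs) - 0.5
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(drift), 3 * se)
})

test_that("newly founded demes have reduced expected heterozygosity", {
  sim <- simulate_expansion(sim_config(
    grid_width = 6, grid_height = 6, deme_size = 50, founders = 2,
    migration = 0.02, colonization_interval = 10, post_expansion = 20,
    burn_in = 10, ancestral_Ne = 2000, seed = 77))
  ev <- sim$diagnostics$colonization
  expect_gte(nrow(ev), 20)
  succ <- sum(ev$founder_label_het <= ev$source_label_het)
  bt <- binom.test(succ, nrow(ev), p = 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("strong founder bottlenecks leave long autozygous tracts at the edge", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_expansion(sim_config(
      grid_width = 4, grid_height = 4, deme_size = 30, founders = 2,
      migration = 0.02, colonization_interval = 10, post_expansion = 20,
      burn_in = 10, ancestral_Ne = 2000, seed = 100 + s))
    d <- geo_distance_km(sim$data$samples$lon, sim$data$samples$lat,
                         sim$origin_lonlat[["lon"]],
                         sim$origin_lonlat[["lat"]])
    edge <- d >= sort(unique(d), decreasing = TRUE)[2]
    any(sim$diagnostics$max_ibd_tract_bp[edge] >= 5000)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("no founder bottleneck and strong mixing give no diversity gradient", {
  rs <- vapply(1:10, function(s) {
    sim <- simulate_expansion(sim_config(
      grid_width = 4, grid_height = 4, deme_size = 30, founders = 30,
      migration = 0.5, colonization_interval = 10, post_expansion = 30,
      burn_in = 10, ancestral_Ne = 2000, seed = 200 + s))
    gs <- sim$data
    het <- heterozygosity(gs)
    d <- geo_distance_km(gs$samples$lon, gs$samples$lat,
                         sim$origin_lonlat[["lon"]],
                         sim$origin_lonlat[["lat"]])
    gt <- gradient_test(het, gs$samples$lon, gs$samples$lat,
                        sim$origin_lonlat, "het")
    c(gt$r, gt$p)
  }, numeric(2))
  sig_neg <- sum(rs[1, ] < 0 & rs[2, ] < 0.05)
  expect_lte(sig_neg, 3)
  expect_gt(median(rs[1, ]), -0.15)
})

test_that("write_sim_outputs emits VCF with AA/CLASS tags and round-trips", {
  sim <- simulate_expansion(quick_config(seed = 51))
  dir <- withr::local_tempdir()
  paths <- write_sim_outputs(sim, dir)
  expect_true(all(file.exists(paths)))
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), ncol(sim$data$genotypes))
  expect_true(all(grepl("CLASS=(SYN|NONSYN|LOF)", body)))
  expect_true(all(grepl("AA=[ACGT]", body)))

  gs2 <- read_vcf(paths[["vcf"]], samples = read_samples(paths[["samples"]]))
  expect_identical(unname(gs2$genotypes), unname(sim$data$genotypes))
  r2 <- read_ascii_raster(paths[["presence_lgm"]])
  expect_equal(r2$values, sim$presence_lgm$values)

  sim$data$genotypes <- sim$data$genotypes[integer(0), , drop = FALSE]
  expect_error(write_sim_outputs(sim, dir), "no samples")
})
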