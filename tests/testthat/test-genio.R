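vcf_lines <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
  "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", "s1", "s2", "s3", sep = "\t"),
  paste("chr1", 100, ".", "A", "G", ".", "PASS", "AA=A;CLASS=SYN", "GT",
        "0/1", "./.", "1/1", sep = "\t"),
  paste("chr1", 200, ".", "C", "T,G", ".", "PASS", ".", "GT",
        "0/1", "0/0", "0/0", sep = "\t"),
  paste("chr1", 300, ".", "G", "A", ".", "PASS", "AA=A;CLASS=NONSYN", "GT",
        "0|1", "0/0", "1|1", sep = "\t"),
  paste("chr1", 400, ".", "AT", "A", ".", "PASS", ".", "GT",
        "0/1", "0/0", "0/0", sep = "\t"),
  paste("chr2", 50, ".", "T", "C", ".", "PASS", "CLASS=LOF", "GT",
        "0/0", "0/1", "0/0", sep = "\t")
)

test_that("read_vcf converts GT to dosage, skips non-SNPs, parses AA/CLASS", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, path)
  expect_message(gs <- read_vcf(path), "skipped 2")
  expect_equal(dim(gs$genotypes), c(3, 3))
  # chr1:100  0/1 ./. 1/1 -> 1 NA 2
  expect_equal(unname(gs$genotypes[, 1]), c(1L, NA, 2L))
  # phased genotypes handled
  expect_equal(unname(gs$genotypes[, 2]), c(1L, 0L, 2L))
  expect_equal(gs$variants$pos, c(100L, 300L, 50L))
  expect_equal(gs$variants$class, c("SYN", "NONSYN", "LOF"))
  # AA equal to REF, AA equal to ALT, AA absent
  expect_equal(gs$variants$ancestral, c("A", "A", NA))
})

test_that("VCF written by the package round-trips losslessly", {
  sim <- simulate_expansion(quick_config(seed = 21))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$data, path)
  gs2 <- read_vcf(path, samples = sim$data$samples)
  expect_identical(unname(gs2$genotypes), unname(sim$data$genotypes))
  v1 <- sim$data$variants
  rownames(v1) <- NULL
  expect_identical(gs2$variants[names(v1)], v1)
  expect_identical(gs2$samples, sim$data$samples)
})

test_that("geno_set validates dosages, duplicates and coordinates", {
  d <- matrix(c(0L, 3L), 1, 2)
  v <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
                  ancestral = NA, class = "OTHER")
  expect_error(geno_set(d, v), "dosages")
  d2 <- matrix(0L, 1, 2)
  v$pos <- c(5L, 5L)
  expect_error(geno_set(d2, v), "unique")
})

test_that("filter_maf keeps sites with MAF strictly above the threshold", {
  # 10 diploids, one alt allele: freq 0.05 -> removed at 0.10
  d <- matrix(0L, 10, 3)
  d[1, 1] <- 1L       # freq 0.05
  d[1:5, 2] <- 2L     # freq 0.5
  d[1, 3] <- 2L; d[2, 3] <- 1L  # freq 0.15
  gs <- make_gs(d)
  out <- filter_maf(gs, 0.10)
  expect_equal(out$variants$pos, c(2000L, 3000L))
  # threshold 0 removes only monomorphic sites
  d2 <- cbind(d, 0L)
  out2 <- filter_maf(make_gs(d2), 0)
  expect_equal(ncol(out2$genotypes), 3)
  # idempotent
  expect_identical(filter_maf(out, 0.10)$genotypes, out$genotypes)
  expect_error(filter_maf(gs, 0.5), "threshold")
})

test_that("ld_prune removes exactly one of a duplicated pair", {
  set.seed(1)
  d <- matrix(rbinom(200 * 10, 2, 0.4), 200, 10)
  d[, 4] <- d[, 7]  # duplicates in one window
  gs <- make_gs(d)
  out <- ld_prune(gs, window_snps = 10, step_snps = 5, r2_max = 0.2)
  kept <- out$variants$pos / 1000
  expect_equal(sum(c(4, 7) %in% kept), 1)
  # tie on missingness removes the later position
  expect_true(4 %in% kept)
})

test_that("ld_prune keeps mutually uncorrelated sites", {
  d <- cbind(c(0, 2, 0, 2), c(0, 0, 2, 2), c(0, 2, 2, 0))
  expect_equal(abs(cor(d)[lower.tri(cor(d))]), rep(0, 3))
  out <- ld_prune(make_gs(d), window_snps = 3, step_snps = 1, r2_max = 0.2)
  expect_equal(ncol(out$genotypes), 3)
})

test_that("ld_prune window schedule never co-windows distant duplicates", {
  # 60 SNPs, windows of 50 advancing by 10: windows are 1-50, 11-60, 21-60...
  # sites 1 and 55 are never in the same window, so both survive even as
  # exact duplicates; the result is also a fixed point of re-pruning.
  set.seed(42)
  d <- matrix(rbinom(300 * 60, 2, 0.5), 300, 60)
  d[, 55] <- d[, 1]
  gs <- make_gs(d)
  out <- ld_prune(gs, window_snps = 50, step_snps = 10, r2_max = 0.2)
  kept <- out$variants$pos / 1000
  expect_true(all(c(1, 55) %in% kept))
  again <- ld_prune(out, window_snps = 50, step_snps = 10, r2_max = 0.2)
  expect_identical(again$genotypes, out$genotypes)
})

test_that("ld_prune output is invariant to re-pruning on correlated data", {
  set.seed(7)
  base <- matrix(rbinom(80 * 12, 2, 0.5), 80, 12)
  d <- base[, c(1, 1, 2, 3, 3, 3, 4:12)]  # heavy duplication
  d[sample(length(d), 40)] <- NA
  gs <- make_gs(d)
  out <- ld_prune(gs, window_snps = 8, step_snps = 3, r2_max = 0.2)
  again <- ld_prune(out, window_snps = 8, step_snps = 3, r2_max = 0.2)
  expect_identical(out$genotypes, again$genotypes)
})

test_that("derived_freqs polarizes against the ancestral allele", {
  d <- rbind(c(1L, 1L, 1L), c(2L, 2L, 2L), c(0L, 0L, 0L),
             c(0L, 0L, 0L), c(0L, 0L, 0L))  # alt freq 0.3 at all sites
  gs <- make_gs(d, ancestral = c("ref", "alt", "unknown"))
  df <- derived_freqs(gs)
  expect_equal(df, c(0.3, 0.7, NA))
})
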