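test_that("ratio_ns counts carried nonsynonymous vs synonymous sites", {
  # one individual carrying derived alleles at 10 NONSYN and 30 SYN sites
  d <- matrix(1L, 1, 40)
  cls <- c(rep("NONSYN", 10), rep("SYN", 30))
  gs <- make_gs(d, class = cls)
  out <- individual_load(gs)
  expect_equal(out$Pn, 10)
  expect_equal(out$Ps, 30)
  expect_equal(out$ratio_ns, 0.25)
})

test_that("freq_ratio uses mean derived frequency over carried sites", {
  # population of 5 diploids; derived allele counts give frequencies
  # 0.2 and 0.4 at the NONSYN sites, 0.3 and 0.3 at the SYN sites;
  # individual 1 carries a derived allele at all four
  d <- matrix(0L, 5, 4)
  d[1, ] <- 1L
  d[2, 2] <- 2L; d[3, 2] <- 1L   # site 2 total 4/10 = 0.4
  d[2, 3] <- 2L                  # site 3 total 3/10 = 0.3
  d[2, 4] <- 1L; d[3, 4] <- 1L   # site 4 total 3/10 = 0.3
  cls <- c("NONSYN", "NONSYN", "SYN", "SYN")
  gs <- make_gs(d, class = cls)
  expect_equal(derived_freqs(gs), c(0.1, 0.4, 0.3, 0.3))
  out <- individual_load(gs)
  expect_equal(out$fn_bar[1], 0.25)
  expect_equal(out$fs_bar[1], 0.3)
  expect_equal(out$freq_ratio[1], (2 * 0.25) / (2 * 0.3))
})

test_that("lof_dosage sums derived dosages at LOF sites", {
  d <- matrix(c(1L, 2L, 1L), 1, 3)
  gs <- make_gs(d, class = c("LOF", "LOF", "SYN"))
  out <- individual_load(gs)
  expect_equal(out$lof_dosage, 3)
})

test_that("individual_load matches a brute-force per-individual scan", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8; m <- sample(5:20, 1)
    d <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), n, m)
    cls <- sample(c("SYN", "NONSYN", "LOF", "OTHER"), m, replace = TRUE)
    anc <- sample(c("ref", "alt", "unknown"), m, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    if (!any(cls %in% c("SYN", "NONSYN", "LOF") & anc != "unknown")) next
    gs <- make_gs(d, class = cls, ancestral = anc)
    df <- derived_freqs(gs)
    out <- individual_load(gs)
    for (i in seq_len(n)) {
      Pn <- Ps <- 0; fn <- fs <- numeric(0); lof <- 0
      for (j in seq_len(m)) {
        if (is.na(df[j]) || is.na(d[i, j])) next
        dd <- if (anc[j] == "ref") d[i, j] else 2 - d[i, j]
        if (cls[j] == "NONSYN" && dd >= 1) { Pn <- Pn + 1; fn <- c(fn, df[j]) }
        if (cls[j] == "SYN" && dd >= 1) { Ps <- Ps + 1; fs <- c(fs, df[j]) }
        if (cls[j] == "LOF") lof <- lof + dd
      }
      expect_equal(out$Pn[i], Pn)
      expect_equal(out$Ps[i], Ps)
      expect_equal(out$lof_dosage[i], lof)
      if (Pn + Ps > 0) expect_equal(out$ratio_ns[i], Pn / (Pn + Ps))
      else expect_true(is.na(out$ratio_ns[i]))
      if (Ps > 0 && Pn > 0 && mean(fs) > 0)
        expect_equal(out$freq_ratio[i], (Pn * mean(fn)) / (Ps * mean(fs)))
    }
  }
})

test_that("random class labels make E[ratio_ns] the NONSYN proportion", {
  set.seed(23)
  d <- matrix(sample(0:2, 12 * 40, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
              12, 40)
  cls0 <- c(rep("NONSYN", 16), rep("SYN", 24))  # proportion 0.4
  vals <- replicate(200, {
    gs <- make_gs(d, class = sample(cls0))
    mean(individual_load(gs)$ratio_ns, na.rm = TRUE)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.4), 3 * se + 1e-12)
})

test_that("load metrics are invariant to site and individual order", {
  set.seed(3)
  d <- matrix(sample(0:2, 10 * 15, replace = TRUE), 10, 15)
  cls <- sample(c("SYN", "NONSYN", "LOF"), 15, replace = TRUE)
  samples <- data.frame(sample_id = paste0("i", 1:10), site_id = "a",
                        lon = 0, lat = 0)
  gs <- make_gs(d, class = cls, samples = samples)
  out <- individual_load(gs)
  perm_s <- sample(15); perm_i <- sample(10)
  gs2 <- make_gs(d[perm_i, perm_s], class = cls[perm_s],
                 samples = samples[perm_i, ], pos = (1:15 * 1000L)[perm_s])
  out2 <- individual_load(gs2)
  out2 <- out2[match(out$sample_id, out2$sample_id), ]
  rownames(out2) <- NULL
  expect_equal(out2, out)
})

test_that("population_load handles symmetry, absence and counts", {
  # identical NONSYN and SYN spectra within the group -> freq_ratio 1
  d <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L), c(1L, 1L, 1L, 1L))
  gs <- make_gs(d, class = c("NONSYN", "NONSYN", "SYN", "SYN"),
                samples = data.frame(sample_id = paste0("i", 1:3),
                                     site_id = "a", lon = 0, lat = 0))
  out <- population_load(gs)
  expect_equal(out$freq_ratio, 1)
  expect_equal(out$ratio_ns, 0.5)

  # no segregating SYN sites -> undefined sentinel
  d2 <- rbind(c(1L, 2L), c(0L, 2L))
  gs2 <- make_gs(d2, class = c("NONSYN", "SYN"),
                 samples = data.frame(sample_id = c("a1", "a2"),
                                      site_id = "a", lon = 0, lat = 0))
  out2 <- population_load(gs2)
  expect_true(is.na(out2$fs_bar) && is.na(out2$freq_ratio))

  # 3 NONSYN vs 6 SYN segregating -> ratio 1/3
  set.seed(9)
  d3 <- rbind(rep(1L, 9), rep(0L, 9), rep(1L, 9))
  gs3 <- make_gs(d3, class = c(rep("NONSYN", 3), rep("SYN", 6)),
                 samples = data.frame(sample_id = paste0("i", 1:3),
                                      site_id = "a", lon = 0, lat = 0))
  expect_equal(population_load(gs3)$ratio_ns, 1 / 3)

  expect_error(population_load(gs, grouping = c("a", "b", "b")),
               "at least 2")
})
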