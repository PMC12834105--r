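# Independent oracle implementations used to cross-check the package's
# estimators, written as plain per-locus / per-element loops.

# Weir & Cockerham (1984) variance components for two populations,
# scalar arithmetic locus by locus.
wc_fst_brute <- function(d, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  sum_a <- 0
  sum_abc <- 0
  r <- 2
  for (l in seq_len(ncol(d))) {
    n <- p <- h <- numeric(2)
    for (g in 1:2) {
      x <- d[groups == lev[g], l]
      x <- x[!is.na(x)]
      n[g] <- length(x)
      if (n[g] == 0) next
      p[g] <- sum(x) / (2 * n[g])
      h[g] <- mean(x == 1)
    }
    if (n[1] < 1 || n[2] < 1) next
    ptot <- (n[1] * p[1] + n[2] * p[2]) / (n[1] + n[2])
    if (ptot <= 0 || ptot >= 1) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - (n[1]^2 + n[2]^2) / (r * nbar)) / (r - 1)
    pbar <- (n[1] * p[1] + n[2] * p[2]) / (r * nbar)
    s2 <- (n[1] * (p[1] - pbar)^2 + n[2] * (p[2] - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n[1] * h[1] + n[2] * h[2]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  sum_a / sum_abc
}

# Benjamini-Hochberg step-up computed directly from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    shifted <- sub + (sub >= k)
    cbind(k, shifted)
  }))
}

# exhaustive Mantel p-value by enumerating every permutation
mantel_exhaustive <- function(dm_x, dm_y, alternative = "greater") {
  n <- nrow(dm_x)
  lt <- lower.tri(dm_x)
  r_obs <- cor(dm_x[lt], dm_y[lt])
  pm <- all_perms(n)
  r_all <- apply(pm, 1, function(p) cor(dm_x[lt], dm_y[p, p][lt]))
  switch(alternative,
    greater = mean(r_all >= r_obs),
    less = mean(r_all <= r_obs),
    two.sided = mean(abs(r_all) >= abs(r_obs)))
}

# random symmetric distance-like matrix with zero diagonal
rand_dist_matrix <- function(n) {
  pts <- matrix(runif(2 * n), n, 2)
  as.matrix(dist(pts))
}

# build a geno_set from a dosage matrix with minimal metadata
make_gs <- function(d, class = rep("OTHER", ncol(d)),
                    ancestral = rep("ref", ncol(d)), samples = NULL,
                    pos = NULL) {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000L
  ref <- rep("A", ncol(d))
  alt <- rep("G", ncol(d))
  anc <- ifelse(ancestral == "ref", "A", ifelse(ancestral == "alt", "G", NA))
  v <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                  ancestral = anc, class = class, stringsAsFactors = FALSE)
  geno_set(d, v, samples)
}

# small, fast simulator configuration for unit tests
quick_config <- function(...) {
  sim_config(grid_width = 4, grid_height = 4, deme_size = 30,
             founders = 5, migration = 0.02, colonization_interval = 10,
             post_expansion = 40, burn_in = 10, ancestral_Ne = 2000,
             sample_per_deme = 2, ...)
}
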