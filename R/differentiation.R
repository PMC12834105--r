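#' Weir-Cockerham (1984) FST between two groups
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are combined
#' as `sum(a) / sum(a + b + c)` over loci polymorphic in the pooled pair;
#' monomorphic loci are skipped. Negative estimates are retained (they are
#' informative small-differentiation outcomes, not errors).
#'
#' @param gs A [geno_set()] (or plain dosage matrix).
#' @param groups Two-level vector assigning each individual to a group.
#' @return Scalar FST estimate.
#' @export
wc_fst <- function(gs, groups) {
  d <- if (inherits(gs, "geno_set")) gs$genotypes else as.matrix(gs)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  d1 <- d[groups == lev[1], , drop = FALSE]
  d2 <- d[groups == lev[2], , drop = FALSE]
  if (nrow(d1) < 2 || nrow(d2) < 2)
    stop("both groups need at least 2 individuals")

  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)

  ptot <- (n1 * p1 + n2 * p2) / (n1 + n2)
  use <- n1 >= 1 & n2 >= 1 & !is.na(ptot) & ptot > 0 & ptot < 1
  nbar <- (n1 + n2) / 2
  use <- use & nbar > 1
  if (!any(use)) stop("no usable polymorphic loci shared by the two groups")

  n1 <- n1[use]; n2 <- n2[use]; p1 <- p1[use]; p2 <- p2[use]
  h1 <- h1[use]; h2 <- h2[use]
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cw <- hbar / 2
  denom <- sum(a + b + cw)
  if (denom == 0) stop("degenerate loci: zero total variance")
  sum(a) / denom
}

#' Pairwise FST matrix between sampling sites
#'
#' @param gs A [geno_set()] with a sample table.
#' @param min_per_site Minimum individuals per site (smaller sites dropped).
#' @return Symmetric labeled matrix of Weir-Cockerham FST estimates.
#' @export
fst_matrix <- function(gs, min_per_site = 2) {
  if (is.null(gs$samples)) stop("geno_set has no sample table")
  grp <- gs$samples$site_id
  sites <- names(which(table(grp) >= min_per_site))
  sites <- sites[order(sites)]
  if (length(sites) < 2) stop("need at least 2 sites with enough individuals")
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)[-length(sites)])
    for (j in seq.int(i + 1, length(sites))) {
      keep <- grp %in% c(sites[i], sites[j])
      f <- wc_fst(gs$genotypes[keep, , drop = FALSE], grp[keep])
      m[i, j] <- m[j, i] <- f
    }
  m
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @export
geo_distance_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lon1, lon2)) > 180) || any(abs(c(lat1, lat2)) > 90))
    stop("invalid coordinates")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Pairwise great-circle distance matrix
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param labels Optional dimnames.
#' @return Symmetric matrix of distances in km.
#' @export
geo_distance_matrix <- function(lon, lat, labels = NULL) {
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371.0088))
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Mantel permutation test
#'
#' Pearson correlation between the strictly-lower-triangle entries of two
#' conformable distance matrices, with significance from simultaneous
#' row/column permutation of the second matrix:
#' `p = (1 + #permutations at least as extreme) / (1 + n_perm)`.
#'
#' @param dm_x,dm_y Square symmetric matrices with identical ordering.
#' @param n_perm Number of permutations.
#' @param alternative `"greater"` (the isolation-by-distance default),
#'   `"less"`, or `"two.sided"`.
#' @param seed Optional integer; when given, the permutation stream is
#'   seeded locally and the caller's RNG state is untouched.
#' @return List with `r`, `p`, `n_perm`, `alternative`, `perm_r`.
#' @export
mantel_test <- function(dm_x, dm_y, n_perm = 9999,
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL) {
  alternative <- match.arg(alternative)
  dm_x <- as.matrix(dm_x); dm_y <- as.matrix(dm_y)
  n <- nrow(dm_x)
  if (n < 3) stop("need at least 3 sites")
  if (!all(dim(dm_x) == dim(dm_y))) stop("matrices not conformable")
  lt <- lower.tri(dm_x)
  x <- dm_x[lt]
  r_obs <- stats::cor(x, dm_y[lt])
  perm_r <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      stats::cor(x, dm_y[p, p][lt])
    }, numeric(1))
  })
  hits <- switch(alternative,
    greater = sum(perm_r >= r_obs),
    less = sum(perm_r <= r_obs),
    two.sided = sum(abs(perm_r) >= abs(r_obs)))
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
       alternative = alternative, perm_r = perm_r)
}

# linearize FST -> FST/(1-FST); FST = 1 maps to +Inf, replaced by the
# largest finite value plus a rank-preserving epsilon
linearize_fst <- function(m) {
  lin <- m / (1 - m)
  diag(lin) <- 0
  inf <- !is.finite(lin) & m >= 1
  if (any(inf)) {
    fin <- lin[is.finite(lin)]
    top <- if (length(fin)) max(fin) else 0
    lin[inf] <- top + 1e-6 * max(1, abs(top))
    message(sprintf("linearize_fst: %d entries at FST = 1 capped",
                    sum(inf) / 2))
  }
  lin
}

#' Isolation-by-distance test
#'
#' Applies the standard SNP filters (MAF > `maf`, then LD pruning), builds
#' the linearized genetic distance matrix `FST/(1-FST)` between sampling
#' sites and the great-circle geographic distance matrix between site mean
#' coordinates, and runs the Mantel permutation test.
#'
#' @param gs A [geno_set()] with a sample table.
#' @param maf MAF threshold passed to [filter_maf()].
#' @param window_snps,step_snps,r2_max Passed to [ld_prune()].
#' @param min_per_site Minimum individuals per sampling site.
#' @inheritParams mantel_test
#' @return List: `r`, `p`, `n_sites`, `n_snps_used`, `n_perm`,
#'   `alternative`, `genetic` and `geographic` distance matrices.
#' @export
ibd_test <- function(gs, maf = 0.10, window_snps = 50, step_snps = 10,
                     r2_max = 0.2, min_per_site = 2, n_perm = 9999,
                     alternative = "greater", seed = NULL) {
  if (is.null(gs$samples)) stop("geno_set has no sample table")
  sizes <- table(gs$samples$site_id)
  eligible <- names(which(sizes >= min_per_site))
  if (length(eligible) < 3)
    stop("need at least 3 sampling sites with enough individuals")
  keep <- gs$samples$site_id %in% eligible
  gs <- geno_set(gs$genotypes[keep, , drop = FALSE], gs$variants,
                 gs$samples[keep, , drop = FALSE])
  gs2 <- ld_prune(filter_maf(gs, maf), window_snps, step_snps, r2_max)
  if (ncol(gs2$genotypes) == 0) stop("no SNPs survive filtering")

  fst <- fst_matrix(gs2, min_per_site)
  gen <- linearize_fst(fst)
  agg <- aggregate(gs$samples[c("lon", "lat")],
                   by = list(site_id = gs$samples$site_id), FUN = mean)
  agg <- agg[match(rownames(gen), agg$site_id), ]
  geo <- geo_distance_matrix(agg$lon, agg$lat, labels = agg$site_id)
  mt <- mantel_test(geo, gen, n_perm = n_perm, alternative = alternative,
                    seed = seed)
  list(r = mt$r, p = mt$p, n_sites = nrow(gen),
       n_snps_used = ncol(gs2$genotypes), n_perm = n_perm,
       alternative = mt$alternative, genetic = gen, geographic = geo)
}
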