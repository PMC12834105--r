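#' Per-individual heterozygosity
#'
#' The fraction of an individual's called genotypes at variant sites that
#' are heterozygous: `H_i = #het / (#hom + #het)`. Missing genotypes are
#' excluded from both counts. Individuals with zero called sites get `NA`
#' with a message.
#'
#' @param gs A [geno_set()].
#' @return Named numeric vector in `[0, 1]`, one value per individual.
#' @export
heterozygosity <- function(gs) {
  d <- gs$genotypes
  called <- rowSums(!is.na(d))
  het <- rowSums(d == 1L, na.rm = TRUE)
  out <- ifelse(called > 0, het / called, NA_real_)
  if (any(called == 0))
    message(sprintf("heterozygosity: %d individuals with no called sites",
                    sum(called == 0)))
  setNames(out, sample_ids(gs))
}

#' Detect runs of homozygosity (windowed, PLINK-style)
#'
#' For each individual and chromosome, a sliding window of `window_snps`
#' consecutive SNPs passes if it contains at most `window_het_max`
#' heterozygous and `window_miss_max` missing genotypes. Each SNP's hit
#' fraction is the proportion of windows covering it that pass; SNPs with
#' hit fraction >= `hit_frac` are ROH-eligible, so isolated heterozygotes
#' absorbed by the window tolerance do not split a run. Maximal runs of
#' consecutive eligible SNPs, trimmed so that both end SNPs are
#' non-heterozygous, are reported when they contain at least `min_snps`
#' SNPs and span at least `min_length_bp`. Segment bounds are the first
#' and last SNP positions (end exclusive at last + 1). Chromosomes with
#' fewer than `window_snps` SNPs yield no calls.
#'
#' @param gs A [geno_set()].
#' @param window_snps,window_het_max,window_miss_max Window definition.
#' @param hit_frac Minimum passing-window fraction for SNP eligibility.
#' @param min_snps,min_length_bp Segment reporting thresholds; the default
#'   5 kb floor makes the 5 kb - 1 Mb ROH age band reachable.
#' @return Data frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (half-open), `n_snps`, `length_bp`.
#' @export
detect_roh <- function(gs, window_snps = 50, window_het_max = 1,
                       window_miss_max = 5, hit_frac = 0.05,
                       min_snps = 25, min_length_bp = 5000) {
  ids <- sample_ids(gs)
  chroms <- unique(gs$variants$chrom)
  segs <- list()
  short_chroms <- 0L
  for (ch in chroms) {
    idx <- which(gs$variants$chrom == ch)
    pos <- gs$variants$pos[idx]
    n <- length(idx)
    if (n < window_snps) {
      short_chroms <- short_chroms + 1L
      next
    }
    w <- window_snps
    nw <- n - w + 1L
    # number of windows covering SNP j
    cover <- pmin(seq_len(n), nw) - pmax(seq_len(n) - w + 1L, 1L) + 1L
    for (i in seq_along(ids)) {
      d <- gs$genotypes[i, idx]
      het <- !is.na(d) & d == 1L
      mis <- is.na(d)
      chet <- c(0L, cumsum(het))
      cmis <- c(0L, cumsum(mis))
      win_start <- seq_len(nw)
      pass <- (chet[win_start + w] - chet[win_start]) <= window_het_max &
        (cmis[win_start + w] - cmis[win_start]) <= window_miss_max
      cpass <- c(0L, cumsum(pass))
      lo <- pmax(seq_len(n) - w + 1L, 1L)
      hi <- pmin(seq_len(n), nw)
      n_pass <- cpass[hi + 1L] - cpass[lo]
      elig <- (n_pass / cover) >= hit_frac
      r <- rle(elig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        s0 <- starts[k]; e0 <- ends[k]
        while (s0 <= e0 && het[s0]) s0 <- s0 + 1L  # trim het ends
        while (e0 >= s0 && het[e0]) e0 <- e0 - 1L
        len_snps <- e0 - s0 + 1L
        if (len_snps < min_snps) next
        sb <- pos[s0]
        eb <- pos[e0] + 1L
        if (eb - sb < min_length_bp) next
        segs[[length(segs) + 1L]] <- data.frame(
          sample_id = ids[i], chrom = ch, start_bp = sb, end_bp = eb,
          n_snps = len_snps, length_bp = eb - sb, stringsAsFactors = FALSE)
      }
    }
  }
  if (short_chroms > 0)
    message(sprintf(
      "detect_roh: %d chromosomes with fewer than %d SNPs skipped",
      short_chroms, window_snps))
  if (length(segs) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Summarise ROH per individual within a length band
#'
#' Counts segments with `lo_bp <= length_bp < hi_bp` (closed below, open
#' above); the default band, 5 kb to 1 Mb, targets ROH old enough to date
#' historical inbreeding rather than very recent consanguinity.
#'
#' @param segments Segment table from [detect_roh()].
#' @param ids Sample ids to report (individuals without segments get 0).
#' @param lo_bp,hi_bp Length band in bp.
#' @return Data frame: `sample_id`, `roh_count`, `roh_total_bp`.
#' @export
roh_summary <- function(segments, ids = unique(segments$sample_id),
                        lo_bp = 5000, hi_bp = 1e6) {
  inband <- segments[segments$length_bp >= lo_bp &
                       segments$length_bp < hi_bp, , drop = FALSE]
  cnt <- table(factor(inband$sample_id, levels = ids))
  tot <- tapply(inband$length_bp, factor(inband$sample_id, levels = ids),
                sum, default = 0)
  data.frame(sample_id = ids,
             roh_count = as.integer(cnt[ids]),
             roh_total_bp = as.numeric(tot[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age of a ROH segment in generations
#'
#' `g = 100 / (2 * length_cM)`, with the genetic length obtained from the
#' physical length via `cM_per_Mb`. A 1 Mb tract at 1 cM/Mb dates to ~50
#' generations; a 5 kb tract to ~10,000.
#'
#' @param length_bp Segment length(s) in bp (> 0).
#' @param cM_per_Mb Recombination rate.
#' @return Age(s) in generations.
#' @export
roh_age <- function(length_bp, cM_per_Mb = 1.0) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  length_cM <- length_bp * cM_per_Mb / 1e6
  100 / (2 * length_cM)
}

#' Write ROH segments as BED (0-based half-open) with a sample_id column
#'
#' @param segments Segment table from [detect_roh()].
#' @param path Output path.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp - 1L,
                    sample_id = segments$sample_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
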