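#' Genotype/variant/sample container
#'
#' The core data model: a diploid alternate-allele dosage matrix
#' (individuals x sites, values 0/1/2 or `NA`), a variant table (one row
#' per site: `chrom`, `pos` 1-based, `ref`, `alt`, `ancestral` base or `NA`
#' when unknown, `class` in SYN/NONSYN/LOF/OTHER) sorted by
#' `(chrom, pos)`, and an optional sample table (`sample_id`, `site_id`,
#' `lon`, `lat`).
#'
#' @param genotypes Integer matrix of dosages, individuals in rows.
#' @param variants Data frame with one row per genotype column.
#' @param samples Optional data frame with one row per genotype row.
#' @return An object of class `geno_set`.
#' @export
geno_set <- function(genotypes, variants, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) != nrow(variants))
    stop("genotype columns and variant rows differ")
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) stop("(chrom, pos) must be unique")
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
    rownames(variants) <- NULL
  }
  colnames(genotypes) <- paste0(variants$chrom, ":", variants$pos)
  if (!is.null(samples)) {
    if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
    if (nrow(samples) != nrow(genotypes))
      stop("sample table and genotype rows differ")
    if (any(samples$lon < -180 | samples$lon > 180, na.rm = TRUE) ||
        any(samples$lat < -90 | samples$lat > 90, na.rm = TRUE))
      stop("coordinates out of range")
    rownames(genotypes) <- samples$sample_id
  }
  structure(list(genotypes = genotypes, variants = variants,
                 samples = samples), class = "geno_set")
}

#' @method print geno_set
#' @export
print.geno_set <- function(x, ...) {
  cat(sprintf("geno_set: %d individuals x %d biallelic sites\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  classes: %s\n",
              paste(names(table(x$variants$class)), table(x$variants$class),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$samples))
    cat(sprintf("  %d sampling sites\n", length(unique(x$samples$site_id))))
  invisible(x)
}

sample_ids <- function(gs) {
  if (!is.null(gs$samples)) return(gs$samples$sample_id)
  rn <- rownames(gs$genotypes)
  if (is.null(rn)) rn <- paste0("ind", seq_len(nrow(gs$genotypes)))
  rn
}

subset_sites <- function(gs, keep) {
  geno_set(gs$genotypes[, keep, drop = FALSE],
           gs$variants[keep, , drop = FALSE], gs$samples)
}

#' Read a VCF into a geno_set
#'
#' Biallelic SNP records are converted to diploid alternate-allele dosages;
#' multi-allelic and non-SNP records are skipped with a reported count.
#' `AA` (ancestral allele) and `CLASS` (SYN/NONSYN/LOF) INFO tags are
#' parsed when present; otherwise the ancestral state is unknown and the
#' class is OTHER. Missing genotypes become `NA`.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param samples Optional sample table (e.g. from [read_samples()]) to
#'   attach; must cover every VCF individual.
#' @return A [geno_set()].
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records")
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(sprintf("read_vcf: skipped %d multi-allelic or non-SNP records",
                    n_skip))
  if (!any(snp)) stop("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos <- matrix(lookup[gt], nrow = nrow(gt), ncol = ncol(gt))
  geno <- t(dos)
  rownames(geno) <- colnames(gt)

  info <- fix$INFO[snp]
  aa <- extract_info_tag(info, "AA")
  cls <- extract_info_tag(info, "CLASS")
  cls[!cls %in% c("SYN", "NONSYN", "LOF")] <- "OTHER"
  ref <- fix$REF[snp]; alt <- fix$ALT[snp]
  anc <- ifelse(!is.na(aa) & (aa == ref | aa == alt), aa, NA_character_)

  variants <- data.frame(chrom = fix$CHROM[snp],
                         pos = as.integer(fix$POS[snp]),
                         ref = ref, alt = alt, ancestral = anc, class = cls,
                         stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    m <- match(rownames(geno), samples$sample_id)
    if (anyNA(m)) stop("sample table is missing VCF individuals")
    samples <- samples[m, , drop = FALSE]
    rownames(samples) <- NULL
  }
  geno_set(geno, variants, samples)
}

extract_info_tag <- function(info, tag) {
  hit <- regexpr(paste0("(^|;)", tag, "=[^;]*"), info)
  val <- rep(NA_character_, length(info))
  val[hit > 0] <- sub(paste0("^;?", tag, "="), "", regmatches(info, hit))
  val
}

#' Write a geno_set as VCF 4.2
#'
#' Emits diploid `GT` genotypes with `AA` and `CLASS` INFO tags; the
#' output round-trips losslessly through [read_vcf()].
#'
#' @param gs A [geno_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gs, path) {
  if (nrow(gs$genotypes) == 0) stop("geno_set contains no individuals")
  v <- gs$variants
  ids <- sample_ids(gs)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(gs$genotypes)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=refugia",
    "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
    paste0("##INFO=<ID=CLASS,Number=1,Type=String,Description=",
           "\"Functional class: SYN, NONSYN or LOF\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  info <- ifelse(is.na(v$ancestral), paste0("CLASS=", v$class),
                 paste0("AA=", v$ancestral, ";CLASS=", v$class))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gs$genotypes), ncol(gs$genotypes))
  ok <- !is.na(gs$genotypes)
  gt[ok] <- gt_code[gs$genotypes[ok] + 1L]
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample table
#'
#' CSV with columns `sample_id`, `site_id`, `lon`, `lat` (degrees E / N).
#'
#' @param path CSV path.
#' @return Data frame with the four columns, validated.
#' @export
read_samples <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "lon", "lat")
  if (!all(need %in% names(s)))
    stop("sample CSV must have columns sample_id, site_id, lon, lat")
  s <- s[need]
  if (anyDuplicated(s$sample_id)) stop("sample_ids must be unique")
  if (any(s$lon < -180 | s$lon > 180) || any(s$lat < -90 | s$lat > 90))
    stop("coordinates out of range")
  s
}

#' @rdname read_samples
#' @param samples Sample data frame.
#' @export
write_samples <- function(samples, path) {
  write.csv(samples[c("sample_id", "site_id", "lon", "lat")], path,
            row.names = FALSE)
  invisible(path)
}

# alternate-allele frequency per site over non-missing alleles
alt_freq <- function(genotypes) {
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Filter sites by minor-allele frequency
#'
#' Retains sites whose minor-allele frequency, computed over non-missing
#' alleles, is strictly greater than `threshold`.
#'
#' @param gs A [geno_set()].
#' @param threshold MAF threshold in `[0, 0.5)`; the analysis default is
#'   0.10 (sites with MAF > 10\% kept).
#' @return A filtered [geno_set()].
#' @export
filter_maf <- function(gs, threshold = 0.10) {
  if (threshold < 0 || threshold >= 0.5) stop("threshold must be in [0, 0.5)")
  af <- alt_freq(gs$genotypes)
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf > threshold
  subset_sites(gs, keep)
}

#' LD-prune sites (indep-pairwise style)
#'
#' Slides a window of `window_snps` SNPs advancing by `step_snps` along each
#' chromosome; within a window, while any pair of sites has squared Pearson
#' genotype (dosage) correlation above `r2_max`, the member of the offending
#' pair with the lower non-missing count is removed (ties remove the later
#' position). Missing entries are pairwise-deleted. The pass is repeated on
#' the surviving set until it is a fixed point, so the result is invariant
#' to re-pruning with the same parameters.
#'
#' @param gs A [geno_set()] with sites sorted by `(chrom, pos)`.
#' @param window_snps,step_snps,r2_max Window size, step and r^2 ceiling;
#'   the defaults mirror PLINK's `--indep-pairwise 50 10 0.2`.
#' @return A pruned [geno_set()].
#' @export
ld_prune <- function(gs, window_snps = 50, step_snps = 10, r2_max = 0.2) {
  keep_idx <- seq_len(ncol(gs$genotypes))
  repeat {
    removed <- ld_prune_pass(gs$genotypes[, keep_idx, drop = FALSE],
                             gs$variants$chrom[keep_idx],
                             window_snps, step_snps, r2_max)
    if (!any(removed)) break
    keep_idx <- keep_idx[!removed]
  }
  subset_sites(gs, keep_idx)
}

# one pruning pass; returns logical vector of removals
ld_prune_pass <- function(d, chrom, window_snps, step_snps, r2_max) {
  n <- ncol(d)
  drop <- rep(FALSE, n)
  if (n < 2) return(drop)
  nm <- colSums(!is.na(d))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nc <- length(idx)
    starts <- seq(1L, nc, by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, nc)]
      repeat {
        act <- win[!drop[win]]
        if (length(act) < 2) break
        cc <- suppressWarnings(stats::cor(d[, act, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        r2 <- cc^2
        r2[!is.finite(r2)] <- 0
        r2[lower.tri(r2, diag = TRUE)] <- 0
        off <- which(r2 > r2_max, arr.ind = TRUE)
        if (nrow(off) == 0) break
        o <- off[order(off[, 1], off[, 2]), , drop = FALSE][1, ]
        i <- act[o[1]]; j <- act[o[2]]
        drop[if (nm[i] < nm[j]) i else j] <- TRUE
      }
    }
  }
  drop
}

#' Per-site derived-allele frequency
#'
#' Polarizes alternate-allele frequencies against the ancestral-allele
#' annotation: frequency of the non-ancestral allele, or `NA` where the
#' ancestral state is unknown (such sites are excluded from load metrics).
#'
#' @param gs A [geno_set()].
#' @return Numeric vector, one value per site (NA = unpolarizable).
#' @export
derived_freqs <- function(gs) {
  af <- alt_freq(gs$genotypes)
  v <- gs$variants
  out <- rep(NA_real_, length(af))
  anc_is_ref <- !is.na(v$ancestral) & v$ancestral == v$ref
  anc_is_alt <- !is.na(v$ancestral) & v$ancestral == v$alt
  out[anc_is_ref] <- af[anc_is_ref]
  out[anc_is_alt] <- 1 - af[anc_is_alt]
  out
}

# derived-allele dosage matrix (NA where ancestral unknown or genotype missing)
derived_dosage <- function(gs) {
  v <- gs$variants
  d <- gs$genotypes
  out <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
  anc_is_ref <- !is.na(v$ancestral) & v$ancestral == v$ref
  anc_is_alt <- !is.na(v$ancestral) & v$ancestral == v$alt
  out[, anc_is_ref] <- d[, anc_is_ref, drop = FALSE]
  out[, anc_is_alt] <- 2L - d[, anc_is_alt, drop = FALSE]
  out
}
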