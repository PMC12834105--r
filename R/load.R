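#' Per-individual genetic-load statistics
#'
#' Three complementary proxies for the burden of deleterious variation,
#' computed from derived-allele polarization and functional classes:
#' \describe{
#'   \item{`ratio_ns = Pn/(Pn+Ps)`}{`Pn` and `Ps` count the nonsynonymous
#'     and synonymous polymorphic sites at which the individual carries at
#'     least one derived allele; higher values indicate more retained
#'     nonsynonymous (putatively deleterious) variation.}
#'   \item{`freq_ratio = (Pn*fn_bar)/(Ps*fs_bar)`}{`fn_bar` and `fs_bar`
#'     are the mean population derived-allele frequencies over those same
#'     carried sites; the product contrasts the frequency spectrum of
#'     presumed-deleterious alleles with the presumed-neutral one and rises
#'     with drift.}
#'   \item{`lof_dosage`}{sum of derived-allele dosages at loss-of-function
#'     sites.}
#' }
#' Sites with unknown ancestral state are excluded. Undefined values
#' (e.g. `Pn + Ps = 0`, or `Ps * fs_bar = 0`) are returned as `NA` and
#' excluded from downstream interpolation and correlation.
#'
#' @param gs A [geno_set()] whose variants carry `class` and `ancestral`.
#' @param nonsyn_includes_lof Treat LOF sites as nonsynonymous too
#'   (default FALSE: NONSYN means missense only).
#' @return Data frame: `sample_id`, `Pn`, `Ps`, `fn_bar`, `fs_bar`,
#'   `ratio_ns`, `freq_ratio`, `lof_dosage`.
#' @export
individual_load <- function(gs, nonsyn_includes_lof = FALSE) {
  df <- derived_freqs(gs)
  cls <- gs$variants$class
  usable <- !is.na(df) & cls %in% c("SYN", "NONSYN", "LOF")
  if (!any(usable))
    stop("no classified sites with known ancestral state")
  dd <- derived_dosage(gs)
  mask_n <- usable & (cls == "NONSYN" | (nonsyn_includes_lof & cls == "LOF"))
  mask_s <- usable & cls == "SYN"
  mask_l <- usable & cls == "LOF"

  carried <- !is.na(dd) & dd >= 1L
  Pn <- rowSums(carried[, mask_n, drop = FALSE])
  Ps <- rowSums(carried[, mask_s, drop = FALSE])
  fn_sum <- as.numeric(carried[, mask_n, drop = FALSE] %*% df[mask_n])
  fs_sum <- as.numeric(carried[, mask_s, drop = FALSE] %*% df[mask_s])
  fn_bar <- ifelse(Pn > 0, fn_sum / Pn, NA_real_)
  fs_bar <- ifelse(Ps > 0, fs_sum / Ps, NA_real_)
  ratio_ns <- ifelse(Pn + Ps > 0, Pn / (Pn + Ps), NA_real_)
  denom <- Ps * fs_bar
  freq_ratio <- ifelse(!is.na(denom) & denom > 0 & Pn > 0 & !is.na(fn_bar),
                       (Pn * fn_bar) / denom, NA_real_)
  lof_dosage <- rowSums(dd[, mask_l, drop = FALSE], na.rm = TRUE)
  data.frame(sample_id = sample_ids(gs), Pn = Pn, Ps = Ps,
             fn_bar = fn_bar, fs_bar = fs_bar, ratio_ns = ratio_ns,
             freq_ratio = freq_ratio, lof_dosage = lof_dosage,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Population-level genetic load per sampling site
#'
#' The population analogue of [individual_load()] for sensitivity checks:
#' within each group, `Pn` and `Ps` count the nonsynonymous and synonymous
#' sites segregating in the group (derived frequency strictly between 0
#' and 1), and `fn_bar`, `fs_bar` are the mean group derived frequencies
#' over those sites; the ratio definitions are unchanged.
#'
#' @param gs A [geno_set()].
#' @param grouping Factor-like vector mapping individuals to groups;
#'   defaults to `samples$site_id`.
#' @inheritParams individual_load
#' @return Data frame with one row per group: `site_id`, `n`, `Pn`, `Ps`,
#'   `fn_bar`, `fs_bar`, `ratio_ns`, `freq_ratio`.
#' @export
population_load <- function(gs, grouping = NULL,
                            nonsyn_includes_lof = FALSE) {
  if (is.null(grouping)) {
    if (is.null(gs$samples)) stop("no grouping and no sample table")
    grouping <- gs$samples$site_id
  }
  if (length(grouping) != nrow(gs$genotypes))
    stop("grouping length must match individuals")
  sizes <- table(grouping)
  if (any(sizes < 2)) stop("all groups must contain at least 2 individuals")
  cls <- gs$variants$class
  dd <- derived_dosage(gs)
  groups <- sort(unique(as.character(grouping)))
  out <- lapply(groups, function(g) {
    sub <- dd[grouping == g, , drop = FALSE]
    f <- colMeans(sub, na.rm = TRUE) / 2
    seg <- !is.na(f) & f > 0 & f < 1
    segN <- (seg & cls == "NONSYN") |
      (nonsyn_includes_lof & seg & cls == "LOF")
    segS <- seg & cls == "SYN"
    Pn <- sum(segN); Ps <- sum(segS)
    fn_bar <- if (Pn > 0) mean(f[segN]) else NA_real_
    fs_bar <- if (Ps > 0) mean(f[segS]) else NA_real_
    denom <- Ps * fs_bar
    data.frame(
      site_id = g, n = sum(grouping == g), Pn = Pn, Ps = Ps,
      fn_bar = fn_bar, fs_bar = fs_bar,
      ratio_ns = if (Pn + Ps > 0) Pn / (Pn + Ps) else NA_real_,
      freq_ratio = if (!is.na(denom) && denom > 0 && Pn > 0)
        (Pn * fn_bar) / denom else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
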