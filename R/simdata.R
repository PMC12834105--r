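#' Configuration for the serial-founder range-expansion simulator
#'
#' Builds and validates the parameter set for [simulate_expansion()]. The
#' defaults describe a desk-scale refuge-origin expansion: an 8 x 8 deme
#' grid seeded from its north-eastern corner, demes of 100 diploids founded
#' by 5 colonists every 20 generations, weak stepping-stone migration, a
#' 2 x 10 Mb genome mutating at 4.6e-9 per bp per generation, standing
#' refuge variation from a long-term ancestral Ne of 10000, and a 300
#' generation post-expansion phase (the expansion is sampled long after it
#' completed, so founder-derived homozygous tracts have recombined into the
#' 5 kb - 1 Mb ROH band).
#'
#' @param grid_width,grid_height Deme grid dimensions (columns, rows).
#' @param origin Integer `c(row, col)` (1-based) of the refuge deme;
#'   defaults to the north-eastern corner `c(1, grid_width)`.
#' @param deme_size Diploid individuals per colonized deme (N).
#' @param founders Diploids seeding each newly colonized deme (K), drawn
#'   from the nearest colonized 4-neighbour.
#' @param migration Per-generation fraction of a deme exchanged with each
#'   colonized 4-neighbour (`floor(migration * deme_size)` individuals per
#'   neighbour pair); must lie in [0, 0.5].
#' @param colonization_interval Generations between expansion wave steps.
#' @param post_expansion Generations simulated after the last wave step with
#'   the range stable, before sampling. A completed post-glacial expansion
#'   is observed long after its youngest colonization, so founder-derived
#'   homozygous tracts have had time to recombine down into the 5 kb - 1 Mb
#'   ROH band (a tract of age g generations has expected length
#'   100/(2g) cM).
#' @param burn_in Generations of within-refuge drift before the expansion
#'   starts (default 10). The refuge's diversity is supplied by the
#'   standing ancestral pool; a long confinement at the deme model's small
#'   N would spuriously erase it, because a single deme of `deme_size`
#'   understates the census size of a real refugium.
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param mu Per-bp per-generation mutation rate.
#' @param recomb_cM_per_Mb Recombination rate.
#' @param class_probs Probabilities that a new mutation is synonymous,
#'   nonsynonymous (missense) or loss-of-function; must sum to 1.
#' @param sel_coef Per-class selection coefficients (multiplicative fitness
#'   `1 + s` per derived allele); mutations are neutral by default.
#' @param sample_per_deme Individuals emitted per colonized deme.
#' @param lgm_epoch Generation at which the presence-raster snapshot is
#'   taken; defaults to `burn_in`, i.e. the pre-expansion refuge.
#' @param lon0,lat0,cell_deg Geographic registration: deme `(row, col)` has
#'   centre `lon = lon0 + (col-1)*cell_deg`, `lat = lat0 - (row-1)*cell_deg`
#'   (north-up convention, row 1 is the northern edge).
#' @param polarization_flip_prob Probability that a site is written with the
#'   derived base as REF (so the ancestral allele equals ALT), emulating
#'   reference genomes that carry derived alleles.
#' @param ancestral_Ne Long-term effective size of the refuge's source
#'   population, used to seed standing variation: the refuge founders carry
#'   `4 * ancestral_Ne * mu * L_total * a_(2N-1)` standing sites (Watterson's
#'   expectation) with neutral 1/f frequency spectrum.
#' @param n_standing,standing_freq Explicit overrides for the standing
#'   variation: number of sites, and a fixed carrier frequency instead of
#'   the 1/f spectrum (`NULL` = spectrum; used in drift calibration
#'   experiments).
#' @param drop_monomorphic Drop sites monomorphic in the final sample
#'   (default TRUE).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_expansion()]
#' @export
sim_config <- function(grid_width = 8, grid_height = 8, origin = NULL,
                       deme_size = 100, founders = 5, migration = 0.01,
                       colonization_interval = 20, post_expansion = 300,
                       burn_in = 10,
                       n_chromosomes = 2, chrom_length_bp = 1e7,
                       mu = 4.6e-9, recomb_cM_per_Mb = 1.0,
                       class_probs = c(SYN = 0.6, NONSYN = 0.35, LOF = 0.05),
                       sel_coef = c(SYN = 0, NONSYN = 0, LOF = 0),
                       sample_per_deme = 2, lgm_epoch = NULL,
                       lon0 = 88, lat0 = 36, cell_deg = 1,
                       polarization_flip_prob = 0.3,
                       ancestral_Ne = 10000, n_standing = NULL,
                       standing_freq = NULL,
                       drop_monomorphic = TRUE, seed = 1L) {
  if (is.null(origin)) origin <- c(1L, as.integer(grid_width))
  if (is.null(lgm_epoch)) lgm_epoch <- as.integer(burn_in)
  if (is.null(n_standing)) {
    a_n <- sum(1 / seq_len(2L * as.integer(deme_size) - 1L))
    n_standing <- round(4 * ancestral_Ne * mu *
                          n_chromosomes * chrom_length_bp * a_n)
  }
  if (is.null(standing_freq)) standing_freq <- -1
  cfg <- list(
    grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
    origin = as.integer(origin), deme_size = as.integer(deme_size),
    founders = as.integer(founders), migration = as.numeric(migration),
    colonization_interval = as.integer(colonization_interval),
    post_expansion = as.integer(post_expansion),
    burn_in = as.integer(burn_in), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp), mu = as.numeric(mu),
    recomb_cM_per_Mb = as.numeric(recomb_cM_per_Mb),
    class_probs = as.numeric(class_probs), sel_coef = as.numeric(sel_coef),
    sample_per_deme = as.integer(sample_per_deme),
    lgm_epoch = as.integer(lgm_epoch), lon0 = as.numeric(lon0),
    lat0 = as.numeric(lat0), cell_deg = as.numeric(cell_deg),
    polarization_flip_prob = as.numeric(polarization_flip_prob),
    ancestral_Ne = as.numeric(ancestral_Ne),
    n_standing = as.integer(n_standing),
    standing_freq = as.numeric(standing_freq),
    drop_monomorphic = isTRUE(drop_monomorphic), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$grid_width >= 1, cfg$grid_height >= 1, cfg$deme_size >= 1,
    cfg$n_chromosomes >= 1, cfg$chrom_length_bp >= 1,
    cfg$sample_per_deme >= 1, cfg$colonization_interval >= 1,
    cfg$post_expansion >= 0, cfg$burn_in >= 0, cfg$mu >= 0, cfg$recomb_cM_per_Mb >= 0,
    cfg$cell_deg > 0, length(cfg$origin) == 2,
    length(cfg$class_probs) == 3, length(cfg$sel_coef) == 3,
    cfg$n_standing >= 0, cfg$standing_freq <= 1
  )
  if (cfg$migration < 0 || cfg$migration > 0.5)
    stop("migration must lie in [0, 0.5]")
  if (cfg$founders < 1 || cfg$founders > cfg$deme_size)
    stop("founders must satisfy 0 < K <= deme_size")
  if (any(cfg$class_probs < 0) || abs(sum(cfg$class_probs) - 1) > 1e-9)
    stop("class_probs must be non-negative and sum to 1")
  if (cfg$origin[1] < 1 || cfg$origin[1] > cfg$grid_height ||
      cfg$origin[2] < 1 || cfg$origin[2] > cfg$grid_width)
    stop("origin lies outside the deme grid")
  if (cfg$sample_per_deme > cfg$deme_size)
    stop("sample_per_deme cannot exceed deme_size")
  if (cfg$polarization_flip_prob < 0 || cfg$polarization_flip_prob > 1)
    stop("polarization_flip_prob must lie in [0, 1]")
  invisible(cfg)
}

#' Simulate a serial-founder range expansion
#'
#' Runs a forward-in-time Wright-Fisher simulation on a deme grid. The
#' refuge deme drifts for `burn_in` generations, then every
#' `colonization_interval` generations each empty cell adjacent to the
#' colonized range is founded by `founders` diploids drawn from its nearest
#' colonized 4-neighbour (ties broken in fixed N, E, S, W order), after
#' which it exchanges migrants symmetrically with colonized neighbours.
#' Haplotypes are founder-interval mosaics with Poisson crossovers and
#' Poisson(`mu * L`) new mutations per gamete, each assigned a functional
#' class and an ancestral state (absence of the mutation). At the final
#' generation `sample_per_deme` individuals per colonized deme are emitted
#' with deme-centre coordinates; sites monomorphic in the sample are
#' dropped.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `expansion_sim`: a list with elements
#'   `data` (a [geno_set()]: genotype dosage matrix, variant table with
#'   SYN/NONSYN/LOF classes and ancestral alleles, sample table with
#'   coordinates), `presence_lgm` and `presence_final` (binary
#'   [raster_grid()] snapshots), `origin_lonlat`, `diagnostics` (per-event
#'   colonization expected-heterozygosity pairs; per-sample longest
#'   autozygous founder tract in bp) and `config`.
#' @examples
#' sim <- simulate_expansion(sim_config(grid_width = 3, grid_height = 3,
#'   deme_size = 20, burn_in = 40, seed = 7))
#' dim(sim$data$genotypes)
#' @export
simulate_expansion <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  validate_sim_config(config)
  set.seed(config$seed)
  cc <- unclass(config)
  cc$origin_row <- config$origin[1] - 1L
  cc$origin_col <- config$origin[2] - 1L
  res <- .sim_expansion_cpp(cc)

  n_site <- length(res$pos0)
  bases <- c("A", "C", "G", "T")
  anc_idx <- sample.int(4L, n_site, replace = TRUE)
  der_idx <- (anc_idx - 1L + sample.int(3L, n_site, replace = TRUE)) %% 4L + 1L
  flip <- runif(n_site) < config$polarization_flip_prob
  anc_base <- bases[anc_idx]
  der_base <- bases[der_idx]
  ref <- ifelse(flip, der_base, anc_base)
  alt <- ifelse(flip, anc_base, der_base)

  geno <- res$genotypes  # derived-allele dosage
  if (n_site > 0 && any(flip)) geno[, flip] <- 2L - geno[, flip, drop = FALSE]

  cls_levels <- c("SYN", "NONSYN", "LOF")
  variants <- data.frame(
    chrom = paste0("chr", res$chrom0 + 1L),
    pos = res$pos0 + 1L,
    ref = ref, alt = alt,
    ancestral = anc_base,
    class = cls_levels[res$class_code + 1L],
    stringsAsFactors = FALSE
  )

  row <- res$sample_row + 1L
  col <- res$sample_col + 1L
  site_id <- sprintf("s%02d_%02d", row, col)
  idx_in_site <- stats::ave(seq_along(site_id), site_id, FUN = seq_along)
  samples <- data.frame(
    sample_id = sprintf("%s_i%d", site_id, idx_in_site),
    site_id = site_id,
    lon = config$lon0 + (col - 1) * config$cell_deg,
    lat = config$lat0 - (row - 1) * config$cell_deg,
    stringsAsFactors = FALSE
  )
  rownames(geno) <- samples$sample_id

  gs <- geno_set(geno, variants, samples)
  orow <- config$origin[1]; ocol <- config$origin[2]
  origin_lonlat <- c(lon = config$lon0 + (ocol - 1) * config$cell_deg,
                     lat = config$lat0 - (orow - 1) * config$cell_deg)

  mk_raster <- function(m) {
    raster_grid(matrix(as.numeric(m), nrow(m), ncol(m)),
                lon0 = config$lon0, lat0 = config$lat0,
                cell_deg = config$cell_deg)
  }
  colonization <- as.data.frame(res$colonization, stringsAsFactors = FALSE)
  structure(list(
    data = gs,
    presence_lgm = mk_raster(res$presence_lgm),
    presence_final = mk_raster(res$presence_final),
    origin_lonlat = origin_lonlat,
    diagnostics = list(
      colonization = colonization,
      max_ibd_tract_bp = setNames(as.integer(res$max_tract),
                                  samples$sample_id),
      colonized_gen = res$colonized_gen,
      total_generations = res$total_generations,
      n_mutations_total = res$n_mutations_total
    ),
    config = config
  ), class = "expansion_sim")
}

#' @method print expansion_sim
#' @export
print.expansion_sim <- function(x, ...) {
  d <- x$data
  cat("Serial-founder range-expansion simulation\n")
  cat(sprintf("  grid %d x %d, origin (%d, %d), N = %d, K = %d, m = %g\n",
              x$config$grid_height, x$config$grid_width,
              x$config$origin[1], x$config$origin[2],
              x$config$deme_size, x$config$founders, x$config$migration))
  cat(sprintf("  %d sampled individuals, %d segregating sites, %d generations\n",
              nrow(d$genotypes), ncol(d$genotypes),
              x$diagnostics$total_generations))
  invisible(x)
}

#' Write simulator outputs to disk
#'
#' Emits a VCF 4.2 file (with `AA` ancestral-allele and `CLASS` functional
#' tags), a sample CSV (`sample_id, site_id, lon, lat`), ESRI ASCII
#' presence rasters for the refuge-epoch and final colonized sets, and the
#' origin coordinates. The files round-trip losslessly through
#' [read_vcf()], [read_samples()] and [read_ascii_raster()].
#'
#' @param sim An `expansion_sim` object.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  if (!inherits(sim, "expansion_sim")) stop("sim must be an expansion_sim")
  if (nrow(sim$data$genotypes) == 0) stop("simulation contains no samples")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    samples = file.path(dir, "samples.csv"),
    presence_lgm = file.path(dir, "presence_lgm.asc"),
    presence_final = file.path(dir, "presence_final.asc"),
    origin = file.path(dir, "origin.csv")
  )
  write_vcf(sim$data, paths[["vcf"]])
  write_samples(sim$data$samples, paths[["samples"]])
  write_ascii_raster(sim$presence_lgm, paths[["presence_lgm"]])
  write_ascii_raster(sim$presence_final, paths[["presence_final"]])
  write.csv(data.frame(lon = sim$origin_lonlat[["lon"]],
                       lat = sim$origin_lonlat[["lat"]]),
            paths[["origin"]], row.names = FALSE)
  invisible(paths)
}
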