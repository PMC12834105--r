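#' Pipeline configuration
#'
#' Builds (or loads from YAML/JSON) the configuration for [run_pipeline()].
#' Exactly one input source must be given: either file paths (`vcf`,
#' `samples`, `presence`) or a simulation block (arguments for
#' [sim_config()]). Stage parameter blocks mirror the module defaults and
#' may be partially specified.
#'
#' @param x Path to a YAML or JSON config file, or a named list.
#' @param ... Fields overriding the file/list contents.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list(), ...) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else x
  over <- list(...)
  cfg[names(over)] <- over
  defaults <- list(
    input = NULL,          # list(vcf=, samples=, presence=)
    sim = NULL,            # list of sim_config() arguments
    seed = 1L,
    output_dir = NULL,
    maf = 0.10,
    ld = list(window_snps = 50, step_snps = 10, r2_max = 0.2),
    roh = list(window_snps = 50, window_het_max = 1, window_miss_max = 5,
               hit_frac = 0.05, min_snps = 25, min_length_bp = 5000,
               lo_bp = 5000, hi_bp = 1e6),
    load = list(nonsyn_includes_lof = FALSE),
    ibd = list(n_perm = 9999, alternative = "greater", min_per_site = 2),
    krige = list(family = "exponential", n_lags = 12,
                 n_cells = c(100, 100),
                 statistics = c("heterozygosity", "roh_count")),
    gradient = list(statistics = c("heterozygosity", "roh_count",
                                   "ratio_ns", "freq_ratio", "lof_dosage"))
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(cfg[[nm]]))
      cfg[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$sim)
  if (has_input == has_sim)
    stop("exactly one of 'input' (file paths) or 'sim' must be supplied")
  if (has_input) {
    need <- c("vcf", "samples", "presence")
    if (!all(need %in% names(cfg$input)))
      stop("input must name vcf, samples and presence files")
    missing_files <- !vapply(cfg$input[need], file.exists, logical(1))
    if (any(missing_files))
      stop("missing input files: ",
           paste(unlist(cfg$input[need])[missing_files], collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full spatial population-genomics pipeline
#'
#' Executes, in order: data acquisition (simulation or file input), SNP
#' filtering, per-individual diversity (heterozygosity + ROH), genetic
#' load, isolation by distance, and spatial analysis (refuge centre,
#' kriging, distance-gradient tests with FDR applied across the statistics
#' tested in the run). Per-stage tables are written as CSV, rasters as
#' ESRI ASCII grids, and a JSON manifest records versions, seed, the
#' normalised parameter set and per-stage row counts. A stage failure
#' writes a `FAILED` marker naming the stage and aborts; earlier outputs
#' are retained.
#'
#' @param config A [pipeline_config()] (or something coercible to one).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  manifest <- list(
    package = "refugia",
    version = as.character(packageVersion("refugia")),
    seed = config$seed,
    parameters = normalize_config(config),
    stages = list()
  )
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    res
  }

  # -- stage 1: input ------------------------------------------------------
  acq <- stage("input", function() {
    if (!is.null(config$sim)) {
      sc <- do.call(sim_config, c(config$sim,
                                  if (is.null(config$sim$seed))
                                    list(seed = config$seed)))
      sim <- simulate_expansion(sc)
      write_sim_outputs(sim, file.path(out, "simulated"))
      list(gs = sim$data, presence = sim$presence_lgm)
    } else {
      samples <- read_samples(config$input$samples)
      gs <- read_vcf(config$input$vcf, samples = samples)
      list(gs = gs, presence = read_ascii_raster(config$input$presence))
    }
  })
  gs <- acq$gs
  manifest$stages$input <- list(n_individuals = nrow(gs$genotypes),
                                n_sites = ncol(gs$genotypes))

  # -- stage 2: filters (feed the IBD analysis) ----------------------------
  filt <- stage("filter", function() {
    ld <- config$ld
    ld_prune(filter_maf(gs, config$maf),
             ld$window_snps, ld$step_snps, ld$r2_max)
  })
  manifest$stages$filter <- list(n_sites_maf_ld = ncol(filt$genotypes))

  # -- stage 3: diversity --------------------------------------------------
  div <- stage("diversity", function() {
    het <- heterozygosity(gs)
    rp <- config$roh
    segs <- detect_roh(gs, rp$window_snps, rp$window_het_max,
                       rp$window_miss_max, rp$hit_frac, rp$min_snps,
                       rp$min_length_bp)
    rs <- roh_summary(segs, ids = sample_ids(gs), lo_bp = rp$lo_bp,
                      hi_bp = rp$hi_bp)
    per_ind <- data.frame(sample_id = sample_ids(gs),
                          heterozygosity = unname(het))
    per_ind <- merge(per_ind, rs, by = "sample_id", sort = FALSE)
    write.csv(per_ind, file.path(out, "diversity.csv"), row.names = FALSE)
    if (nrow(segs) > 0)
      write_roh_bed(segs, file.path(out, "roh_segments.bed"))
    list(per_ind = per_ind, segs = segs)
  })
  manifest$stages$diversity <- list(n_individuals = nrow(div$per_ind),
                                    n_roh_segments = nrow(div$segs))

  # -- stage 4: genetic load -----------------------------------------------
  load_df <- stage("load", function() {
    ld <- individual_load(gs, config$load$nonsyn_includes_lof)
    write.csv(ld, file.path(out, "load.csv"), row.names = FALSE)
    ld
  })
  manifest$stages$load <- list(n_individuals = nrow(load_df))

  # -- stage 5: differentiation / IBD --------------------------------------
  ibd <- stage("ibd", function() {
    r <- ibd_test(gs, maf = config$maf,
                  window_snps = config$ld$window_snps,
                  step_snps = config$ld$step_snps,
                  r2_max = config$ld$r2_max,
                  min_per_site = config$ibd$min_per_site,
                  n_perm = config$ibd$n_perm,
                  alternative = config$ibd$alternative,
                  seed = config$seed)
    write.csv(r$genetic, file.path(out, "fst_linearized.csv"))
    write.csv(r$geographic, file.path(out, "geo_distance_km.csv"))
    jsonlite::write_json(
      list(r = r$r, p = r$p, n_sites = r$n_sites,
           n_snps_used = r$n_snps_used, n_perm = r$n_perm,
           seed = config$seed),
      file.path(out, "ibd.json"), auto_unbox = TRUE, digits = NA)
    r
  })
  manifest$stages$ibd <- list(r = ibd$r, p = ibd$p, n_sites = ibd$n_sites,
                              n_snps_used = ibd$n_snps_used)

  # -- stage 6: spatial ----------------------------------------------------
  spat <- stage("spatial", function() {
    center <- refuge_center(acq$presence)
    stats_df <- data.frame(
      heterozygosity = div$per_ind$heterozygosity,
      roh_count = div$per_ind$roh_count,
      ratio_ns = load_df$ratio_ns,
      freq_ratio = load_df$freq_ratio,
      lof_dosage = load_df$lof_dosage)
    stats_df <- stats_df[config$gradient$statistics]
    gt <- gradient_table(stats_df, gs$samples$lon, gs$samples$lat, center)
    write.csv(gt, file.path(out, "gradients.csv"), row.names = FALSE)
    kriged <- character()
    for (nm in config$krige$statistics) {
      v <- stats_df[[nm]]
      if (is.null(v) || sum(is.finite(v)) < 5 ||
          stats::sd(v[is.finite(v)]) == 0) next
      ev <- empirical_variogram(gs$samples$lon, gs$samples$lat, v,
                                n_lags = config$krige$n_lags)
      vm <- fit_variogram(ev, family = config$krige$family)
      kr <- ordinary_krige(gs$samples$lon, gs$samples$lat, v, vm,
                           n_cells = config$krige$n_cells)
      path <- file.path(out, sprintf("krige_%s.asc", nm))
      write_ascii_raster(kr$prediction, path)
      kriged <- c(kriged, path)
    }
    list(center = center, gradients = gt, kriged = kriged)
  })
  manifest$stages$spatial <- list(
    refuge_center = as.list(spat$center),
    n_gradient_tests = nrow(spat$gradients),
    kriged = basename(spat$kriged))

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical parameter echo for the manifest (stable field order)
normalize_config <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  lapply(cfg, function(x) if (is.list(x)) x[order(names(x))] else x)
}
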