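#' Lightweight lon/lat raster
#'
#' A north-up grid of values registered by the centre of its north-western
#' cell: cell `(row, col)` has centre `lon = lon0 + (col-1)*cell_deg`,
#' `lat = lat0 - (row-1)*cell_deg`. Row 1 is the northern edge.
#'
#' @param values Numeric matrix (`NA` = nodata).
#' @param lon0,lat0 Centre of the top-left cell, decimal degrees.
#' @param cell_deg Cell size in degrees.
#' @param nodata Sentinel written to disk for `NA` (default -9999).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, lon0, lat0, cell_deg, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.finite(lon0), is.finite(lat0), cell_deg > 0)
  structure(list(values = values, lon0 = lon0, lat0 = lat0,
                 cell_deg = cell_deg, nrows = nrow(values),
                 ncols = ncol(values), nodata = nodata),
            class = "raster_grid")
}

#' @method print raster_grid
#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "raster_grid: %d x %d cells of %g deg, NW centre (%.4g, %.4g)\n",
    x$nrows, x$ncols, x$cell_deg, x$lon0, x$lat0))
  invisible(x)
}

# lon/lat of every cell centre, row-major
raster_coords <- function(r) {
  list(lon = r$lon0 + (col(r$values) - 1) * r$cell_deg,
       lat = r$lat0 - (row(r$values) - 1) * r$cell_deg)
}

#' Read / write ESRI ASCII grids
#'
#' Standard `.asc` format (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header, rows north to south); `NA` maps to the nodata
#' sentinel.
#'
#' @param r A [raster_grid()].
#' @param path File path.
#' @return The raster (read) or `path` invisibly (write).
#' @export
write_ascii_raster <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$ncols),
    sprintf("nrows %d", r$nrows),
    sprintf("xllcorner %.10g", r$lon0 - r$cell_deg / 2),
    sprintf("yllcorner %.10g", r$lat0 - (r$nrows - 1) * r$cell_deg -
              r$cell_deg / 2),
    sprintf("cellsize %.10g", r$cell_deg),
    sprintf("NODATA_value %g", r$nodata)), con)
  v <- r$values
  v[is.na(v)] <- r$nodata
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_raster
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows
  cell <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  lon0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner + cell / 2 else
    hdr$xllcenter
  lat_ll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner + cell / 2 else
    hdr$yllcenter
  raster_grid(m, lon0 = lon0, lat0 = lat_ll + (nrows - 1) * cell,
              cell_deg = cell, nodata = nodata)
}

#' Empirical semivariogram
#'
#' `gamma_hat(h) = (1/2N(h)) * sum (z_i - z_j)^2` over point pairs binned
#' by great-circle distance; empty bins are dropped.
#'
#' @param lon,lat,values Observation coordinates and values.
#' @param n_lags Number of distance bins.
#' @param max_dist Maximum pair distance used (default: half the maximum
#'   pairwise distance).
#' @return Data frame with `h` (bin mean distance, km), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(lon, lat, values, n_lags = 12,
                                max_dist = NULL) {
  ok <- is.finite(values)
  lon <- lon[ok]; lat <- lat[ok]; values <- values[ok]
  n <- length(values)
  if (n < 2) stop("need at least 2 points with finite values")
  dm <- geo_distance_matrix(lon, lat)
  lt <- lower.tri(dm)
  h <- dm[lt]
  g2 <- outer(values, values, "-")[lt]^2
  if (is.null(max_dist)) max_dist <- max(h) / 2
  keep <- h <= max_dist & h > 0
  if (!any(keep)) stop("no point pairs within max_dist")
  h <- h[keep]; g2 <- g2[keep]
  bin <- pmin(ceiling(h / (max_dist / n_lags)), n_lags)
  out <- data.frame(
    h = as.numeric(tapply(h, bin, mean)),
    gamma = as.numeric(tapply(g2, bin, sum) / (2 * tapply(g2, bin, length))),
    n_pairs = as.integer(tapply(g2, bin, length)))
  out <- out[order(out$h), , drop = FALSE]
  rownames(out) <- NULL
  if (all(out$gamma == 0))
    message("empirical_variogram: constant field, zero variogram")
  out
}

#' Theoretical semivariance
#'
#' `gamma(0) = 0`; for `h > 0`, `gamma(h) = nugget + partial_sill * f(h/range)`
#' with `f` the spherical, exponential or gaussian correlation complement.
#'
#' @param model A `variogram_model` (see [fit_variogram()]).
#' @param h Distances (km).
#' @return Semivariances.
#' @export
variogram_gamma <- function(model, h) {
  f <- switch(model$family,
    exponential = 1 - exp(-h / model$range_km),
    gaussian = 1 - exp(-(h / model$range_km)^2),
    spherical = ifelse(h < model$range_km,
                       1.5 * h / model$range_km -
                         0.5 * (h / model$range_km)^3, 1),
    stop("unknown variogram family"))
  ifelse(h > 0, model$nugget + model$partial_sill * f, 0)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises `sum N(h)/h^2 * (gamma_model(h) - gamma_hat(h))^2`. Because
#' the model is linear in `(nugget, partial_sill)` once the range is fixed,
#' the fit profiles the range over a deterministic multi-start grid with an
#' exact non-negative weighted least-squares inner solve, then polishes the
#' best bracket with 1-D optimisation; this recovers a model's own
#' theoretical curve essentially exactly.
#'
#' @param ev Lag table from [empirical_variogram()] (>= 3 non-empty lags).
#' @param family `"exponential"` (default), `"spherical"` or `"gaussian"`.
#' @return A `variogram_model`: list with `family`, `nugget`,
#'   `partial_sill`, `range_km`.
#' @export
fit_variogram <- function(ev, family = c("exponential", "spherical",
                                         "gaussian")) {
  family <- match.arg(family)
  if (nrow(ev) < 3) stop("need at least 3 non-empty lags")
  h <- ev$h; g <- ev$gamma; w <- ev$n_pairs / h^2
  if (all(g == 0))
    return(structure(list(family = family, nugget = 0, partial_sill = 0,
                          range_km = max(h)), class = "variogram_model"))
  corr_f <- switch(family,
    exponential = function(hh, r) 1 - exp(-hh / r),
    gaussian = function(hh, r) 1 - exp(-(hh / r)^2),
    spherical = function(hh, r)
      ifelse(hh < r, 1.5 * hh / r - 0.5 * (hh / r)^3, 1))

  # exact WLS in (nugget, psill) for fixed range, clamped to >= 0
  solve_linear <- function(r) {
    x <- corr_f(h, r)
    fits <- list()
    X <- cbind(1, x)
    A <- crossprod(X * sqrt(w))
    bvec <- crossprod(X, w * g)
    co <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (!is.null(co) && all(co >= 0)) fits <- c(fits, list(c(co)))
    ps0 <- sum(w * x * g) / sum(w * x * x)         # nugget = 0
    fits <- c(fits, list(c(0, max(ps0, 0))))
    ng0 <- sum(w * g) / sum(w)                     # psill = 0
    fits <- c(fits, list(c(max(ng0, 0), 0)))
    best <- NULL; best_sse <- Inf
    for (cand in fits) {
      sse <- sum(w * (cand[1] + cand[2] * x - g)^2)
      if (sse < best_sse) { best_sse <- sse; best <- cand }
    }
    list(par = best, sse = best_sse)
  }

  r_grid <- exp(seq(log(min(h) / 10), log(max(h) * 10), length.out = 80))
  sse <- vapply(r_grid, function(r) solve_linear(r)$sse, numeric(1))
  k <- which.min(sse)
  lo <- r_grid[max(1, k - 1)]; hi <- r_grid[min(length(r_grid), k + 1)]
  opt <- stats::optimize(function(r) solve_linear(r)$sse, c(lo, hi),
                         tol = 1e-10 * max(h))
  best_r <- opt$minimum
  if (sse[k] < opt$objective) best_r <- r_grid[k]
  fit <- solve_linear(best_r)
  structure(list(family = family, nugget = fit$par[1],
                 partial_sill = fit$par[2], range_km = best_r),
            class = "variogram_model")
}

#' @method print variogram_model
#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.4g, partial sill %.4g, range %.4g km\n",
              x$family, x$nugget, x$partial_sill, x$range_km))
  invisible(x)
}

# ordinary-kriging weights and predictions at arbitrary points
krige_points <- function(lon, lat, values, model, pred_lon, pred_lat,
                         jitter_eps = 1e-6) {
  ok <- is.finite(values)
  lon <- lon[ok]; lat <- lat[ok]; values <- values[ok]
  n <- length(values)
  if (n < 2) stop("need at least 2 data points")
  dup <- duplicated(cbind(lon, lat))
  if (any(dup)) {
    message(sprintf("kriging: jittered %d duplicate coordinates by %g deg",
                    sum(dup), jitter_eps))
    while (any(dup)) {
      lon[dup] <- lon[dup] + jitter_eps
      lat[dup] <- lat[dup] + jitter_eps
      dup <- duplicated(cbind(lon, lat))
    }
  }
  G <- variogram_gamma(model, geo_distance_matrix(lon, lat))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  D0 <- geosphere::distm(cbind(pred_lon, pred_lat), cbind(lon, lat),
                         fun = function(a, b)
                           geosphere::distHaversine(a, b, r = 6371.0088))
  B <- rbind(t(variogram_gamma(model, D0)), 1)
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular kriging system"))
  wts <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- as.numeric(crossprod(wts, values))
  vr <- colSums(wts * t(variogram_gamma(model, D0))) + mu
  list(prediction = pred, variance = vr, weights = wts)
}

#' Ordinary kriging onto a lon/lat grid
#'
#' Solves the ordinary-kriging system (semivariances from the fitted
#' model, unbiasedness enforced through a Lagrange multiplier) at every
#' grid node. The predictor is exact: with zero nugget, the surface passes
#' through every observation. Duplicate coordinates are jittered by a
#' documented epsilon (1e-6 degrees).
#'
#' @param lon,lat,values Observations.
#' @param model A `variogram_model` from [fit_variogram()].
#' @param grid Optional [raster_grid()] template; default is the bounding
#'   box of the data padded by 5\%, at `n_cells` resolution.
#' @param n_cells `c(ncols, nrows)` for the default grid.
#' @param jitter_eps Duplicate-coordinate jitter in degrees.
#' @return List of two [raster_grid()]s: `prediction` and `variance`.
#' @export
ordinary_krige <- function(lon, lat, values, model, grid = NULL,
                           n_cells = c(100, 100), jitter_eps = 1e-6) {
  ok <- is.finite(values)
  if (is.null(grid)) {
    rlon <- range(lon[ok]); rlat <- range(lat[ok])
    padx <- diff(rlon) * 0.05; pady <- diff(rlat) * 0.05
    if (padx == 0) padx <- 0.5
    if (pady == 0) pady <- 0.5
    ncx <- n_cells[1]; ncy <- n_cells[2]
    cell <- max((diff(rlon) + 2 * padx) / ncx, (diff(rlat) + 2 * pady) / ncy)
    grid <- raster_grid(matrix(NA_real_, ncy, ncx),
                        lon0 = rlon[1] - padx, lat0 = rlat[2] + pady,
                        cell_deg = cell)
  }
  co <- raster_coords(grid)
  kp <- krige_points(lon, lat, values, model,
                     as.numeric(co$lon), as.numeric(co$lat), jitter_eps)
  pred <- grid
  pred$values <- matrix(kp$prediction, grid$nrows, grid$ncols)
  vr <- grid
  vr$values <- matrix(kp$variance, grid$nrows, grid$ncols)
  list(prediction = pred, variance = vr)
}

#' Geographic centre of presence cells
#'
#' The arithmetic mean of the longitudes and latitudes of all cells equal
#' to 1 in a binary presence raster — the refuge centre when applied to a
#' glacial-maximum distribution snapshot.
#'
#' @param presence A binary [raster_grid()].
#' @return Named vector `c(lon, lat)`.
#' @export
refuge_center <- function(presence) {
  co <- raster_coords(presence)
  idx <- which(!is.na(presence$values) & presence$values == 1)
  if (length(idx) == 0) stop("no presence cells")
  c(lon = mean(co$lon[idx]), lat = mean(co$lat[idx]))
}

#' Correlation of a statistic with distance from a centre
#'
#' Computes each individual's great-circle distance to `center` and the
#' Pearson correlation of the statistic with that distance (two-tailed p
#' from the t distribution with n - 2 df). Non-finite statistic values are
#' dropped with a reported count.
#'
#' @param values Per-individual statistic.
#' @param lon,lat Per-individual coordinates.
#' @param center Named vector `c(lon, lat)` (e.g. from [refuge_center()]).
#' @param name Statistic label carried into the result.
#' @return Data frame row: `statistic`, `r`, `p`, `n`.
#' @export
gradient_test <- function(values, lon, lat, center, name = "statistic") {
  ok <- is.finite(values)
  if (any(!ok))
    message(sprintf("gradient_test(%s): dropped %d undefined values",
                    name, sum(!ok)))
  values <- values[ok]; lon <- lon[ok]; lat <- lat[ok]
  if (length(values) < 3) stop("need at least 3 individuals")
  d <- geo_distance_km(lon, lat, center[["lon"]], center[["lat"]])
  if (stats::sd(values) == 0 || stats::sd(d) == 0)
    stop("zero variance in statistic or distance")
  ct <- stats::cor.test(d, values, method = "pearson",
                        alternative = "two.sided")
  data.frame(statistic = name, r = unname(ct$estimate), p = ct$p.value,
             n = length(values), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1
#' and mapped back to the input order (`stats::p.adjust(method = "BH")`).
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gradient tests for several statistics with a shared FDR family
#'
#' Runs [gradient_test()] for each column of `stats_df` and adjusts the
#' two-tailed p-values jointly with [fdr_adjust()] (the FDR family is the
#' set of statistics tested in one run).
#'
#' @param stats_df Data frame of per-individual statistics (one column per
#'   statistic).
#' @param lon,lat,center As in [gradient_test()].
#' @return Data frame: `statistic`, `r`, `p`, `q`, `n`.
#' @export
gradient_table <- function(stats_df, lon, lat, center) {
  rows <- lapply(names(stats_df), function(nm)
    gradient_test(stats_df[[nm]], lon, lat, center, name = nm))
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out[c("statistic", "r", "p", "q", "n")]
}
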