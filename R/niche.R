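#' Gridded suitability / environmental raster
#'
#' A minimal geographic raster: a numeric matrix (first row = northernmost
#' row) on a regular lat/lon grid, with `NA` marking nodata cells.
#'
#' @param values numeric matrix, rows north to south
#' @param xllcorner,yllcorner lower-left corner of the grid (degrees)
#' @param cellsize cell size (degrees)
#' @return object of class `suitability_raster`
#' @export
ascii_raster <- function(values, xllcorner, yllcorner, cellsize) {
  values <- as.matrix(values)
  if (!any(is.finite(values))) stop("raster has no valid cell")
  structure(list(values = values, xllcorner = xllcorner,
                 yllcorner = yllcorner, cellsize = cellsize),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  cat("suitability_raster: ", nrow(x$values), " x ", ncol(x$values),
      " cells, cellsize ", x$cellsize, " deg, ",
      sum(is.finite(x$values)), " valid\n", sep = "")
  invisible(x)
}

#' Read an ESRI ASCII grid
#' @param path file path
#' @return a [ascii_raster()]
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    hdr[[tolower(f[1])]] <- as.numeric(f[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header incomplete in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  ascii_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#' @param r a [ascii_raster()]
#' @param path output path
#' @param nodata nodata code written for `NA` cells (default -9999)
#' @return `path`, invisibly
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "suitability_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(r$values)),
               paste("nrows", nrow(r$values)),
               paste("xllcorner", r$xllcorner),
               paste("yllcorner", r$yllcorner),
               paste("cellsize", r$cellsize),
               paste("NODATA_value", nodata)), con)
  m <- r$values
  m[!is.finite(m)] <- nodata
  for (i in seq_len(nrow(m)))
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' Cell-center coordinates of a raster
#' @param r a [ascii_raster()]
#' @return data frame `lon`, `lat`, one row per cell in matrix order
#'   (column-major, matching `as.vector(r$values)`)
#' @export
raster_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  lon_of_col <- r$xllcorner + (seq_len(nc) - 0.5) * r$cellsize
  lat_of_row <- r$yllcorner + (nr - seq_len(nr) + 0.5) * r$cellsize
  data.frame(lon = rep(lon_of_col, each = nr),
             lat = rep(lat_of_row, times = nc))
}

#' Extract raster values at point locations
#' @param r a [ascii_raster()]
#' @param lon,lat point coordinates (degrees)
#' @return numeric vector (`NA` for points off-grid or on nodata cells)
#' @export
extract_raster <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xllcorner) / r$cellsize) + 1
  row <- nr - floor((lat - r$yllcorner) / r$cellsize)
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr &
    !is.na(col) & !is.na(row)
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xllcorner, a$yllcorner, a$cellsize),
                     c(b$xllcorner, b$yllcorner, b$cellsize)))
}

#' Greedily prune highly correlated environmental layers
#'
#' While any pair of layers has `|r| > threshold` over their shared valid
#' cells, the member of the worst pair with the larger mean absolute
#' correlation to all remaining layers is dropped. Deterministic.
#'
#' @param layers named list of [ascii_raster()] on a common grid
#' @param threshold absolute-correlation cutoff (default 0.9)
#' @return list with `retained` (layer names kept), `removed`, and the
#'   pruned `layers` list
#' @export
prune_correlated_layers <- function(layers, threshold = 0.9) {
  stopifnot(length(layers) >= 2)
  nm <- names(layers)
  for (l in layers) {
    stopifnot(inherits(l, "suitability_raster"))
    if (!same_grid(l, layers[[1]])) stop("layers are not on a common grid")
    if (!any(is.finite(l$values))) stop("all-nodata layer")
  }
  V <- vapply(layers, function(l) as.vector(l$values),
              numeric(length(layers[[1]]$values)))
  keep <- nm
  repeat {
    C <- suppressWarnings(cor(V[, keep, drop = FALSE],
                              use = "pairwise.complete.obs"))
    diag(C) <- 0
    C[is.na(C)] <- 0
    worst <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    if (abs(C[worst[1], worst[2]]) <= threshold) break
    pair <- keep[worst]
    mac <- colMeans(abs(C))[worst]
    drop_nm <- pair[which.max(mac)]
    if (mac[1] == mac[2]) drop_nm <- pair[2]  # deterministic tie-break
    keep <- setdiff(keep, drop_nm)
    if (length(keep) == 1) break
  }
  list(retained = keep, removed = setdiff(nm, keep),
       layers = layers[keep])
}

#' PCA of a climate table
#'
#' Variables are z-scored and decomposed by the correlation-matrix PCA;
#' constant variables are dropped with a warning.
#'
#' @param tab numeric data frame / matrix (points x variables)
#' @return list: `scores`, `loadings` (orthonormal columns), `explained`
#'   (fraction of variance per component), `dropped` variable names
#' @export
climate_pca <- function(tab) {
  X <- as.matrix(tab)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2)
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant variables: ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pc$x,
       loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Levins' B1 (inverse concentration) niche breadth
#'
#' Suitability is normalized to sum to one over valid cells;
#' `B1 = (1 / sum(p^2) - 1) / (n - 1)` ranges from 0 (all mass on one
#' cell) to 1 (uniform). Invariant to rescaling the raster.
#'
#' @param S a [ascii_raster()] of non-negative suitabilities
#' @return breadth in \[0, 1\]
#' @export
levins_b1 <- function(S) {
  v <- as.vector(S$values)
  v <- v[is.finite(v)]
  if (any(v < 0)) stop("negative suitability")
  tot <- sum(v)
  if (tot <= 0) stop("total suitability is zero")
  n <- length(v)
  if (n == 1) return(0)
  p <- v / tot
  (1 / sum(p^2) - 1) / (n - 1)
}

#' Warren's I niche-overlap index
#'
#' Both rasters are normalized to sum to one over the shared valid cells;
#' `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)`, i.e. one minus half the
#' squared Hellinger distance, ranging from 0 (no overlap) to 1
#' (identical surfaces). Symmetric and invariant to positive rescaling of
#' either raster.
#'
#' @param S1,S2 [ascii_raster()] objects on the same grid
#' @return overlap in \[0, 1\]
#' @export
warren_i <- function(S1, S2) {
  if (!same_grid(S1, S2)) stop("rasters are not on the same grid")
  v1 <- as.vector(S1$values); v2 <- as.vector(S2$values)
  ok <- is.finite(v1) & is.finite(v2)
  if (!any(ok)) stop("no shared valid cells")
  p <- v1[ok] / sum(v1[ok])
  q <- v2[ok] / sum(v2[ok])
  max(0, min(1, 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)))
}

#' Mahalanobis climate-envelope suitability estimator
#'
#' A deterministic stand-in for a full niche-modelling algorithm:
#' suitability of a cell is `exp(-d^2 / 2)` where `d^2` is the Mahalanobis
#' distance of the cell's climate vector to the mean of the occurrence
#' climates, with the occurrence covariance regularized by adding
#' `ridge * I`.
#'
#' @param occ data frame of occurrences with columns `lon`, `lat`
#' @param layers named list of [ascii_raster()] climate layers on a common
#'   grid
#' @param ridge covariance regularization constant (default 1e-6)
#' @return a [ascii_raster()] of suitabilities in (0, 1\]
#' @export
envelope_estimator <- function(occ, layers, ridge = 1e-6) {
  stopifnot(nrow(occ) >= 3, length(layers) >= 1)
  clim_occ <- vapply(layers, function(l) extract_raster(l, occ$lon, occ$lat),
                     numeric(nrow(occ)))
  clim_occ <- matrix(clim_occ, nrow = nrow(occ))
  if (anyNA(clim_occ)) stop("occurrences fall on nodata or off-grid cells")
  mu <- colMeans(clim_occ)
  Sg <- var(clim_occ) + diag(ridge, ncol(clim_occ))
  V <- vapply(layers, function(l) as.vector(l$values),
              numeric(length(layers[[1]]$values)))
  V <- matrix(V, ncol = length(layers))
  ok <- rowSums(!is.finite(V)) == 0
  d2 <- rep(NA_real_, nrow(V))
  Si <- tryCatch(solve(Sg), error = function(e)
    stop("singular occurrence covariance despite regularization"))
  d2[ok] <- mahalanobis(V[ok, , drop = FALSE], mu, Si, inverted = TRUE)
  out <- matrix(exp(-d2 / 2), nrow = nrow(layers[[1]]$values))
  ascii_raster(out, layers[[1]]$xllcorner, layers[[1]]$yllcorner,
               layers[[1]]$cellsize)
}

# indices of valid cells within buffer_km of any of the given points
buffer_cells <- function(layers, pts, buffer_km) {
  cc <- raster_coords(layers[[1]])
  V <- vapply(layers, function(l) as.vector(l$values),
              numeric(nrow(cc)))
  ok <- rowSums(!is.finite(matrix(V, nrow = nrow(cc)))) == 0
  inbuf <- rep(FALSE, nrow(cc))
  for (i in seq_len(nrow(pts))) {
    d <- geosphere::distHaversine(cbind(cc$lon, cc$lat),
                                  c(pts$lon[i], pts$lat[i]),
                                  r = 6371008.8) / 1000
    inbuf <- inbuf | d <= buffer_km
  }
  which(ok & inbuf)
}

#' Background (niche similarity) randomization test
#'
#' Compares the empirical niche overlap (Warren's I between the two
#' species' fitted suitability surfaces) with two null distributions: the
#' overlap between species X's surface and surfaces fitted to random
#' points drawn from species Y's background (valid cells within
#' `buffer_km` of Y's occurrences), and vice versa. Per direction, the
#' verdict is `"conservatism"` if the empirical I exceeds the 97.5th
#' percentile of the null, `"divergence"` if below the 2.5th, and
#' `"similarity not rejected"` otherwise.
#'
#' @param occ_x,occ_y occurrence data frames (`lon`, `lat`) for the two
#'   species
#' @param layers named list of climate [ascii_raster()] layers
#' @param estimator niche estimator function taking `(occ, layers)`
#'   (default [envelope_estimator()])
#' @param buffer_km background buffer radius (default 100)
#' @param n_reps null replicates per direction (default 100)
#' @return list of class `background_test`: `I_empirical`, per-direction
#'   `null` distributions, `percentile` positions and `verdict`s
#' @export
background_test <- function(occ_x, occ_y, layers,
                            estimator = envelope_estimator,
                            buffer_km = 100, n_reps = 100) {
  enm_x <- estimator(occ_x, layers)
  enm_y <- estimator(occ_y, layers)
  I_emp <- warren_i(enm_x, enm_y)

  one_direction <- function(enm_fixed, occ_other) {
    cells <- buffer_cells(layers, occ_other, buffer_km)
    if (length(cells) < nrow(occ_other))
      stop("background buffer holds fewer valid cells (", length(cells),
           ") than occurrence points (", nrow(occ_other), ")")
    cc <- raster_coords(layers[[1]])
    vapply(seq_len(n_reps), function(r) {
      pick <- sample(cells, nrow(occ_other))
      occ_r <- data.frame(lon = cc$lon[pick], lat = cc$lat[pick])
      warren_i(enm_fixed, estimator(occ_r, layers))
    }, numeric(1))
  }
  null_x_vs_bgy <- one_direction(enm_x, occ_y)
  null_y_vs_bgx <- one_direction(enm_y, occ_x)

  verdict <- function(null) {
    lo <- quantile(null, 0.025, names = FALSE)
    hi <- quantile(null, 0.975, names = FALSE)
    if (I_emp > hi) "conservatism"
    else if (I_emp < lo) "divergence"
    else "similarity not rejected"
  }
  structure(list(
    I_empirical = I_emp,
    null = list(x_vs_background_y = null_x_vs_bgy,
                y_vs_background_x = null_y_vs_bgx),
    percentile = c(
      x_vs_background_y = mean(null_x_vs_bgy <= I_emp),
      y_vs_background_x = mean(null_y_vs_bgx <= I_emp)),
    verdict = c(x_vs_background_y = verdict(null_x_vs_bgy),
                y_vs_background_x = verdict(null_y_vs_bgx)),
    n_reps = n_reps), class = "background_test")
}

#' @export
print.background_test <- function(x, ...) {
  cat("background similarity test: empirical I =",
      round(x$I_empirical, 4), "\n")
  for (nm in names(x$verdict))
    cat("  ", nm, ": percentile ", round(x$percentile[nm], 3),
        " -> ", x$verdict[nm], "\n", sep = "")
  invisible(x)
}
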