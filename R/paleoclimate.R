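#' Construct a climate grid
#'
#' A regular lat/lon raster of one climate variable at one time slice,
#' stored with rows running north to south (the ESRI ASCII convention).
#'
#' @param values numeric matrix; `values[1, ]` is the northernmost row.
#' @param xll,yll longitude/latitude of the lower-left corner of the
#'   lower-left cell, decimal degrees.
#' @param cellsize cell size in decimal degrees (> 0).
#' @param variable variable name, e.g. `"MAT"` (deg C) or `"MAP"` (mm).
#' @param slice `"present"` or `"LGM"`.
#' @param nodata value marking missing cells (stored as `NA` internally).
#' @return object of class `"climate_grid"`.
#' @export
climate_grid <- function(values, xll, yll, cellsize, variable = "MAT",
                         slice = "present", nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("config error: non-positive grid dimensions")
  if (cellsize <= 0) stop("config error: cellsize must be positive")
  values[values == nodata] <- NA
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 variable = variable, slice = slice, nodata = nodata),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid %s [%s]: %d x %d cells, %.4g deg, origin (%.3f, %.3f)\n",
              x$variable, x$slice, nrow(x$values), ncol(x$values),
              x$cellsize, x$xll, x$yll))
  invisible(x)
}

# cell-center coordinate vectors; rows north->south
grid_lats <- function(g) {
  n <- nrow(g$values)
  g$yll + g$cellsize * (n - seq_len(n) + 0.5)
}
grid_lons <- function(g) g$xll + g$cellsize * (seq_len(ncol(g$values)) - 0.5)

check_georef <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) stop("input error: grid shapes differ")
  if (abs(a$xll - b$xll) > 1e-9 || abs(a$yll - b$yll) > 1e-9 ||
      abs(a$cellsize - b$cellsize) > 1e-12) {
    stop("input error: grid georeferences differ")
  }
  if (!identical(a$variable, b$variable)) {
    stop("input error: grids describe different variables (", a$variable,
         " vs ", b$variable, ")")
  }
  invisible(TRUE)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text `.asc` raster format: six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of cell values, north first.
#'
#' @param path file path.
#' @param variable,slice metadata attached to the grid on read.
#' @return [climate_grid()] for the reader; the writer returns `path`
#'   invisibly.
#' @export
read_esri_ascii <- function(path, variable = "MAT", slice = "present") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2]); names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != ncols * nrows) stop("input error: cell count does not match header")
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  climate_grid(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
               cellsize = val[["cellsize"]],
               nodata = if ("nodata_value" %in% key) val[["nodata_value"]] else -9999,
               variable = variable, slice = slice)
}

#' @rdname read_esri_ascii
#' @param grid a [climate_grid()].
#' @export
write_esri_ascii <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", format(grid$xll, digits = 12)),
               paste("yllcorner", format(grid$yll, digits = 12)),
               paste("cellsize", format(grid$cellsize, digits = 12)),
               paste("NODATA_value", grid$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cellwise mean of two LGM model grids
#'
#' Paleoclimate simulations from different models (the CCSM / MIROC
#' convention) are combined by cellwise averaging before anomaly and
#' velocity are computed.
#'
#' @param a,b [climate_grid()]s of the same variable and georeference.
#' @return a [climate_grid()].
#' @export
lgm_ensemble_mean <- function(a, b) {
  check_georef(a, b)
  out <- a
  out$values <- (a$values + b$values) / 2
  out
}

#' Climate anomaly between present and LGM
#'
#' Cellwise absolute difference `|present - LGM|`, a sign-free measure of
#' the magnitude of late-Quaternary change in the variable.
#'
#' @param present,lgm [climate_grid()]s of the same variable, shape and
#'   georeference.
#' @return a [climate_grid()] (slice `"anomaly"`).
#' @export
anomaly <- function(present, lgm) {
  check_georef(present, lgm)
  out <- present
  out$values <- abs(present$values - lgm$values)
  out$slice <- "anomaly"
  out
}

KM_PER_DEG <- 111.195  # mean-earth-radius degree of latitude, km

#' Spatial gradient of a climate grid
#'
#' Per-cell slope magnitude in variable units per km from the 3x3
#' neighborhood. The default `"average_maximum"` kernel is the standard
#' finite-difference slope (Horn weights 1-2-1 on each flank); the
#' `"central"` kernel uses plain central differences. East-west cell size
#' is scaled by `cos(latitude)`; edge cells use the available neighbors
#' (edge replication). Missing neighbors are replaced by the focal value.
#'
#' @param grid a [climate_grid()], at least 3x3.
#' @param kernel `"average_maximum"` or `"central"`.
#' @return a [climate_grid()] of slopes (units per km).
#' @export
spatial_gradient <- function(grid, kernel = c("average_maximum", "central")) {
  kernel <- match.arg(kernel)
  z <- grid$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("input error: gradient needs a grid of at least 3x3")
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # replicate-pad
  ctr <- zp[2:(nr + 1), 2:(nc + 1)]
  nb <- function(dr, dc) {
    m <- zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    m[is.na(m)] <- ctr[is.na(m)]
    m
  }
  lat <- grid_lats(grid)
  dx_km <- matrix(grid$cellsize * KM_PER_DEG * cos(lat * pi / 180), nr, nc)
  dy_km <- grid$cellsize * KM_PER_DEG
  if (kernel == "average_maximum") {
    dzdx <- ((nb(-1, 1) + 2 * nb(0, 1) + nb(1, 1)) -
             (nb(-1, -1) + 2 * nb(0, -1) + nb(1, -1))) / (8 * dx_km)
    dzdy <- ((nb(-1, -1) + 2 * nb(-1, 0) + nb(-1, 1)) -
             (nb(1, -1) + 2 * nb(1, 0) + nb(1, 1))) / (8 * dy_km)
  } else {
    dzdx <- (nb(0, 1) - nb(0, -1)) / (2 * dx_km)
    dzdy <- (nb(-1, 0) - nb(1, 0)) / (2 * dy_km)
  }
  out <- grid
  out$values <- sqrt(dzdx^2 + dzdy^2)
  out$values[is.na(z)] <- NA
  out$slice <- paste0(grid$slice, "_gradient")
  out
}

#' Climate-change velocity from anomaly and spatial gradient
#'
#' Velocity (km per yr) is the temporal rate of change (anomaly divided by
#' `years`) divided by the local spatial gradient, the displacement rate a
#' population must sustain to track its climate. Gradients below
#' `gradient_floor` are floored to keep velocities finite on flat terrain;
#' floored cells are flagged in `capped`.
#'
#' @param anomaly_grid anomaly [climate_grid()] (variable units).
#' @param gradient_grid matching gradient grid (units per km).
#' @param years elapsed time, default 21000 (LGM to present).
#' @param gradient_floor minimum gradient, units per km.
#' @return list of class `"velocity_result"`: `anomaly`, `temporal_rate`
#'   (units/yr), `gradient`, `velocity` (km/yr) grids, `years`, and
#'   logical `capped` matrix.
#' @export
velocity <- function(anomaly_grid, gradient_grid, years = 21000,
                     gradient_floor = 1e-5) {
  if (!identical(dim(anomaly_grid$values), dim(gradient_grid$values))) {
    stop("input error: anomaly and gradient grids differ in shape")
  }
  if (length(years) != 1 || is.na(years) || years <= 0) {
    stop("input error: years must be positive")
  }
  rate <- anomaly_grid
  rate$values <- anomaly_grid$values / years
  rate$slice <- "temporal_rate"
  capped <- !is.na(gradient_grid$values) & gradient_grid$values < gradient_floor
  vel <- anomaly_grid
  vel$values <- rate$values / pmax(gradient_grid$values, gradient_floor)
  vel$slice <- "velocity"
  structure(list(anomaly = anomaly_grid, temporal_rate = rate,
                 gradient = gradient_grid, velocity = vel,
                 years = years, capped = capped),
            class = "velocity_result")
}

#' Extract grid values at point coordinates
#'
#' Nearest-cell (containing-cell) lookup.
#'
#' @param grid a [climate_grid()].
#' @param coords data frame with `lat` and `lon` columns (and optionally
#'   `sample` or `site` used in error messages and names).
#' @return named numeric vector, one value per row of `coords`.
#' @export
extract_at <- function(grid, coords) {
  lat <- coords$lat; lon <- coords$lon
  id <- coords$sample %||% coords$site %||% rownames(coords) %||% seq_along(lat)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_from_s <- floor((lat - grid$yll) / grid$cellsize) + 1  # 1 = southernmost
  bad <- col < 1 | col > nc | row_from_s < 1 | row_from_s > nr | is.na(lat) | is.na(lon)
  if (any(bad)) {
    stop("input error: coordinates outside grid extent for: ",
         paste(id[bad], collapse = ", "))
  }
  row <- nr - row_from_s + 1
  out <- grid$values[cbind(row, col)]
  names(out) <- id
  out
}

#' Per-site paleoclimate covariates
#'
#' Computes the four late-Quaternary change covariates (MAT velocity, MAP
#' velocity, MAT anomaly, MAP anomaly) from paired present/LGM grids and
#' extracts them at sample locations.
#'
#' @param climate_grids list with `$MAT`/`$MAP`, each `$present`/`$lgm`.
#' @param coords data frame with `lat`/`lon` (and `sample` ids).
#' @param years elapsed years, default 21000.
#' @param gradient_floor passed to [velocity()].
#' @return data frame with columns `mat_anomaly`, `map_anomaly`,
#'   `mat_velocity`, `map_velocity`, one row per coordinate.
#' @export
paleoclimate_covariates <- function(climate_grids, coords, years = 21000,
                                    gradient_floor = 1e-5) {
  one <- function(v) {
    an <- anomaly(climate_grids[[v]]$present, climate_grids[[v]]$lgm)
    gr <- spatial_gradient(climate_grids[[v]]$present)
    vel <- velocity(an, gr, years = years, gradient_floor = gradient_floor)
    list(anomaly = extract_at(an, coords),
         velocity = extract_at(vel$velocity, coords))
  }
  mat <- one("MAT"); map <- one("MAP")
  data.frame(mat_anomaly = mat$anomaly, map_anomaly = map$anomaly,
             mat_velocity = mat$velocity, map_velocity = map$velocity,
             row.names = coords$sample %||% coords$site %||% rownames(coords))
}
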