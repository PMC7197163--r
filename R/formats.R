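# I/O for the plain-text formats the pipeline consumes and emits:
# ESRI ASCII grids, GeoJSON vector layers, and GPS fix CSVs.

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return List with `grid` (matrix, row 1 = southernmost row, column 1 =
#'   westernmost column), `origin` (xll, yll), `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  stopifnot(length(vals) == nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # file rows run north->south
  m <- m[nr:1L, , drop = FALSE]                          # internal rows run south->north
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  list(grid = m, origin = c(hdr$xllcorner, hdr$yllcorner),
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#' @param grid matrix (row 1 = south); @param origin c(xll, yll);
#' @param cellsize cell edge (m); @param path output; @param nodata sentinel.
#' @export
write_ascii_grid <- function(grid, origin, cellsize, path, nodata = -9999) {
  nr <- nrow(grid); nc <- ncol(grid)
  g <- grid[nr:1L, , drop = FALSE]
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1L]), sprintf("yllcorner %.10g", origin[2L]),
           sprintf("cellsize %.10g", cellsize), sprintf("NODATA_value %.10g", nodata))
  body <- apply(g, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GeoJSON layer into coordinate parts
#'
#' Supports FeatureCollections of LineString, MultiLineString, Polygon and
#' MultiPolygon. Polygon holes are kept as additional rings (even-odd rule).
#'
#' @param path GeoJSON file path.
#' @return List with `kind` ("lines" or "polygons") and `parts`, a list of
#'   two-column coordinate matrices.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  parts <- list(); kinds <- character(0)
  coord_mat <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1L]], p[[2L]])))
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    ty <- geom$type
    cc <- geom$coordinates
    if (ty == "LineString") {
      parts <- c(parts, list(coord_mat(cc))); kinds <- c(kinds, "lines")
    } else if (ty == "MultiLineString") {
      parts <- c(parts, lapply(cc, coord_mat)); kinds <- c(kinds, "lines")
    } else if (ty == "Polygon") {
      parts <- c(parts, lapply(cc, coord_mat)); kinds <- c(kinds, "polygons")
    } else if (ty == "MultiPolygon") {
      for (poly in cc) parts <- c(parts, lapply(poly, coord_mat))
      kinds <- c(kinds, "polygons")
    } else stop("unsupported GeoJSON geometry type: ", ty)
  }
  kind <- if (length(kinds) && all(kinds == "lines")) "lines" else "polygons"
  list(kind = kind, parts = parts)
}

#' Write coordinate parts as a GeoJSON FeatureCollection
#' @param parts list of two-column matrices; @param kind "lines" or "polygons";
#' @param path output path; @param properties optional list per feature.
#' @export
write_geojson <- function(parts, kind = c("polygons", "lines"), path, properties = NULL) {
  kind <- match.arg(kind)
  feat <- function(m, props) {
    cc <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
    if (kind == "polygons") {
      if (!all(m[1L, ] == m[nrow(m), ])) cc <- c(cc, cc[1L])
      geom <- list(type = "Polygon", coordinates = list(cc))
    } else geom <- list(type = "LineString", coordinates = cc)
    list(type = "Feature", properties = props, geometry = geom)
  }
  feats <- lapply(seq_along(parts), function(i)
    feat(parts[[i]], if (is.null(properties)) structure(list(), names = character(0)) else properties[[i]]))
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GPS fix table
#'
#' Expected columns: animal_id, species, sex, timestamp (ISO-8601, UTC),
#' x, y, elevation (projected metres).
#'
#' @param path CSV path.
#' @return Data frame with parsed POSIXct timestamps, ordered by animal and time.
#' @export
read_fix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "species", "sex", "timestamp", "x", "y", "elevation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix CSV missing columns: ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  df[order(df$animal_id, df$timestamp), , drop = FALSE]
}

#' Write a GPS fix table
#' @param df fix data frame; @param path output CSV.
#' @export
write_fix_csv <- function(df, path) {
  out <- df
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
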