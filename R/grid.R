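#' Construct a raster grid
#'
#' A `Grid` is the package's universal raster currency: a rectangular matrix
#' of cell values on a shared planar coordinate system. Row 1 is the
#' northernmost row; `(origin_x, origin_y)` is the outer top-left corner of
#' the grid in map units (metres); cells are square with edge `cell_size`.
#' Missing cells are held as `NA` internally and written out as the `nodata`
#' sentinel.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param origin_x,origin_y Map coordinates (m) of the outer top-left corner.
#' @param cell_size Cell edge length in metres; must be positive.
#' @param nodata Sentinel value used on disk for missing cells.
#' @param band_name Free-text label for the layer.
#' @return An object of class `Grid`.
#' @examples
#' g <- new_grid(matrix(1:9, 3, 3), cell_size = 30)
#' grid_extent(g)
#' @export
new_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                     cell_size = 30, nodata = -9999, band_name = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata), band_name = as.character(band_name)),
    class = "Grid"
  )
}

#' Construct a categorical grid
#'
#' A `CategoricalGrid` is a [new_grid()] whose values are small non-negative
#' integer class codes with an attached legend. Every non-nodata value must
#' appear in the legend.
#'
#' @inheritParams new_grid
#' @param legend Named character vector mapping class code (name) to class
#'   label, e.g. `c("1" = "forest", "2" = "agriculture")`.
#' @return An object of class `c("CategoricalGrid", "Grid")`.
#' @export
new_categorical_grid <- function(values, legend, origin_x = 0,
                                 origin_y = nrow(values) * cell_size,
                                 cell_size = 30, nodata = -9999,
                                 band_name = "") {
  g <- new_grid(values, origin_x, origin_y, cell_size, nodata, band_name)
  codes <- suppressWarnings(as.integer(names(legend)))
  if (any(is.na(codes))) stop("legend names must be integer class codes", call. = FALSE)
  v <- g$values[!is.na(g$values)]
  if (length(v) && (any(v != round(v)) || any(!(v %in% codes)))) {
    stop("grid contains values not present in the legend", call. = FALSE)
  }
  g$legend <- stats::setNames(as.character(legend), as.character(codes))
  class(g) <- c("CategoricalGrid", "Grid")
  g
}

#' @export
print.Grid <- function(x, ...) {
  cat(sprintf("<%s> %dx%d cells @ %g m%s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              if (nzchar(x$band_name)) paste0(" [", x$band_name, "]") else ""))
  cat(sprintf("  origin: (%g, %g)  nodata cells: %d\n",
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  if (!is.null(x$legend)) {
    cat("  legend:", paste(names(x$legend), x$legend, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Grids are aligned iff they share shape, origin and cell size; every
#' multi-layer operation in the package requires alignment.
#'
#' @param a,b `Grid` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) stop(what, " are not aligned (shape/origin/cell_size differ)", call. = FALSE)
  invisible(TRUE)
}

#' Map extent of a grid
#'
#' @param g A `Grid`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (outer edges).
#' @export
grid_extent <- function(g) {
  c(xmin = g$origin_x,
    xmax = g$origin_x + ncol(g$values) * g$cell_size,
    ymin = g$origin_y - nrow(g$values) * g$cell_size,
    ymax = g$origin_y)
}

#' Cell-centre coordinates
#'
#' Returns the map coordinates of every cell centre, as matrices shaped
#' like `g$values`.
#'
#' @param g A `Grid`.
#' @return List with matrices `x` and `y` of the same shape as `g$values`.
#' @export
cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  x <- matrix(g$origin_x + (seq_len(nc) - 0.5) * g$cell_size, nr, nc, byrow = TRUE)
  y <- matrix(g$origin_y - (seq_len(nr) - 0.5) * g$cell_size, nr, nc)
  list(x = x, y = y)
}

#' Locate points on a grid
#'
#' Assigns each point to its containing cell under the half-open convention
#' `x in [left, right)`, `y in (bottom, top]`, so points on shared cell
#' boundaries resolve deterministically.
#'
#' @param g A `Grid`.
#' @param x,y Numeric vectors of map coordinates.
#' @return Data frame with columns `row`, `col` (`NA` outside the extent).
#' @export
locate_cells <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1L
  row <- ceiling((g$origin_y - y) / g$cell_size)
  row[g$origin_y - y == 0] <- 1L  # top edge belongs to row 1
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Single-band plain-text raster with `ncols/nrows/xllcorner/yllcorner/
#' cellsize/nodata_value` header. Files with rectangular (non-square) cells
#' (`dx`/`dy` headers) are rejected: the analysis assumes square cells.
#'
#' @param path Path to a `.asc` file.
#' @param band_name Optional label attached to the returned grid.
#' @return A `Grid`; nodata cells are `NA`.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, band_name = "") {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (is.na(suppressWarnings(as.numeric(key)))) {
      hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  if (any(c("dx", "dy") %in% names(hdr))) {
    stop("raster has rectangular (non-square) cells; only square cells are supported",
         call. = FALSE)
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("cell count does not match header in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  new_grid(m,
           origin_x = hdr$xllcorner,
           origin_y = hdr$yllcorner + nr * hdr$cellsize,
           cell_size = hdr$cellsize, nodata = nodata, band_name = band_name)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full precision (17 significant digits) so a
#' write/read round trip reproduces values, nodata, origin and cell size
#' exactly.
#'
#' @param g A `Grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", g$origin_x),
           sprintf("yllcorner %.17g", g$origin_y - nr * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("nodata_value %.17g", g$nodata))
  m <- g$values
  m[is.na(m)] <- g$nodata
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Area covered by one class, in hectares
#'
#' Counts the cells carrying `code` and converts the count to hectares with
#' the square of the cell size; nodata cells never contribute.
#'
#' @param cg A `CategoricalGrid`.
#' @param code Integer class code; must be present in the legend.
#' @return Area in hectares.
#' @examples
#' cg <- new_categorical_grid(matrix(1, 10, 10), legend = c("1" = "agriculture"))
#' class_area(cg, 1)  # 100 cells x 900 m2 = 9 ha
#' @export
class_area <- function(cg, code) {
  if (!as.character(code) %in% names(cg$legend)) {
    stop("unknown class code: ", code, call. = FALSE)
  }
  sum(cg$values == code, na.rm = TRUE) * cg$cell_size^2 / 1e4
}

#' Total non-nodata area of a grid, in hectares
#'
#' @param g A `Grid`.
#' @return Area in hectares.
#' @export
total_area <- function(g) {
  sum(!is.na(g$values)) * g$cell_size^2 / 1e4
}

#' Mask a grid by one class of a categorical grid
#'
#' Cells of `g` where `mask` differs from `keep` (or is nodata) become
#' nodata; all other cells pass through unchanged. Used to restrict the
#' suitability analysis to classified agricultural land.
#'
#' @param g A `Grid` to be masked.
#' @param mask An aligned `CategoricalGrid`.
#' @param keep Class code of `mask` to retain.
#' @return A `Grid` like `g`.
#' @export
apply_mask <- function(g, mask, keep) {
  stop_if_misaligned(g, mask)
  out <- g
  out$values[is.na(mask$values) | mask$values != keep] <- NA_real_
  out
}

#' Aggregate a grid to a coarser resolution
#'
#' Block aggregation by an integer factor: block mean for continuous grids,
#' block mode (nearest-dominant) for categorical grids. Used to bring a
#' finer DEM onto the analysis grid.
#'
#' @param g A `Grid`.
#' @param factor Integer >= 1; output cell size is `factor * cell_size`.
#' @param method `"mean"` or `"mode"`.
#' @return A coarser `Grid` covering the same origin.
#' @export
aggregate_grid <- function(g, factor, method = c("mean", "mode")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be a positive integer", call. = FALSE)
  nr <- nrow(g$values) %/% factor; nc <- ncol(g$values) %/% factor
  if (nr < 1 || nc < 1) stop("grid too small for aggregation factor", call. = FALSE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(nc)) {
      block <- g$values[rows, ((j - 1) * factor + 1):(j * factor)]
      block <- block[!is.na(block)]
      if (!length(block)) next
      out[i, j] <- if (method == "mean") mean(block) else
        as.numeric(names(which.max(table(block))))
    }
  }
  g2 <- new_grid(out, g$origin_x, g$origin_y, g$cell_size * factor,
                 g$nodata, g$band_name)
  if (!is.null(g$legend)) {
    g2$legend <- g$legend
    class(g2) <- c("CategoricalGrid", "Grid")
  }
  g2
}
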