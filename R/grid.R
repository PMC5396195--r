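#' Construct a categorical land-cover grid
#'
#' A regular raster of integer land-cover class codes (30 m cells for
#' Cropland-Data-Layer-style data) plus a class map assigning every code
#' a name and an analysis group: `natural`, `agricultural`, `apple`
#' (the focal crop) or `other`.
#'
#' @param codes Integer matrix of class codes; row 1 is the northernmost
#'   row (the usual ASCII grid layout).
#' @param cell_size Cell edge length in metres (> 0).
#' @param xll,yll Coordinates of the lower-left corner of the grid, metres.
#' @param nodata Code used for missing cells.
#' @param class_map Tibble with columns `code`, `name`, `group`.
#' @return An object of class `land_cover_grid`.
#' @export
land_cover_grid <- function(codes, cell_size, xll = 0, yll = 0,
                            nodata = -9999L, class_map) {
  if (!is.matrix(codes)) abort("`codes` must be a matrix.")
  if (!is.finite(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be strictly positive.")
  }
  class_map <- as_tibble(class_map)
  stopifnot(all(c("code", "name", "group") %in% names(class_map)))
  bad_group <- setdiff(unique(class_map$group),
                       c("natural", "agricultural", "apple", "other"))
  if (length(bad_group) > 0) {
    abort(paste0("Unknown land-cover group(s): ",
                 paste(bad_group, collapse = ", ")))
  }
  present <- setdiff(unique(as.vector(codes)), nodata)
  unknown <- setdiff(present, class_map$code)
  if (length(unknown) > 0) {
    abort(paste0("Grid contains class code(s) with no class-map entry: ",
                 paste(sort(unknown), collapse = ", ")))
  }
  structure(
    list(codes = codes, cell_size = cell_size, xll = xll, yll = yll,
         nodata = nodata, class_map = class_map),
    class = "land_cover_grid")
}

#' Read an ESRI ASCII land-cover grid with its class map
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' whitespace-separated cell values, and a `class_map.csv` with columns
#' `code,name,group`. Every code present in the grid must have a class-map
#' entry; unknown codes are a hard error listing the offenders.
#'
#' @param path Path to the `.asc` grid.
#' @param classmap_path Path to the class map CSV.
#' @return A [land_cover_grid()] object.
#' @export
read_grid <- function(path, classmap_path) {
  lines <- readLines(path, n = 6)
  header <- list()
  n_header <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      header[[key]] <- as.numeric(parts[2])
      n_header <- n_header + 1
    } else break
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(required %in% names(header))) {
    abort("Malformed ESRI ASCII grid header.")
  }
  nodata <- if ("nodata_value" %in% names(header)) {
    as.integer(header$nodata_value)
  } else -9999L
  vals <- scan(path, what = integer(), skip = n_header, quiet = TRUE)
  ncols <- as.integer(header$ncols)
  nrows <- as.integer(header$nrows)
  if (length(vals) != ncols * nrows) {
    abort(sprintf("Grid body has %d values; header promises %d.",
                  length(vals), ncols * nrows))
  }
  codes <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  class_map <- readr::read_csv(classmap_path, col_types = readr::cols(
    code = readr::col_integer(),
    name = readr::col_character(),
    group = readr::col_character()
  ))
  land_cover_grid(codes, cell_size = header$cellsize,
                  xll = header$xllcorner, yll = header$yllcorner,
                  nodata = nodata, class_map = class_map)
}

#' Write a land-cover grid as ESRI ASCII plus class map
#'
#' @param grid A [land_cover_grid()] object.
#' @param path Output `.asc` path.
#' @param classmap_path Optional output path for the class map CSV.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, classmap_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("ncols %d\n", ncol(grid$codes)),
      sprintf("nrows %d\n", nrow(grid$codes)),
      sprintf("xllcorner %.6g\n", grid$xll),
      sprintf("yllcorner %.6g\n", grid$yll),
      sprintf("cellsize %.6g\n", grid$cell_size),
      sprintf("NODATA_value %d\n", grid$nodata),
      file = con, sep = "")
  writeLines(apply(grid$codes, 1, paste, collapse = " "), con)
  if (!is.null(classmap_path)) {
    readr::write_csv(grid$class_map, classmap_path)
  }
  invisible(path)
}

#' @export
print.land_cover_grid <- function(x, ...) {
  cat(sprintf("Land-cover grid: %d x %d cells of %g m\n",
              nrow(x$codes), ncol(x$codes), x$cell_size))
  cat(sprintf("  origin (xll, yll): %g, %g\n", x$xll, x$yll))
  tab <- table(factor(x$class_map$group[match(as.vector(x$codes),
                                              x$class_map$code)],
                      levels = c("natural", "agricultural", "apple",
                                 "other")))
  n <- sum(tab)
  if (n > 0) {
    cat("  composition:",
        paste(sprintf("%s %.1f%%", names(tab), 100 * tab / n),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Cell-centre coordinates. Row 1 of `codes` is the top (north) row.
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$codes)
  nc <- ncol(grid$codes)
  list(
    x = grid$xll + (seq_len(nc) - 0.5) * grid$cell_size,
    y = grid$yll + (nr - seq_len(nr) + 0.5) * grid$cell_size
  )
}
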