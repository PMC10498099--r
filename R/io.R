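# Grid and curve I/O: MetaImage (.mhd/.raw) reader/writer for density and
# dose grids, CSV curves, JSON configuration.  World coordinates are mm with
# a voxel-corner origin; axis order x, y, z (column-major).

#' Write a 3-D grid to MetaImage (.mhd + .raw)
#'
#' @param arr Numeric 3-D array (or `dose_grid` / `voxel_phantom`, whose
#'   dose / density array is written).
#' @param path Path of the `.mhd` header; the `.raw` file sits beside it.
#' @param spacing Voxel spacing in mm (taken from the object if available).
#' @return `path`, invisibly.
#' @export
write_mhd <- function(arr, path, spacing = c(1, 1, 1)) {
  if (inherits(arr, "dose_grid")) { spacing <- arr$spacing; arr <- arr$dose }
  if (inherits(arr, "voxel_phantom")) { spacing <- arr$spacing; arr <- arr$rho }
  stopifnot(length(dim(arr)) == 3)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           "Offset = 0 0 0",
           sprintf("ElementSpacing = %g %g %g", spacing[1], spacing[2],
                   spacing[3]),
           sprintf("DimSize = %d %d %d", dim(arr)[1], dim(arr)[2],
                   dim(arr)[3]),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage grid written by [write_mhd()]
#'
#' Supports the uncompressed MET_DOUBLE/MET_FLOAT local-file layout.
#'
#' @param path Path of the `.mhd` header.
#' @return List with `array` and `spacing`.
#' @export
read_mhd <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  type <- get("ElementType")
  size <- if (identical(type, "MET_FLOAT")) 4L else 8L
  raw_file <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_file, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(dims), size = size,
                  endian = "little")
  list(array = array(vals, dims), spacing = spacing)
}

#' Build a voxel phantom from a MetaImage density grid
#'
#' Reads a mass-density grid (g/cm^3) written in the package's MetaImage
#' layout and wraps it as a water-equivalent-scaled `voxel_phantom`
#' (relative electron and core densities equal the relative mass density).
#'
#' @param path Path of the `.mhd` header.
#' @return A `voxel_phantom`.
#' @export
phantom_from_mhd <- function(path) {
  g <- read_mhd(path)
  if (any(g$array < 0)) stop("density grid contains negative values")
  structure(list(dims = dim(g$array), spacing = g$spacing, rho = g$array,
                 rho_e_rel = g$array, rho_c_rel = g$array,
                 extent_mm = dim(g$array) * g$spacing),
            class = "voxel_phantom")
}

#' Write depth-dose / profile curves to CSV
#' @param curves List of data frames (as from [extract_curves()]), or a
#'   single data frame.
#' @param path Output CSV (single data frame) or directory (list).
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (is.data.frame(curves)) {
    utils::write.csv(curves, path, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(curves)) {
      utils::write.csv(curves[[nm]], file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a beam/calculation configuration from JSON
#'
#' Validates the minimal schema (`particle`, `phantom`, `beam`) and returns
#' the parsed list with defaults filled in.
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$particle) || !cfg$particle %in% c("photon", "proton")) {
    stop("config: 'particle' must be \"photon\" or \"proton\"")
  }
  if (is.null(cfg$phantom)) stop("config: 'phantom' section missing")
  cfg$iterations <- if (is.null(cfg$iterations)) 5L else as.integer(cfg$iterations)
  cfg$quadrature <- if (is.null(cfg$quadrature)) "standard" else cfg$quadrature
  if (!cfg$quadrature %in% c("standard", "fine")) {
    stop("config: 'quadrature' must be \"standard\" or \"fine\"")
  }
  cfg$adaptive <- isTRUE(cfg$adaptive)
  cfg
}
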