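#' Read a hyperspectral cube from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`envi`}{ENVI header + flat binary. The header is `<path>.hdr` (or
#'     `path` with its extension replaced by `.hdr`). BSQ, BIL and BIP
#'     interleaves and data types 1, 2, 4, 5 and 12 are read.}
#'   \item{`tiff`}{Multi-page TIFF band stack, one page per band, with a JSON
#'     sidecar `<path>.json` carrying the wavelength grid and the intensity
#'     scale used at write time.}
#'   \item{`hdf5`}{HDF5 file with datasets `/values`, `/wavelengths` and a
#'     JSON-encoded `/meta`.}
#' }
#' A cube without wavelength metadata is an error unless `wavelengths` is
#' supplied.
#'
#' @param path file path (for ENVI, the binary data file).
#' @param format one of `"auto"`, `"envi"`, `"tiff"`, `"hdf5"`; `"auto"`
#'   dispatches on the file extension.
#' @param wavelengths optional explicit wavelength grid (nm) overriding or
#'   supplying file metadata.
#' @return An [hsi_cube].
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = c("auto", "envi", "tiff", "hdf5"),
                      wavelengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_cube_format(path)
  switch(format,
         envi = read_cube_envi(path, wavelengths),
         tiff = read_cube_tiff(path, wavelengths),
         hdf5 = read_cube_hdf5(path, wavelengths))
}

#' Write a hyperspectral cube to disk
#'
#' See [read_cube()] for the dialects.  ENVI is written as 64-bit float BSQ
#' (bit-exact round trip); TIFF as 32-bit float pages holding
#' `values / tiff_scale` (the `tiff` writer stores only \[0, 1\], so values
#' are scaled down by the clamp ceiling and restored on read); HDF5 stores
#' the double array directly (bit-exact).
#'
#' @param cube an [hsi_cube].
#' @param path destination path.
#' @param format `"envi"`, `"tiff"` or `"hdf5"` (`"auto"` = by extension).
#' @param tiff_scale divisor applied before TIFF storage (default 1.2,
#'   the calibration clamp ceiling).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "tiff", "hdf5"),
                       tiff_scale = 1.2) {
  stopifnot(is_hsi_cube(cube))
  format <- match.arg(format)
  if (format == "auto") format <- guess_cube_format(path)
  switch(format,
         envi = write_cube_envi(cube, path),
         tiff = write_cube_tiff(cube, path, tiff_scale),
         hdf5 = write_cube_hdf5(cube, path))
  invisible(path)
}

guess_cube_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) return("hdf5")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("dat", "raw", "img", "bsq", "envi", "hdr")) return("envi")
  stop("cannot guess cube format from extension: ", path)
}

envi_header_path <- function(path) {
  ext <- tools::file_ext(path)
  if (tolower(ext) == "hdr") return(path)
  if (nzchar(ext)) paste0(tools::file_path_sans_ext(path), ".hdr")
  else paste0(path, ".hdr")
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  body <- paste(txt, collapse = "\n")
  fields <- list()
  # split on lines that look like "key = value", letting values span lines
  # within braces
  pat <- "(?s)([a-zA-Z][a-zA-Z0-9 _.]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)
  starts <- m[[1]]
  if (starts[1L] == -1L) stop("unparseable ENVI header: ", hdr_path)
  caps <- regmatches(body, m)[[1]]
  for (chunk in caps) {
    key <- tolower(trimws(sub(pat, "\\1", chunk, perl = TRUE)))
    val <- trimws(sub(pat, "\\2", chunk, perl = TRUE))
    fields[[key]] <- val
  }
  fields
}

envi_list_field <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1L]]))
}

read_cube_envi <- function(path, wavelengths = NULL) {
  hdr <- envi_header_path(path)
  if (!file.exists(hdr)) stop("ENVI header not found: ", hdr)
  if (tolower(tools::file_ext(path)) == "hdr") {
    # caller handed us the header; locate the data file
    cand <- c(tools::file_path_sans_ext(path),
              paste0(tools::file_path_sans_ext(path),
                     c(".dat", ".raw", ".img", ".bsq")))
    path <- cand[file.exists(cand)][1L]
    if (is.na(path)) stop("ENVI data file not found next to ", hdr)
  }
  f <- parse_envi_header(hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("ENVI header missing field(s): ",
                         paste(miss, collapse = ", "))
  W <- as.integer(f[["samples"]]); H <- as.integer(f[["lines"]])
  B <- as.integer(f[["bands"]])
  dtype <- as.integer(f[["data type"]])
  interleave <- tolower(f[["interleave"]])
  big <- !is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) == 1L
  endian <- if (big) "big" else "little"
  spec <- switch(as.character(dtype),
                 "1" = list(what = integer(), size = 1L, signed = FALSE),
                 "2" = list(what = integer(), size = 2L, signed = TRUE),
                 "4" = list(what = numeric(), size = 4L, signed = TRUE),
                 "5" = list(what = numeric(), size = 8L, signed = TRUE),
                 "12" = list(what = integer(), size = 2L, signed = FALSE),
                 stop("unsupported ENVI data type: ", dtype))
  n <- W * H * B
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) != n) stop("ENVI data file shorter than header implies")
  values <- switch(interleave,
                   bsq = aperm(array(v, c(W, H, B)), c(2L, 1L, 3L)),
                   bil = aperm(array(v, c(W, B, H)), c(3L, 1L, 2L)),
                   bip = aperm(array(v, c(B, W, H)), c(3L, 2L, 1L)),
                   stop("unsupported interleave: ", interleave))
  wl <- wavelengths
  if (is.null(wl) && !is.null(f[["wavelength"]]))
    wl <- envi_list_field(f[["wavelength"]])
  if (is.null(wl))
    stop("no wavelength metadata in header; supply `wavelengths`")
  hsi_cube(values, wavelengths = wl,
           meta = list(source = path, format = "envi"))
}

write_cube_envi <- function(cube, path) {
  d <- dim(cube$values)
  hdr <- envi_header_path(path)
  v <- aperm(cube$values, c(2L, 1L, 3L))  # BSQ: sample fastest, then line
  con <- file(path, "wb")
  writeBin(as.vector(v), con, size = 8L, endian = "little")
  close(con)
  writeLines(c(
    "ENVI",
    "description = { hsifuse transmittance cube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 12), collapse = ", "))
  ), hdr)
  path
}

read_cube_tiff <- function(path, wavelengths = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  B <- length(pages)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  values <- array(0, c(H, W, B))
  for (b in seq_len(B)) {
    pg <- pages[[b]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # tolerate grey-stored-as-rgb
    values[, , b] <- pg
  }
  scale <- 1
  side <- paste0(path, ".json")
  wl <- wavelengths
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(wl)) wl <- meta$wavelengths
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  if (is.null(wl))
    stop("no wavelength sidecar for ", path, "; supply `wavelengths`")
  hsi_cube(values * scale, wavelengths = wl,
           meta = list(source = path, format = "tiff"))
}

write_cube_tiff <- function(cube, path, tiff_scale = 1.2) {
  d <- dim(cube$values)
  pages <- lapply(seq_len(d[3L]), function(b) {
    pmin(pmax(cube$values[, , b] / tiff_scale, 0), 1)
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(list(wavelengths = cube$wavelengths,
                            scale = tiff_scale),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  path
}

read_cube_hdf5 <- function(path, wavelengths = NULL) {
  values <- rhdf5::h5read(path, "values")
  wl <- wavelengths
  if (is.null(wl)) {
    wl <- tryCatch(as.numeric(rhdf5::h5read(path, "wavelengths")),
                   error = function(e) NULL)
  }
  meta <- tryCatch(jsonlite::parse_json(rhdf5::h5read(path, "meta"),
                                        simplifyVector = TRUE),
                   error = function(e) list())
  if (is.null(wl))
    stop("no /wavelengths dataset in ", path, "; supply `wavelengths`")
  if (!is.list(meta)) meta <- list()
  meta$source <- path; meta$format <- "hdf5"
  hsi_cube(values, wavelengths = wl, meta = meta)
}

write_cube_hdf5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$values, path, "values")
  rhdf5::h5write(cube$wavelengths, path, "wavelengths")
  meta <- cube$meta
  meta$masked <- NULL  # bulky mask not serialized
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)),
                 path, "meta")
  rhdf5::h5closeAll()
  path
}

#' Save / load a patch-pair set
#'
#' Patch sets are persisted as an HDF5 file with groups `patch_<i>` holding
#' `hr_hsi`, `hr_rgb`, `lr_hsi`, `label`, `origin`, plus a shared
#' `/wavelengths` grid.
#'
#' @param patches list of [patch_pair] objects.
#' @param path HDF5 file path.
#' @return `path` (write) or a list of [patch_pair] (read).
#' @export
write_patch_set <- function(patches, path) {
  stopifnot(length(patches) > 0L)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(patches[[1L]]$hr_hsi$wavelengths, path, "wavelengths")
  rhdf5::h5write(length(patches), path, "n_patches")
  for (i in seq_along(patches)) {
    g <- sprintf("patch_%05d", i)
    rhdf5::h5createGroup(path, g)
    p <- patches[[i]]
    rhdf5::h5write(p$hr_hsi$values, path, paste0(g, "/hr_hsi"))
    rhdf5::h5write(p$hr_rgb$values, path, paste0(g, "/hr_rgb"))
    rhdf5::h5write(p$lr_hsi$values, path, paste0(g, "/lr_hsi"))
    rhdf5::h5write(p$label, path, paste0(g, "/label"))
    rhdf5::h5write(p$origin, path, paste0(g, "/origin"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(path) {
  n <- as.integer(rhdf5::h5read(path, "n_patches"))
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- sprintf("patch_%05d", i)
    out[[i]] <- patch_pair(
      hr_hsi = hsi_cube(rhdf5::h5read(path, paste0(g, "/hr_hsi")), wl),
      hr_rgb = rgb_image(rhdf5::h5read(path, paste0(g, "/hr_rgb"))),
      lr_hsi = hsi_cube(rhdf5::h5read(path, paste0(g, "/lr_hsi")), wl),
      label = as.integer(rhdf5::h5read(path, paste0(g, "/label"))),
      origin = as.integer(rhdf5::h5read(path, paste0(g, "/origin"))))
  }
  rhdf5::h5closeAll()
  out
}
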