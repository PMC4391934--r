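# Wavelength grid, endmember spectra and the spectral-cube container.

#' Wavelength grid for a multispectral acquisition
#'
#' Defines the evenly spaced emission bands of a spectral cube. The default
#' grid is the 21-band acquisition used throughout the package: 450 to
#' 650 nm in 10-nm steps.
#'
#' @param start_nm First band centre in nm.
#' @param stop_nm Last band centre in nm.
#' @param step_nm Band spacing in nm.
#' @return An object of class `wavelength_grid` with elements `start_nm`,
#'   `stop_nm`, `step_nm`, `n_bands` and the vector `wavelengths`.
#' @examples
#' g <- wavelength_grid()
#' g$n_bands  # 21
#' @export
wavelength_grid <- function(start_nm = 450, stop_nm = 650, step_nm = 10) {
  if (!is.finite(start_nm) || !is.finite(stop_nm) || !is.finite(step_nm))
    stop("wavelength grid parameters must be finite", call. = FALSE)
  if (start_nm >= stop_nm) stop("start_nm must be smaller than stop_nm", call. = FALSE)
  if (step_nm <= 0) stop("step_nm must be positive", call. = FALSE)
  span <- (stop_nm - start_nm) / step_nm
  if (abs(span - round(span)) > 1e-8)
    stop("step_nm must divide the grid span exactly", call. = FALSE)
  n <- as.integer(round(span)) + 1L
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         n_bands = n, wavelengths = seq(start_nm, stop_nm, by = step_nm)),
    class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength grid: %g-%g nm, step %g nm (%d bands)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n_bands))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$wavelengths, b$wavelengths, tolerance = 1e-9))
}

#' Emission spectrum sampled on a wavelength grid
#'
#' @param grid A [wavelength_grid()].
#' @param values Non-negative intensity per band (arbitrary units).
#' @param label Optional fluorophore label.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(grid, values, label = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_bands)
    stop("spectrum length does not match the grid band count", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrum values must be finite and non-negative", call. = FALSE)
  structure(list(grid = grid, values = values, label = label), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum%s on %d bands, peak %.3g at %g nm\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$grid$n_bands, max(x$values),
              x$grid$wavelengths[which.max(x$values)]))
  invisible(x)
}

#' Gaussian emission lineshape
#'
#' Evaluates a unit-peak Gaussian emission profile on a wavelength grid:
#' `exp(-4 ln 2 (lambda - peak)^2 / fwhm^2)`. The sampled maximum is exactly
#' 1 when the peak coincides with a grid point and below 1 otherwise.
#'
#' @param peak_nm Peak emission wavelength in nm; must lie within 100 nm of
#'   the grid range.
#' @param fwhm_nm Full width at half maximum in nm (> 0).
#' @param grid A [wavelength_grid()]; default 450-650/10.
#' @return A [spectrum()].
#' @examples
#' s <- gaussian_emission(605, 30)
#' s$values[s$grid$wavelengths == 605]  # exactly 1
#' @export
gaussian_emission <- function(peak_nm, fwhm_nm, grid = wavelength_grid()) {
  if (!is.finite(fwhm_nm) || fwhm_nm <= 0)
    stop("fwhm_nm must be a positive number", call. = FALSE)
  if (!is.finite(peak_nm) || peak_nm < grid$start_nm - 100 || peak_nm > grid$stop_nm + 100)
    stop("peak_nm must lie within 100 nm of the grid range", call. = FALSE)
  v <- exp(-4 * log(2) * (grid$wavelengths - peak_nm)^2 / fwhm_nm^2)
  spectrum(grid, v, label = sprintf("gaussian(%g, %g)", peak_nm, fwhm_nm))
}

#' Endmember library of reference emission spectra
#'
#' Bundles the three reference spectra a cube is decomposed into, in the
#' fixed column order (CK, Ki67, AF). All spectra must share one grid and the
#' resulting bands x 3 matrix must have full column rank.
#'
#' @param ck,ki67,af [spectrum()] objects for the CK fluorophore, the Ki67
#'   fluorophore and tissue autofluorescence.
#' @return An object of class `endmember_library` with elements `ck`, `ki67`,
#'   `af`, `grid` and the bands x 3 `matrix` (columns `ck`, `ki67`, `af`).
#' @export
endmember_library <- function(ck, ki67, af) {
  stopifnot(inherits(ck, "spectrum"), inherits(ki67, "spectrum"), inherits(af, "spectrum"))
  if (!same_grid(ck$grid, ki67$grid) || !same_grid(ck$grid, af$grid))
    stop("all endmember spectra must share one wavelength grid", call. = FALSE)
  E <- cbind(ck = ck$values, ki67 = ki67$values, af = af$values)
  sv <- svd(E, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-8 * max(sv))
    stop("ill-conditioned library: endmember columns are linearly dependent", call. = FALSE)
  structure(list(ck = ck, ki67 = ki67, af = af, grid = ck$grid, matrix = E),
            class = "endmember_library")
}

#' @export
as.matrix.endmember_library <- function(x, ...) x$matrix

#' @export
print.endmember_library <- function(x, ...) {
  sv <- svd(x$matrix, nu = 0, nv = 0)$d
  cat(sprintf("endmember library on %d bands (CK, Ki67, AF), condition number %.2f\n",
              x$grid$n_bands, sv[1] / sv[length(sv)]))
  invisible(x)
}

#' Default QD endmember library
#'
#' Builds the reference library for the standard staining scheme: CK labelled
#' with a 525-nm quantum dot, Ki67 with a 605-nm quantum dot (both modelled as
#' Gaussians with 30 nm FWHM, a typical QD emission width), and a broad
#' tissue-autofluorescence component (Gaussian, peak 500 nm, FWHM 150 nm).
#' Each sampled spectrum is then peak-normalised to a maximum of exactly 1
#' (the 525 and 605 nm peaks fall between the 10-nm grid bands), so the
#' abundance of a pure pixel equals its peak signal intensity.
#'
#' @param grid A [wavelength_grid()]; default 450-650/10 (21 bands).
#' @return An [endmember_library()].
#' @examples
#' lib <- build_default_library()
#' dim(as.matrix(lib))  # 21 x 3
#' @export
build_default_library <- function(grid = wavelength_grid()) {
  peak_norm <- function(s) spectrum(s$grid, s$values / max(s$values), s$label)
  lib <- endmember_library(
    ck   = peak_norm(gaussian_emission(525, 30, grid)),
    ki67 = peak_norm(gaussian_emission(605, 30, grid)),
    af   = peak_norm(gaussian_emission(500, 150, grid)))
  sv <- svd(lib$matrix, nu = 0, nv = 0)$d
  stopifnot(sv[1] / sv[length(sv)] < 50)
  lib
}

#' Multispectral image cube
#'
#' A height x width x bands array of non-negative intensities (arbitrary
#' units) on a wavelength grid, with the acquisition exposure recorded.
#'
#' @param intensities Numeric array, `c(height, width, n_bands)`.
#' @param grid A [wavelength_grid()]; its band count must match `dim(intensities)[3]`.
#' @param exposure_ms Exposure time in milliseconds (default 800).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(intensities, grid = wavelength_grid(), exposure_ms = 800) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be a 3-d array (height x width x bands)", call. = FALSE)
  if (dim(intensities)[3] != grid$n_bands)
    stop(sprintf("band-count mismatch: cube has %d bands, grid declares %d",
                 dim(intensities)[3], grid$n_bands), call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("cube intensities must be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("cube intensities must be non-negative", call. = FALSE)
  if (!is.finite(exposure_ms) || exposure_ms <= 0)
    stop("exposure_ms must be positive", call. = FALSE)
  structure(list(intensities = intensities,
                 height = dim(intensities)[1], width = dim(intensities)[2],
                 grid = grid, exposure_ms = exposure_ms),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("spectral cube %d x %d x %d bands (%g-%g nm), exposure %g ms\n",
              x$height, x$width, x$grid$n_bands,
              x$grid$start_nm, x$grid$stop_nm, x$exposure_ms))
  invisible(x)
}

cube_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "scube"
}

#' Write a spectral cube to disk
#'
#' Two dialects are supported, selected by the file extension:
#' \describe{
#'   \item{`.scube` (canonical)}{a gzipped binary array container — a JSON
#'     header carrying `wavelengths_nm` and `exposure_ms` followed by the
#'     intensities as little-endian doubles. Round-trips bit-exactly.}
#'   \item{`.tif` / `.tiff`}{multi-page TIFF, one 32-bit page per band in
#'     ascending wavelength, for interoperability with image viewers. Pages
#'     are scaled into [0, 1] by a power of two and quantised to 32-bit
#'     samples, giving a relative resolution of about 2^-31 of the cube
#'     maximum; `wavelengths_nm`, `exposure_ms` and the scale are stored in
#'     a JSON sidecar `<path>.json`.}
#' }
#'
#' @param cube A [spectral_cube()].
#' @param path Output path; extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube_format(path) == "tiff") return(write_cube_tiff(cube, path))
  header <- jsonlite::toJSON(list(
    format = "scube", version = 1L,
    height = cube$height, width = cube$width,
    wavelengths_nm = cube$grid$wavelengths,
    exposure_ms = cube$exposure_ms), auto_unbox = TRUE, digits = NA)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.numeric(cube$intensities), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a spectral cube from disk
#'
#' Counterpart of [write_cube()]; the dialect is selected by the extension.
#'
#' @param path File written by [write_cube()].
#' @param grid Optional [wavelength_grid()] the file is expected to match; a
#'   band-count or wavelength mismatch raises a format error.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cube <- if (cube_format(path) == "tiff") read_cube_tiff(path) else read_cube_scube(path)
  if (!is.null(grid)) {
    if (grid$n_bands != cube$grid$n_bands)
      stop(sprintf("format error: file has %d bands but the declared grid has %d",
                   cube$grid$n_bands, grid$n_bands), call. = FALSE)
    if (!same_grid(grid, cube$grid))
      stop("format error: file wavelengths do not match the declared grid", call. = FALSE)
  }
  cube
}

read_cube_scube <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L || hlen > 1e6)
    stop("format error: not a spectral-cube container", call. = FALSE)
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$format, "scube"))
    stop("format error: not a spectral-cube container", call. = FALSE)
  wl <- as.numeric(header$wavelengths_nm)
  grid <- wavelength_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  if (grid$n_bands != length(wl))
    stop("format error: irregular wavelength grid in header", call. = FALSE)
  n <- header$height * header$width * grid$n_bands
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(x) != n)
    stop("format error: truncated cube payload", call. = FALSE)
  spectral_cube(array(x, dim = c(header$height, header$width, grid$n_bands)),
                grid = grid, exposure_ms = header$exposure_ms)
}

write_cube_tiff <- function(cube, path) {
  m <- max(cube$intensities)
  scale <- if (m > 0) 2^ceiling(log2(m)) else 1
  pages <- lapply(seq_len(cube$grid$n_bands),
                  function(b) cube$intensities[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(wavelengths_nm = cube$grid$wavelengths,
                            exposure_ms = cube$exposure_ms, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_cube_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing metadata sidecar ", sidecar, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  wl <- as.numeric(meta$wavelengths_nm)
  grid <- wavelength_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != grid$n_bands)
    stop(sprintf("format error: file has %d bands but the declared grid has %d",
                 length(pages), grid$n_bands), call. = FALSE)
  x <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) x[, , b] <- pages[[b]] * meta$scale
  spectral_cube(x, grid = grid, exposure_ms = meta$exposure_ms)
}
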