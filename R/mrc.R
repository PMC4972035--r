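#' Write a 2D image or 3D stack/volume as MRC2014 (mode 2, float32)
#'
#' Data are stored column-major with x fastest, matching the layout of an R
#' array `a[x, y, z]`; the voxel size (nm) goes into the cell dimensions
#' (stored in Angstrom per the MRC convention).
#'
#' @param data 2D matrix or 3D array of densities.
#' @param path Output file path.
#' @param voxel_size Voxel/pixel size in nm.
#' @param is_stack Logical; `TRUE` marks the file as an image stack
#'   (tilt series), `FALSE` as a volume.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, voxel_size = 1, is_stack = FALSE) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nxstart
  wi(d)                                   # mx my mz
  wf(d * voxel_size * 10)                 # cella, Angstrom
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(data), max(data), mean(data))) # dmin dmax dmean
  wi(if (is_stack) 0L else 1L)            # ispg
  wi(0L)                                  # nsymbt
  wi(rep(0L, 2))                          # extra words 26-27
  writeBin(charToRaw("MRCO"), con)        # exttyp
  wi(20140L)                              # nversion
  wi(rep(0L, 21))                         # remaining extra
  wf(c(0, 0, 0))                          # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little endian
  wf(sd(data))                            # rms
  wi(1L)                                  # nlabl
  lab <- charToRaw(sprintf("%-80s", "multitilt"))
  writeBin(lab, con)
  writeBin(raw(800 - 80), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file written by this package (modes 0, 1, 2)
#'
#' @param path File path.
#' @return List with `data` (3D array), `voxel_size` (nm) and `is_stack`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                 # nxstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)   # cellb, axis order, dmin/dmax/dmean
  ispg <- ri(1)
  seek(con, 1024)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE)
  )
  list(
    data = array(data, dim = d),
    voxel_size = if (mx[1] > 0) cella[1] / mx[1] / 10 else 1,
    is_stack = ispg == 0
  )
}
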