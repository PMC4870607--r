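# Volume I/O: minimal baseline multipage TIFF (uncompressed 8-bit grayscale)
# plus a raw-bytes container with JSON sidecar. No TIFF library exists in the
# offline R stack, so the codec is implemented here; it writes little-endian
# and reads either byte order, and is validated against Python tifffile in
# the test suite. On disk the solid phase is bright: WALL = 255, PORE = 0.

# ---- low-level byte helpers -------------------------------------------------

u16 <- function(raw, pos, le) {
  b <- as.integer(raw[pos + 0:1])
  if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}

u32 <- function(raw, pos, le) {
  b <- as.numeric(raw[pos + 0:3])
  if (le) b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
  else    b[4] + 256 * (b[3] + 256 * (b[2] + 256 * b[1]))
}

w16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                 endian = "little")
w32 <- function(con, x) {
  # uint32 via two 16-bit halves (R integers are signed 32-bit)
  x <- as.numeric(x)
  w16(con, x %% 65536)
  w16(con, x %/% 65536)
}

# ---- TIFF writer ------------------------------------------------------------

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L; TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L; TAG_DESCRIPTION <- 270L; TAG_STRIPOFFSETS <- 273L
TAG_SAMPLES <- 277L; TAG_ROWSPERSTRIP <- 278L; TAG_STRIPBYTES <- 279L
TYPE_SHORT <- 3L; TYPE_LONG <- 4L; TYPE_ASCII <- 2L

write_tiff_volume <- function(grid, path) {
  d <- dim(grid$pore)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  desc <- sprintf("spacing_um=%.17g\n", grid$spacing_um)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  w16(con, 42)
  page_bytes <- ny * nx
  desc_off <- 8
  data_off <- desc_off + length(desc_raw)
  strip_offsets <- data_off + page_bytes * (seq_len(nz) - 1)
  total_data <- data_off + page_bytes * nz
  if (total_data %% 2 == 1) total_data <- total_data + 1
  ifd_entries <- 10L
  ifd_size <- 2 + 12 * ifd_entries + 4
  ifd_offsets <- total_data + ifd_size * (seq_len(nz) - 1)
  w32(con, ifd_offsets[1])
  writeBin(desc_raw, con)
  for (z in seq_len(nz)) {
    # page rows are y, columns are x, row-major (x fastest)
    slab <- t(matrix(grid$pore[z, , ], nrow = ny, ncol = nx))  # [x, y]
    writeBin(as.raw(ifelse(slab, 0L, 255L)), con)
  }
  if ((data_off + page_bytes * nz) %% 2 == 1) writeBin(as.raw(0), con)

  entry <- function(tag, type, count, value) {
    w16(con, tag); w16(con, type); w32(con, count)
    if (type == TYPE_SHORT && count == 1) { w16(con, value); w16(con, 0) }
    else w32(con, value)
  }
  for (z in seq_len(nz)) {
    w16(con, ifd_entries)
    entry(TAG_WIDTH, TYPE_LONG, 1, nx)
    entry(TAG_LENGTH, TYPE_LONG, 1, ny)
    entry(TAG_BITS, TYPE_SHORT, 1, 8)
    entry(TAG_COMPRESSION, TYPE_SHORT, 1, 1)
    entry(TAG_PHOTOMETRIC, TYPE_SHORT, 1, 1)
    entry(TAG_DESCRIPTION, TYPE_ASCII, length(desc_raw), desc_off)
    entry(TAG_STRIPOFFSETS, TYPE_LONG, 1, strip_offsets[z])
    entry(TAG_SAMPLES, TYPE_SHORT, 1, 1)
    entry(TAG_ROWSPERSTRIP, TYPE_LONG, 1, ny)
    entry(TAG_STRIPBYTES, TYPE_LONG, 1, page_bytes)
    w32(con, if (z < nz) ifd_offsets[z + 1] else 0)
  }
  invisible(path)
}

# ---- TIFF reader ------------------------------------------------------------

read_tiff_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  le <- identical(order, "II")
  if (!le && !identical(order, "MM"))
    stop("not a TIFF file: ", path, call. = FALSE)
  if (u16(raw, 3, le) != 42) stop("not a TIFF file: ", path, call. = FALSE)

  ifd_off <- u32(raw, 5, le)
  pages <- list()
  spacing <- NA_real_
  while (ifd_off != 0) {
    nent <- u16(raw, ifd_off + 1, le)
    tags <- list()
    for (i in seq_len(nent)) {
      ep <- ifd_off + 2 + 12 * (i - 1) + 1
      tag <- u16(raw, ep, le)
      type <- u16(raw, ep + 2, le)
      count <- u32(raw, ep + 4, le)
      val_field <- ep + 8
      read_vals <- function() {
        sz <- if (type == TYPE_SHORT) 2 else if (type == TYPE_LONG) 4 else 1
        total <- sz * count
        start <- if (total <= 4) val_field else u32(raw, val_field, le) + 1
        if (type == TYPE_SHORT)
          vapply(seq_len(count), function(k) u16(raw, start + 2 * (k - 1), le),
                 numeric(1))
        else if (type == TYPE_LONG)
          vapply(seq_len(count), function(k) u32(raw, start + 4 * (k - 1), le),
                 numeric(1))
        else rawToChar(raw[start:(start + count - 1)][
          raw[start:(start + count - 1)] != as.raw(0)])
      }
      tags[[as.character(tag)]] <- read_vals()
    }
    gettag <- function(tag, default = NULL) tags[[as.character(tag)]] %||%
      default
    if (!is.null(gettag(TAG_COMPRESSION)) && gettag(TAG_COMPRESSION) != 1)
      stop("only uncompressed TIFF is supported", call. = FALSE)
    if (!is.null(gettag(TAG_BITS)) && any(gettag(TAG_BITS) != 8))
      stop("only 8-bit grayscale TIFF is supported", call. = FALSE)
    if (!is.null(gettag(TAG_SAMPLES)) && gettag(TAG_SAMPLES) != 1)
      stop("only single-sample (grayscale) TIFF is supported", call. = FALSE)
    w <- gettag(TAG_WIDTH); h <- gettag(TAG_LENGTH)
    if (is.null(w) || is.null(h)) stop("malformed TIFF IFD", call. = FALSE)
    offs <- gettag(TAG_STRIPOFFSETS)
    cnts <- gettag(TAG_STRIPBYTES, w * h)
    bytes <- unlist(lapply(seq_along(offs), function(k)
      as.integer(raw[(offs[k] + 1):(offs[k] + cnts[k])])))
    if (length(bytes) != w * h) stop("malformed TIFF strips", call. = FALSE)
    desc <- gettag(TAG_DESCRIPTION)
    if (!is.null(desc) && is.na(spacing)) {
      m <- regmatches(desc, regexec("spacing_um=([0-9.eE+-]+)", desc))[[1]]
      if (length(m) == 2) spacing <- as.numeric(m[2])
    }
    pages[[length(pages) + 1L]] <- t(matrix(bytes, nrow = w, ncol = h))
    ifd_off <- u32(raw, ifd_off + 2 + 12 * nent + 1, le)
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)
  hw <- dim(pages[[1]])
  vol <- array(0L, dim = c(length(pages), hw[1], hw[2]))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), hw))
      stop("TIFF pages have differing dimensions", call. = FALSE)
    vol[z, , ] <- pages[[z]]
  }
  list(values = vol, spacing_um = spacing)
}

# ---- raw container ----------------------------------------------------------

write_raw_volume <- function(grid, path) {
  d <- dim(grid$pore)
  sidecar <- sub("\\.raw$", ".json", path)
  # x fastest, then y, then z ("zyx" C order)
  vals <- aperm(array(ifelse(grid$pore, 0L, 255L), dim = d), c(3, 2, 1))
  writeBin(as.raw(vals), path)
  jsonlite::write_json(
    list(shape = d, spacing_um = grid$spacing_um, axis_order = "zyx",
         dtype = "uint8", wall_value = 255),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_raw_volume <- function(path) {
  sidecar <- sub("\\.raw$", ".json", path)
  if (!file.exists(sidecar))
    stop("raw volume requires a JSON sidecar at ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  if (length(d) != 3) stop("sidecar `shape` must have length 3", call. = FALSE)
  if (!identical(meta$axis_order %||% "zyx", "zyx"))
    stop("only axis_order \"zyx\" is supported", call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) != prod(d))
    stop("raw file size does not match sidecar shape", call. = FALSE)
  vol <- aperm(array(as.integer(bytes), dim = rev(d)), c(3, 2, 1))
  list(values = vol, spacing_um = as.numeric(meta$spacing_um %||% NA_real_))
}

# ---- public interface -------------------------------------------------------

#' Read a 3D volume from disk
#'
#' Reads a multipage TIFF stack (uncompressed 8-bit grayscale; pages are z
#' slices, page rows are y, page columns are x) or a `.raw` byte container
#' with a JSON sidecar (`{shape, spacing_um, axis_order: "zyx"}`). The solid
#' (wall) phase is imaged bright: with no `threshold`, nonzero values become
#' WALL; with a `threshold`, grayscale values `>= threshold` become WALL and
#' values below become PORE.
#'
#' @param path file path (`.tif`/`.tiff` or `.raw`).
#' @param spacing_um voxel edge length in micrometers. Optional if the file
#'   metadata records it; an explicit value overrides metadata.
#' @param threshold optional grayscale threshold for non-binary input.
#' @return a [voxel_grid()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing_um = NULL, threshold = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  res <- if (grepl("\\.raw$", path, ignore.case = TRUE))
    read_raw_volume(path) else read_tiff_volume(path)
  vals <- res$values
  if (length(dim(vals)) != 3) stop("input is not 3D", call. = FALSE)
  wall <- if (is.null(threshold)) vals != 0 else vals >= threshold
  if (is.null(threshold) && !all(vals %in% c(0L, 255L)))
    warning("input is not binary (0/255); mapping all nonzero values to WALL",
            call. = FALSE)
  spacing <- spacing_um %||% res$spacing_um
  if (is.null(spacing) || is.na(spacing))
    stop("no spacing in file metadata; supply `spacing_um`", call. = FALSE)
  voxel_grid(!wall, spacing_um = spacing,
             provenance = paste0("read_volume:", basename(path)))
}

#' Write a 3D volume to disk
#'
#' Writes a multipage TIFF (WALL = 255, PORE = 0, spacing recorded in the
#' ImageDescription as `spacing_um=<float>`) or, for a `.raw` path, a raw
#' byte container plus JSON sidecar. `read_volume(write_volume(g))` is the
#' identity on data and spacing.
#'
#' @param grid a [voxel_grid()].
#' @param path destination path (`.tif`/`.tiff` or `.raw`).
#' @return the path, invisibly.
#' @export
write_volume <- function(grid, path) {
  assert_grid(grid)
  if (grepl("\\.raw$", path, ignore.case = TRUE)) write_raw_volume(grid, path)
  else write_tiff_volume(grid, path)
  invisible(path)
}
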