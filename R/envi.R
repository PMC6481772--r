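# ENVI format I/O: ASCII header (key = value pairs, `{}`-delimited lists)
# plus a raw binary payload in BSQ, BIL or BIP interleave.  Supported data
# types: 2 (int16, promoted to double on read), 4 (float32), 5 (float64).

.envi_types <- data.frame(
  code = c(2L, 4L, 5L),
  what = c("integer", "double", "double"),
  size = c(2L, 4L, 8L),
  stringsAsFactors = FALSE
)

.envi_binary_candidates <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  unique(c(base, paste0(tools::file_path_sans_ext(header_path),
                        c(".img", ".dat", ".raw", ".bsq", ".bil", ".bip"))))
}

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^\\s*ENVI\\s*$", lines[1]))
    stop("malformed ENVI header (missing 'ENVI' magic line): ", header_path)
  txt <- paste(lines[-1], collapse = "\n")
  # join `{ ... }` blocks that span lines, then split into key = value
  fields <- list()
  pos <- 1L
  for (ln in strsplit(txt, "\n", fixed = TRUE)[[1]]) {
    if (grepl("=", ln, fixed = TRUE) || length(fields) == 0L) {
      fields[[length(fields) + 1L]] <- ln
    } else {
      fields[[length(fields)]] <- paste(fields[[length(fields)]], ln)
    }
  }
  out <- list()
  for (f in fields) {
    if (!grepl("=", f, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", f)))
    val <- trimws(sub("^[^=]*=", "", f))
    out[[key]] <- val
  }
  out
}

.header_int <- function(hdr, key, path) {
  v <- hdr[[key]]
  if (is.null(v)) stop("ENVI header missing required key '", key, "': ", path)
  n <- suppressWarnings(as.integer(v))
  if (is.na(n)) stop("ENVI header key '", key, "' is not an integer: ", v)
  n
}

#' Read a hyperspectral cube from an ENVI file pair
#'
#' Resolves the interleave (BSQ/BIL/BIP) and byte order declared in the
#' header so the in-memory layout is always the canonical `W x H x S`
#' array.  A `wavelength` list, if present, populates the wavenumber axis.
#'
#' @param header_path path to the `.hdr` header; the binary companion is
#'   located by stripping the `.hdr` suffix or substituting a standard
#'   extension (`.img`, `.dat`, `.raw`, `.bsq`, `.bil`, `.bip`).
#' @return an [hsi_cube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- .parse_envi_header(header_path)
  W <- .header_int(hdr, "samples", header_path)
  H <- .header_int(hdr, "lines", header_path)
  S <- .header_int(hdr, "bands", header_path)
  dtype <- .header_int(hdr, "data type", header_path)
  ti <- match(dtype, .envi_types$code)
  if (is.na(ti)) stop("unsupported ENVI data type: ", dtype,
                      " (supported: 2, 4, 5)")
  interleave <- toupper(trimws(hdr[["interleave"]] %||% "bsq"))
  if (!interleave %in% c("BSQ", "BIL", "BIP"))
    stop("unsupported ENVI interleave: ", interleave)
  byte_order <- .header_int(hdr, "byte order", header_path)
  endian <- if (byte_order == 0L) "little" else "big"
  offset <- suppressWarnings(as.integer(hdr[["header offset"]] %||% "0"))

  bin <- Filter(file.exists, .envi_binary_candidates(header_path))
  if (length(bin) == 0L)
    stop("binary companion of ", header_path, " not found")
  bin <- bin[1]
  n_vals <- as.double(W) * H * S
  expect_bytes <- n_vals * .envi_types$size[ti] + offset
  if (file.size(bin) != expect_bytes)
    stop(sprintf("binary size mismatch for %s: %d bytes on disk, %d expected from header (samples=%d, lines=%d, bands=%d, data type=%d)",
                 bin, file.size(bin), as.integer(expect_bytes), W, H, S, dtype))
  con <- file(bin, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  vals <- readBin(con, what = .envi_types$what[ti], n = n_vals,
                  size = .envi_types$size[ti], endian = endian,
                  signed = TRUE)
  vals <- as.double(vals)
  cube_arr <- switch(interleave,
    BSQ = array(vals, dim = c(W, H, S)),
    BIL = aperm(array(vals, dim = c(W, S, H)), c(1, 3, 2)),
    BIP = aperm(array(vals, dim = c(S, W, H)), c(2, 3, 1)))

  wn <- NULL
  if (!is.null(hdr[["wavelength"]])) {
    raw_wn <- gsub("[{}]", "", hdr[["wavelength"]])
    wn <- as.numeric(strsplit(raw_wn, ",")[[1]])
    if (length(wn) != S || anyNA(wn)) {
      warning("ignoring malformed wavelength list in ", header_path)
      wn <- NULL
    }
  }
  md <- list()
  if (!is.null(hdr[["description"]]))
    md$description <- gsub("[{}]", "", hdr[["description"]])
  hsi_cube(cube_arr, wavenumbers = wn, interleave_origin = interleave,
           metadata = md)
}

#' Write a cube as an ENVI header + binary pair
#'
#' Wavenumbers are written to the `wavelength` header field with 17
#' significant digits, so a double-precision cube round-trips losslessly
#' through [read_envi()].
#'
#' @param cube an [hsi_cube()].
#' @param header_path output path for the header; the binary payload goes
#'   to the same path with an `.img` extension.
#' @param interleave on-disk layout: `"BSQ"`, `"BIL"` or `"BIP"`.
#' @param data_type ENVI numeric type code: 5 (float64, default), 4
#'   (float32) or 2 (int16).
#' @return invisibly, the binary path.
#' @export
write_envi <- function(cube, header_path, interleave = c("BSQ", "BIL", "BIP"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(toupper(interleave[1]), c("BSQ", "BIL", "BIP"))
  ti <- match(data_type, .envi_types$code)
  if (is.na(ti)) stop("unsupported ENVI data type: ", data_type)
  d <- dim(cube$data)
  bin_path <- paste0(tools::file_path_sans_ext(header_path), ".img")

  arr <- switch(interleave,
    BSQ = cube$data,
    BIL = aperm(cube$data, c(1, 3, 2)),
    BIP = aperm(cube$data, c(3, 1, 2)))
  vals <- as.vector(arr)
  if (data_type == 2L) vals <- as.integer(round(vals))

  hdr <- c(
    "ENVI",
    sprintf("description = {%s}",
            cube$metadata$description %||% "fastMNF export"),
    sprintf("samples = %d", d[1]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", tolower(interleave)),
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavenumbers, digits = 17, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  ok <- tryCatch({
    writeLines(hdr, header_path)
    con <- file(bin_path, "wb")
    writeBin(vals, con, size = .envi_types$size[ti], endian = "little")
    close(con)
    TRUE
  }, error = function(e) stop("failed to write ENVI pair: ",
                              conditionMessage(e)))
  invisible(bin_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
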