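# ABIF (".ab1") reader/writer. Big-endian header, 28-byte directory
# entries; values with <= 4 data bytes live inline in the offset field.

.ABIF_HEADER_SIZE <- 128L

# element type codes used here (Applied Biosystems convention)
.ABIF_TYPE_BYTE <- 1L   # unsigned 8-bit
.ABIF_TYPE_CHAR <- 2L   # 8-bit character
.ABIF_TYPE_SHORT <- 4L  # signed 16-bit
.ABIF_TYPE_DIR <- 1023L

.read_u8 <- function(con, n) readBin(con, "integer", n = n, size = 1L, signed = FALSE)
.read_i16 <- function(con, n) readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "big")
.read_i32 <- function(con, n) readBin(con, "integer", n = n, size = 4L, endian = "big")

#' Canonicalize a well label
#'
#' Converts facility naming dialects ("a1", "A1", "A01", with trailing
#' separators) to the canonical form: uppercase row letter A--P followed by
#' a zero-padded two-digit column 01--24. Labels that do not resolve to a
#' 96- or 384-well coordinate yield \code{NA}.
#'
#' @param x character vector of raw well labels (e.g. the first three
#'   characters of a trace file name).
#' @return character vector of canonical labels, \code{NA} where invalid.
#' @examples
#' canonicalWell(c("A1", "a01", "P24", "Q01", "A25"))
#' @export
canonicalWell <- function(x) {
  x <- toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
  m <- regexec("^([A-P])([0-9]{1,2})$", x)
  vapply(seq_along(x), function(i) {
    g <- regmatches(x[i], m[i])[[1]]
    if (length(g) != 3L) return(NA_character_)
    col <- as.integer(g[3])
    if (col < 1L || col > 24L) return(NA_character_)
    sprintf("%s%02d", g[2], col)
  }, character(1))
}

.well_from_filename <- function(path) {
  canonicalWell(substr(basename(path), 1L, 3L))
}

#' Read an ABIF Sanger trace file
#'
#' Parses an ABIF ".ab1" file into a [Chromatogram-class]. The analysed
#' traces (tags \code{DATA} 9--12), channel order (\code{FWO_}), base calls
#' (\code{PBAS}), per-base Phred qualities (\code{PCON}) and peak locations
#' (\code{PLOC}) are read; for the per-base tags, tag number 1 is preferred
#' over 2 when both are present. Phred values outside 0--62 are clamped
#' with a warning. The plate identifier is taken from the containing folder
#' and the well from the first three characters of the file name.
#'
#' @param path path to an ".ab1" file.
#' @return a [Chromatogram-class] object.
#' @seealso [writeABIF()], [discoverInputs()]
#' @export
readABIF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(rawToChar(magic), "ABIF")) {
    stop("not an ABIF file (bad magic): ", path)
  }
  .read_i16(con, 1L) # version
  root <- .read_abif_entry(con)
  if (length(root$numelements) != 1L || length(root$dataoffset) != 1L ||
      is.na(root$dataoffset)) {
    stop("ABIF directory header truncated: ", path)
  }
  ndir <- root$numelements
  seek(con, root$dataoffset)
  entries <- vector("list", ndir)
  for (i in seq_len(ndir)) entries[[i]] <- .read_abif_entry(con)
  key <- vapply(entries, function(e) paste0(e$name, e$number), character(1))
  names(entries) <- key

  get_tag <- function(name, numbers, required = TRUE) {
    for (num in numbers) {
      e <- entries[[paste0(name, num)]]
      if (!is.null(e)) return(.read_abif_payload(con, e))
    }
    if (required) {
      stop("ABIF tag missing: ", name, paste(numbers, collapse = "/"),
           " in ", path)
    }
    NULL
  }

  fwo <- rawToChar(as.raw(get_tag("FWO_", 1L)))
  data_raw <- lapply(9:12, function(num) get_tag("DATA", num))
  lens <- lengths(data_raw)
  if (length(unique(lens)) != 1L) {
    stop("ABIF DATA9-12 trace arrays differ in length in ", path)
  }
  traces <- vapply(data_raw, function(v) pmax(as.integer(v), 0L),
                   integer(lens[1]))
  if (lens[1] == 0L) traces <- matrix(integer(0), ncol = 4L)
  colnames(traces) <- strsplit(fwo, "")[[1]]

  pbas <- rawToChar(as.raw(get_tag("PBAS", c(1L, 2L))))
  pcon <- as.integer(get_tag("PCON", c(1L, 2L)))
  ploc <- as.integer(get_tag("PLOC", c(1L, 2L)))
  if (nchar(pbas) != length(pcon) || nchar(pbas) != length(ploc)) {
    stop("ABIF per-base tags PBAS/PCON/PLOC disagree in length in ", path)
  }
  if (any(pcon < 0L | pcon > 62L)) {
    warning("Phred qualities outside [0, 62] clamped in ", path)
    pcon <- pmin(pmax(pcon, 0L), 62L)
  }
  pbas <- toupper(pbas)
  pbas <- gsub("[^ACGTN]", "N", pbas)

  well <- .well_from_filename(path)
  new("Chromatogram",
      sourcePath = path,
      plateId = basename(dirname(normalizePath(path))),
      wellId = if (is.na(well)) "" else well,
      channelOrder = fwo,
      traces = traces,
      peakLocations = ploc,
      baseCalls = pbas,
      qualities = pcon)
}

.raw_to_i32 <- function(r) {
  sum(as.integer(r) * c(16777216, 65536, 256, 1))
}

# one 28-byte directory entry; dataoffset kept both raw (inline payloads
# live in that field) and decoded
.read_abif_entry <- function(con) {
  name <- readBin(con, "raw", n = 4L)
  e <- list(
    name = rawToChar(name),
    number = .read_i32(con, 1L),
    elementtype = .read_i16(con, 1L),
    elementsize = .read_i16(con, 1L),
    numelements = .read_i32(con, 1L),
    datasize = .read_i32(con, 1L),
    dataoffset_raw = readBin(con, "raw", n = 4L),
    datahandle = .read_i32(con, 1L)
  )
  if (length(e$dataoffset_raw) == 4L) {
    e$dataoffset <- .raw_to_i32(e$dataoffset_raw)
  } else {
    e$dataoffset <- NA_integer_
  }
  e
}

.read_abif_payload <- function(con, e) {
  if (e$datasize <= 4L) {
    bytes <- e$dataoffset_raw[seq_len(e$datasize)]
  } else {
    seek(con, e$dataoffset)
    bytes <- readBin(con, "raw", n = e$datasize)
  }
  if (length(bytes) < e$datasize) stop("ABIF payload truncated for tag ", e$name)
  switch(as.character(e$elementtype),
    "1" = as.integer(bytes),
    "2" = as.integer(bytes),
    "4" = readBin(bytes, "integer", n = e$numelements, size = 2L,
                  signed = TRUE, endian = "big"),
    stop("unsupported ABIF element type ", e$elementtype, " for tag ", e$name)
  )
}

#' Write a Chromatogram as an ABIF file
#'
#' Serializes a [Chromatogram-class] to a valid ABIF ".ab1" file: big-endian
#' directory header, tags \code{FWO_1}, \code{DATA} 9--12 (short),
#' \code{PLOC}, \code{PBAS} and \code{PCON} (the per-base tags are written
#' under both tag numbers 1 and 2 so that mainstream readers accept the
#' file). The result round-trips through [readABIF()] field-by-field.
#'
#' @param chromatogram a valid [Chromatogram-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeABIF <- function(chromatogram, path) {
  validObject(chromatogram)
  cg <- chromatogram
  if (any(cg@traces > 32767L)) {
    stop("trace intensities exceed the 16-bit ABIF DATA range")
  }

  i16be <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "big")
  i32be <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "big")

  tags <- list()
  add <- function(name, number, type, elsize, payload) {
    tags[[length(tags) + 1L]] <<- list(name = name, number = number,
      type = type, elsize = elsize, n = length(payload) %/% elsize,
      payload = payload)
  }
  fwo <- charToRaw(cg@channelOrder)
  add("FWO_", 1L, .ABIF_TYPE_CHAR, 1L, fwo)
  for (k in 1:4) {
    add("DATA", 8L + k, .ABIF_TYPE_SHORT, 2L, i16be(cg@traces[, k]))
  }
  bas <- charToRaw(cg@baseCalls)
  con_raw <- as.raw(cg@qualities)
  ploc <- i16be(cg@peakLocations)
  for (num in c(1L, 2L)) {
    add("PBAS", num, .ABIF_TYPE_CHAR, 1L, bas)
    add("PCON", num, .ABIF_TYPE_CHAR, 1L, con_raw)
    add("PLOC", num, .ABIF_TYPE_SHORT, 2L, ploc)
  }

  # lay out data blocks after the 128-byte header
  offset <- .ABIF_HEADER_SIZE
  for (i in seq_along(tags)) {
    t <- tags[[i]]
    if (length(t$payload) > 4L) {
      tags[[i]]$offset <- offset
      offset <- offset + length(t$payload)
    } else {
      tags[[i]]$offset <- NA_integer_ # inline
    }
  }
  dir_offset <- offset

  entry_bytes <- function(t) {
    off_field <- if (is.na(t$offset)) {
      c(t$payload, raw(4L - length(t$payload)))
    } else {
      i32be(t$offset)
    }
    c(charToRaw(t$name), i32be(t$number), i16be(t$type), i16be(t$elsize),
      i32be(t$n), i32be(length(t$payload)), off_field, i32be(0L))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  writeBin(i16be(101L), con)
  # root entry describing the directory
  writeBin(c(charToRaw("tdir"), i32be(1L), i16be(.ABIF_TYPE_DIR), i16be(28L),
             i32be(length(tags)), i32be(length(tags) * 28L),
             i32be(dir_offset), i32be(0L)), con)
  writeBin(raw(.ABIF_HEADER_SIZE - 34L), con)
  for (t in tags) if (!is.na(t$offset)) writeBin(t$payload, con)
  for (t in tags) writeBin(entry_bytes(t), con)
  invisible(path)
}

#' Discover plate/well-organised trace files
#'
#' Searches a directory tree recursively for ".ab1" files. Each file's
#' plate is its immediate parent folder and its well the canonicalized
#' first three characters of its file name. Files whose prefix does not
#' resolve to a valid well are reported in a rejects table rather than
#' silently dropped. The listing is deterministic (lexicographic by path)
#' and repeated calls on an unchanged tree return identical results.
#' Multiple files mapping to the same (plate, well) — technical
#' replicates — are all retained here; deduplication happens in
#' [dedupeReplicates()].
#'
#' @param rootDir directory to search.
#' @return a list with elements \code{files} (data.frame: plate_id,
#'   well_id, path) and \code{rejects} (data.frame: path, reason).
#' @export
discoverInputs <- function(rootDir) {
  if (!dir.exists(rootDir)) stop("input directory not found: ", rootDir)
  paths <- sort(list.files(rootDir, pattern = "\\.ab1$", recursive = TRUE,
                           full.names = TRUE, ignore.case = TRUE))
  wells <- .well_from_filename(paths)
  plates <- basename(dirname(paths))
  ok <- !is.na(wells)
  list(
    files = data.frame(plate_id = plates[ok], well_id = wells[ok],
                       path = paths[ok], stringsAsFactors = FALSE),
    rejects = data.frame(path = paths[!ok],
                         reason = rep("unparseable well prefix", sum(!ok)),
                         stringsAsFactors = FALSE)
  )
}
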