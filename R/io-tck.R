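#' @include AllClasses.R
NULL

## MRtrix track file dialect handled here:
##   text header starting with the magic line "mrtrix tracks", "key: value"
##   lines including datatype (Float32LE/Float32BE), optional count, and
##   "file: . <offset>" giving the byte offset of the binary section; header
##   closed by END. Binary section: 32-bit float triplets, one (NaN,NaN,NaN)
##   triple after each streamline, one (Inf,Inf,Inf) triple terminating the
##   file. Coordinates are world-space mm. Writes are little-endian.

#' Read an MRtrix track file
#'
#' Parses the text header, locates the binary section through the declared
#' byte offset, and splits the 32-bit float triplet stream on NaN-triple
#' streamline delimiters up to the Inf-triple terminator. Coordinates are
#' returned as stored (world-space mm).
#'
#' @param path path to a `.tck` file.
#' @return a \linkS4class{Tractogram}.
#' @seealso [writeTck()]
#' @export
readTck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ## header is ASCII terminated by an END line; locate it byte-wise (the
  ## binary section that follows is not valid text)
  n <- min(length(raw), 65536L)
  if (n < 19L)
    stop("not a tck file: missing 'mrtrix tracks' magic line")
  endPat <- which(raw[seq_len(n - 4L)] == as.raw(0x0a) &
                  raw[seq_len(n - 4L) + 1L] == as.raw(0x45) &
                  raw[seq_len(n - 4L) + 2L] == as.raw(0x4e) &
                  raw[seq_len(n - 4L) + 3L] == as.raw(0x44) &
                  raw[seq_len(n - 4L) + 4L] == as.raw(0x0a))
  if (!length(endPat)) {
    if (!identical(rawToChar(raw[1:13]), "mrtrix tracks"))
      stop("not a tck file: missing 'mrtrix tracks' magic line")
    stop("tck header not terminated by END")
  }
  txt <- rawToChar(raw[seq_len(endPat[1] + 4L)])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L || trimws(lines[1]) != "mrtrix tracks")
    stop("not a tck file: missing 'mrtrix tracks' magic line")
  endAt <- length(lines)  # the END line located above
  kv <- list()
  for (ln in if (endAt > 2L) lines[2:(endAt - 1L)] else character(0)) {
    m <- regmatches(ln, regexec("^([^:]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) == 3L)
      kv[[trimws(m[2])]] <- trimws(m[3])
  }
  datatype <- kv[["datatype"]]
  if (is.null(datatype))
    stop("tck header missing datatype")
  endian <- switch(datatype,
                   "Float32LE" = "little",
                   "Float32BE" = "big",
                   stop("unsupported tck datatype: ", datatype))
  fileField <- kv[["file"]]
  if (is.null(fileField))
    stop("tck header missing 'file' field")
  offset <- as.integer(sub("^\\.[[:space:]]+", "", fileField))
  if (is.na(offset) || offset > length(raw))
    stop("invalid tck binary offset")
  nbytes <- length(raw) - offset
  if (nbytes %% 12L != 0L)
    stop("truncated tck binary section (not a whole number of triplets)")
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  n = nbytes %/% 4L, size = 4L, endian = endian)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  isNaNrow <- is.nan(m[, 1]) & is.nan(m[, 2]) & is.nan(m[, 3])
  isInfrow <- is.infinite(m[, 1]) & is.infinite(m[, 2]) & is.infinite(m[, 3])
  term <- which(isInfrow)
  if (length(term) == 0L)
    stop("truncated tck file: missing Inf-triple terminator")
  term <- term[1]
  sl <- list()
  start <- 1L
  for (d in which(isNaNrow[seq_len(term - 1L)])) {
    if (d > start)
      sl[[length(sl) + 1L]] <- m[start:(d - 1L), , drop = FALSE]
    start <- d + 1L
  }
  if (start < term)  # final streamline not NaN-delimited before terminator
    sl[[length(sl) + 1L]] <- m[start:(term - 1L), , drop = FALSE]
  if (!is.null(kv[["count"]])) {
    declared <- suppressWarnings(as.integer(kv[["count"]]))
    if (!is.na(declared) && declared != length(sl))
      warning(sprintf("tck header declares %d streamlines, found %d",
                      declared, length(sl)))
  }
  Tractogram(sl)
}

#' Write an MRtrix track file
#'
#' Emits the little-endian Float32 dialect: text header with the
#' `mrtrix tracks` magic line, `datatype: Float32LE`, `count`, and
#' `file: . <offset>`, followed by the binary triplet stream with NaN-triple
#' streamline delimiters and an Inf-triple terminator. Reading the file back
#' reproduces the coordinates bit-identically at 32-bit float precision.
#'
#' @param tractogram a \linkS4class{Tractogram} (or \linkS4class{Tract}).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTck <- function(tractogram, path) {
  sl <- streamlines(tractogram)
  for (p in sl)
    if (!all(is.finite(p)))
      stop("non-finite coordinates cannot be written: ",
           "NaN/Inf are reserved tck delimiters")
  fixed <- paste0("mrtrix tracks\n",
                  "datatype: Float32LE\n",
                  sprintf("count: %d\n", length(sl)))
  ## the offset names a byte position in a header that contains the offset
  ## itself; iterate until the digit count stabilizes
  offset <- nchar(fixed) + nchar("file: . \nEND\n")
  repeat {
    candidate <- nchar(fixed) +
      nchar(sprintf("file: . %d\nEND\n", offset))
    if (candidate == offset) break
    offset <- candidate
  }
  header <- paste0(fixed, sprintf("file: . %d\nEND\n", offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  nan3 <- rep(NaN, 3)
  for (p in sl)
    writeBin(c(as.numeric(t(p)), nan3), con, size = 4L, endian = "little")
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}
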