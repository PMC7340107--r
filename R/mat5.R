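# Minimal MAT v5 (Level 5 MAT-file) codec.
#
# Scope: what ground-truthed single-channel benchmark containers actually
# use — named numeric arrays (any integer/float storage type, read back as
# double), character arrays, one level of cell nesting, and zlib-compressed
# elements on read. The writer emits uncompressed double matrices only.
# Sparse, struct and object classes are out of scope.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L

MX_CELL <- 1L; MX_CHAR <- 4L
MX_NUMERIC <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L)

mi_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
         "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L, "16" = 1L,
         stop("unsupported MAT data type: ", type))
}

mi_read_values <- function(raw, type, nbytes) {
  n <- nbytes %/% mi_size(type)
  if (n == 0L) return(numeric(0))
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
         "1" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE, endian = "little")),
         "2" = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE, endian = "little")),
         "3" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")),
         "4" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little")),
         "5" = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
         "6" = { # uint32: readBin has no unsigned 4-byte; reconstruct
           v <- readBin(con, "integer", n, size = 4L, endian = "little")
           ifelse(v < 0, v + 2^32, as.numeric(v))
         },
         "7" = as.numeric(readBin(con, "double", n, size = 4L, endian = "little")),
         "9" = readBin(con, "double", n, size = 8L, endian = "little"),
         "12" = , "13" = { # (u)int64 via 32-bit halves; exact below 2^53
           w <- readBin(con, "integer", 2L * n, size = 4L, endian = "little")
           lo <- w[seq(1L, 2L * n, 2L)]
           hi <- w[seq(2L, 2L * n, 2L)]
           ifelse(lo < 0, lo + 2^32, as.numeric(lo)) + as.numeric(hi) * 2^32
         },
         "16" = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE, endian = "little")),
         stop("unsupported MAT numeric storage type: ", type))
}

# Reads one sub/element tag at position pos (1-based). Returns list
# (type, nbytes, data_start, next_pos) honouring the small-element format.
mat5_tag <- function(bytes, pos) {
  word1 <- readBin(bytes[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  if (word1 < 0) word1 <- word1 + 2^32
  small_n <- word1 %/% 65536
  if (small_n > 0) {
    list(type = as.integer(word1 %% 65536), nbytes = as.integer(small_n),
         data_start = pos + 4L, next_pos = pos + 8L)
  } else {
    nb <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L, endian = "little")
    if (nb < 0) nb <- nb + 2^32
    padded <- 8L * ((as.integer(nb) + 7L) %/% 8L)
    list(type = as.integer(word1), nbytes = as.integer(nb),
         data_start = pos + 8L, next_pos = pos + 8L + padded)
  }
}

mat5_parse_matrix <- function(bytes, pos, end) {
  # array flags
  tg <- mat5_tag(bytes, pos)
  flags <- readBin(bytes[tg$data_start:(tg$data_start + 3L)], "integer", 1L,
                   size = 4L, endian = "little")
  cls <- as.integer(flags %% 256)
  pos <- tg$next_pos
  # dimensions
  tg <- mat5_tag(bytes, pos)
  dims <- mi_read_values(bytes[tg$data_start:(tg$data_start + tg$nbytes - 1L)],
                         tg$type, tg$nbytes)
  pos <- tg$next_pos
  # name
  tg <- mat5_tag(bytes, pos)
  nm <- if (tg$nbytes > 0)
    rawToChar(bytes[tg$data_start:(tg$data_start + tg$nbytes - 1L)]) else ""
  pos <- tg$next_pos

  if (cls %in% MX_NUMERIC) {
    tg <- mat5_tag(bytes, pos)
    vals <- if (tg$nbytes > 0)
      mi_read_values(bytes[tg$data_start:(tg$data_start + tg$nbytes - 1L)],
                     tg$type, tg$nbytes) else numeric(0)
    value <- if (length(dims) == 2L) {
      matrix(vals, nrow = dims[1], ncol = dims[2])
    } else {
      array(vals, dim = dims)
    }
  } else if (cls == MX_CHAR) {
    tg <- mat5_tag(bytes, pos)
    codes <- mi_read_values(bytes[tg$data_start:(tg$data_start + tg$nbytes - 1L)],
                            tg$type, tg$nbytes)
    value <- intToUtf8(as.integer(codes[codes > 0]))
  } else if (cls == MX_CELL) {
    n_el <- prod(dims)
    value <- vector("list", n_el)
    for (i in seq_len(n_el)) {
      tg <- mat5_tag(bytes, pos)
      el <- mat5_parse_matrix(bytes, tg$data_start, tg$next_pos)
      value[[i]] <- el$value
      pos <- tg$next_pos
    }
  } else {
    value <- NULL # unsupported class; name still reported
  }
  list(name = nm, value = value)
}

#' Read a MAT v5 container
#'
#' Parses a Level 5 MAT-file into a named list. Numeric arrays are returned
#' as double matrices/arrays, character arrays as strings, and cell arrays
#' as lists. Compressed elements are inflated transparently.
#'
#' @param path path to a `.mat` file.
#' @return named list of the variables stored in the file.
#' @export
read_mat5 <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 128L)
    stop("not a MAT v5 file (shorter than the 128-byte header): ", path)
  endian <- rawToChar(bytes[127:128])
  if (!endian %in% c("IM", "MI"))
    stop("not a MAT v5 file (bad endian indicator): ", path)
  if (endian == "MI")
    stop("big-endian MAT files are not supported")
  out <- list()
  pos <- 129L
  n_total <- length(bytes)
  while (pos + 7L <= n_total) {
    tg <- mat5_tag(bytes, pos)
    if (tg$type == MI_COMPRESSED) {
      payload <- bytes[tg$data_start:(tg$data_start + tg$nbytes - 1L)]
      inflated <- memDecompress(payload, type = "gzip")
      sub <- mat5_tag(inflated, 1L)
      if (sub$type == MI_MATRIX) {
        el <- mat5_parse_matrix(inflated, sub$data_start, sub$next_pos)
        out[[el$name]] <- el$value
      }
    } else if (tg$type == MI_MATRIX) {
      el <- mat5_parse_matrix(bytes, tg$data_start, tg$next_pos)
      out[[el$name]] <- el$value
    }
    pos <- tg$next_pos
  }
  out
}

mat5_pad <- function(raw) {
  pad <- (8L - length(raw) %% 8L) %% 8L
  c(raw, raw(pad))
}

mat5_element <- function(type, payload) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(length(payload), raw(), size = 4L, endian = "little"),
    mat5_pad(payload))
}

mat5_encode_matrix <- function(name, value) {
  value <- as.matrix(value)
  flags <- mat5_element(MI_UINT32,
                        writeBin(c(6L, 0L), raw(), size = 4L, endian = "little"))
  dims <- mat5_element(MI_INT32,
                       writeBin(as.integer(dim(value)), raw(), size = 4L,
                                endian = "little"))
  nm <- mat5_element(MI_INT8, charToRaw(name))
  dat <- mat5_element(MI_DOUBLE,
                      writeBin(as.numeric(value), raw(), size = 8L,
                               endian = "little"))
  body <- c(flags, dims, nm, dat)
  c(writeBin(MI_MATRIX, raw(), size = 4L, endian = "little"),
    writeBin(length(body), raw(), size = 4L, endian = "little"),
    body)
}

#' Write a MAT v5 container
#'
#' Writes a named list of numeric vectors/matrices as uncompressed double
#' arrays. Vectors are stored as 1 x n row vectors, the usual orientation
#' in the benchmark containers this package consumes.
#'
#' @param vars named list of numeric vectors or matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by spikebench"))
  header <- c(header, raw(116L - length(header)))
  header <- c(header, raw(8L)) # subsystem offset
  header <- c(header, writeBin(c(0x00L, 0x01L), raw(), size = 1L)) # version 0x0100
  header <- c(header, charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) stop("only numeric variables can be written: ", nm)
    if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
    body <- c(body, mat5_encode_matrix(nm, v))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}
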