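# Minimal FCS 3.0 / 3.1 reader and writer.
#
# Only list-mode ($MODE L) files with a uniform bit width per parameter and
# linear amplification ($PnE 0,0) are supported -- which covers files
# exported by modern plate cytometers.  The time channel (named "Time",
# case-insensitive) is scaled by $TIMESTEP into seconds on read.

FCS_DELIM <- "/"

#' Read an FCS 3.0/3.1 file into an event table
#'
#' @param path path to an FCS file.
#' @return an [event_table()]; if the file contains a time channel its values
#'   multiplied by `$TIMESTEP` populate the `time` field (seconds).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("not an FCS 3.0/3.1 file (header version '%s')", version)
  off <- suppressWarnings(as.numeric(vapply(0:5, function(i)
    substr(header, 11L + 8L * i, 18L + 8L * i), character(1))))
  if (anyNA(off[1:2]))
    stopf("malformed FCS header: unreadable TEXT segment offsets")
  text_begin <- off[1]; text_end <- off[2]
  seek(con, text_begin)
  raw_text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(raw_text, 1L, 1L)
  parts <- strsplit(substring(raw_text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  kw <- as.list(parts[seq(2L, length(parts), by = 2L)])
  names(kw) <- trimws(parts[seq(1L, length(parts), by = 2L)])

  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stopf("FCS file missing required keyword %s", key)
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  datatype <- toupper(need("$DATATYPE"))
  mode <- toupper(need("$MODE"))
  byteord <- need("$BYTEORD")
  if (mode != "L") stopf("unsupported $MODE '%s' (only list mode)", mode)
  if (!datatype %in% c("F", "D"))
    stopf("unsupported $DATATYPE '%s' (only F or D)", datatype)
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stopf("unsupported $BYTEORD '%s'", byteord)
  ch_names <- vapply(seq_len(n_par),
                     function(i) need(sprintf("$P%dN", i)), character(1))
  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(need(sprintf("$P%dB", i))), integer(1))
  expect_bits <- if (datatype == "F") 32L else 64L
  if (any(bits != expect_bits))
    stopf("$PnB = %s inconsistent with $DATATYPE %s",
          paste(unique(bits), collapse = "/"), datatype)

  data_begin <- off[3]; data_end <- off[4]
  if (is.na(data_begin) || data_begin == 0) {
    data_begin <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  seek(con, data_begin)
  size <- expect_bits %/% 8L
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = size,
                  endian = endian)
  if (length(vals) < n_par * n_tot)
    stopf("FCS data segment truncated: expected %d values, read %d",
          n_par * n_tot, length(vals))
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE,
                dimnames = list(NULL, ch_names))
  time <- NULL
  ti <- which(tolower(ch_names) == "time")
  if (length(ti) == 1L) {
    timestep <- as.numeric(kw[["$TIMESTEP"]] %||% "1")
    time <- mat[, ti] * timestep
  }
  event_table(mat, time = time, source = path)
}

#' Write an event table to an FCS 3.1 file
#'
#' Events are stored as little-endian doubles (`$DATATYPE D`) so that a
#' write/read round trip preserves values exactly. If the table carries a
#' `time` field and no `Time` channel, a `Time` channel is appended using the
#' given `$TIMESTEP`.
#'
#' @param table an [event_table()].
#' @param path output path.
#' @param timestep seconds per time-channel unit (`$TIMESTEP`), used only
#'   when a `Time` channel is created from `table$time`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path, timestep = 0.01) {
  stopifnot(inherits(table, "event_table"))
  mat <- table$exprs
  has_time_col <- any(tolower(colnames(mat)) == "time")
  if (!is.null(table$time) && !has_time_col) {
    mat <- cbind(mat, Time = table$time / timestep)
  } else if (has_time_col) {
    timestep <- 1
  }
  n_par <- ncol(mat); n_tot <- nrow(mat)
  d <- FCS_DELIM
  pair <- function(k, v) paste0(k, d, v, d)
  kw <- paste0(
    pair("$BEGINANALYSIS", "0"), pair("$ENDANALYSIS", "0"),
    pair("$BEGINSTEXT", "0"), pair("$ENDSTEXT", "0"),
    pair("$BEGINDATA", "%012d"), pair("$ENDDATA", "%012d"),
    pair("$BYTEORD", "1,2,3,4"), pair("$DATATYPE", "D"),
    pair("$MODE", "L"), pair("$NEXTDATA", "0"),
    pair("$PAR", n_par), pair("$TOT", n_tot),
    pair("$TIMESTEP", format(timestep, scientific = FALSE)))
  for (i in seq_len(n_par)) {
    rng <- max(1, ceiling(max(mat[, i], na.rm = TRUE)))
    kw <- paste0(kw, pair(sprintf("$P%dN", i), colnames(mat)[i]),
                 pair(sprintf("$P%dB", i), "64"),
                 pair(sprintf("$P%dE", i), "0,0"),
                 pair(sprintf("$P%dR", i), format(rng, scientific = FALSE)))
  }
  text_begin <- 58L
  # offsets are zero-padded to 12 chars so the TEXT length is known up front
  text_len <- 1L + nchar(kw, type = "bytes") + 2L * (12L - nchar("%012d"))
  text_end <- text_begin + text_len - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 8L * n_par * n_tot - 1L
  kw <- sprintf(kw, data_begin, data_end)
  stopifnot(nchar(kw, type = "bytes") + 1L == text_len)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0L,
                    if (data_end <= 99999999) data_end else 0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(paste0(d, kw), con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(mat)), con, size = 8L, endian = "little")
  invisible(path)
}
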