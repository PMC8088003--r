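# Crash-safe append-only checkpoint log.
#
# Wire format, per record: 4-byte little-endian payload length, the
# serialized record payload, then a 4-byte little-endian Adler-32 checksum
# of the payload.  Appending is a single buffered write followed by a
# flush, so a crash can only truncate the final record; readers keep every
# record whose frame is complete and whose checksum validates.

#' Adler-32 checksum
#'
#' The standard Adler-32 rolling checksum (two 16-bit sums modulo 65521,
#' initial value 1), implemented in vectorized chunks.  Any single-byte
#' change in the input changes the checksum, which is what the checkpoint
#' log relies on to detect torn writes.
#'
#' @param data A raw vector, or a character scalar (taken as its bytes).
#' @return The checksum as a double (value of an unsigned 32-bit integer).
#' @export
adler32 <- function(data) {
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  if (!is.raw(data)) stop("data must be raw or character", call. = FALSE)
  MOD <- 65521
  a <- 1; b <- 0
  n <- length(data)
  i <- 1L
  chunk <- 262144L   # keeps the running sums exactly representable
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    x <- as.numeric(data[i:j])
    ca <- cumsum(x)
    b <- (b + (j - i + 1) * a + sum(ca)) %% MOD
    a <- (a + ca[length(ca)]) %% MOD
    i <- j + 1L
  }
  b * 65536 + a
}

.u32_raw <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.raw_u32 <- function(r) {
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))
}

#' Append one record to a checkpoint log
#'
#' Serializes the record, frames it with its length and Adler-32 checksum,
#' and appends it to \code{path} in one write.
#'
#' @param path Log file path (created if absent).
#' @param record Any serializable R object; the search drivers store lists
#'   with \code{edge}, \code{beta}, \code{ll}, \code{params} and
#'   \code{iterations}.
#' @return \code{path}, invisibly.
#' @export
checkpoint_append <- function(path, record) {
  payload <- serialize(record, NULL)
  frame <- c(.u32_raw(length(payload)), payload, .u32_raw(adler32(payload)))
  con <- file(path, "ab")
  on.exit(close(con))
  writeBin(frame, con)
  flush(con)
  invisible(path)
}

#' Read all complete, valid records from a checkpoint log
#'
#' Records are returned in append order.  A truncated final frame (torn
#' write) or a record whose checksum does not validate is counted in
#' \code{n_bad} and excluded; reading stops at the first bad frame since
#' everything after it is unreliable.
#'
#' @param path Log file path; a missing file reads as empty.
#' @return List with \code{records} (list of deserialized records) and
#'   \code{n_bad} (0 or 1).
#' @export
checkpoint_read <- function(path) {
  if (!file.exists(path)) return(list(records = list(), n_bad = 0L))
  bytes <- readBin(path, "raw", n = file.size(path))
  records <- list()
  n_bad <- 0L
  i <- 1L
  n <- length(bytes)
  while (i + 3L <= n) {
    len <- .raw_u32(bytes[i:(i + 3L)])
    if (len < 1 || i + 3L + len + 4L > n) { n_bad <- 1L; break }
    payload <- bytes[(i + 4L):(i + 3L + len)]
    chk <- .raw_u32(bytes[(i + 4L + len):(i + 7L + len)])
    if (chk != adler32(payload)) { n_bad <- 1L; break }
    rec <- tryCatch(unserialize(payload), error = function(e) NULL)
    if (is.null(rec)) { n_bad <- 1L; break }
    records[[length(records) + 1L]] <- rec
    i <- i + 8L + len
  }
  if (i <= n && n_bad == 0L && i + 3L > n) n_bad <- 1L  # trailing partial length
  list(records = records, n_bad = n_bad)
}

#' Determine the remaining work units after a restart
#'
#' Compares the units recorded as complete in the checkpoint log against
#' the full unit list (edge ids in exhaustive mode).  Units whose record is
#' missing, truncated, or checksum-corrupt are rescheduled.
#'
#' @param path Log file path (possibly absent or empty).
#' @param all_units Integer vector of all work-unit ids.
#' @return List with \code{remaining} (unit ids still to run) and
#'   \code{records} (valid completed records for units in \code{all_units}).
#' @export
checkpoint_resume <- function(path, all_units) {
  res <- checkpoint_read(path)
  if (!length(res$records))
    return(list(remaining = all_units, records = list()))
  ids <- vapply(res$records, function(r) as.numeric(r$edge), numeric(1))
  keep <- ids %in% all_units & !duplicated(ids)
  list(remaining = setdiff(all_units, ids[keep]),
       records = res$records[keep])
}
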