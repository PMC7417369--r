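# Minimal, standards-conforming FCS 3.1 I/O: list-mode, $DATATYPE=F (read
# also accepts D), little- or big-endian $BYTEORD, single data set.

#' Write an FCS 3.1 file
#'
#' Writes an [event_matrix()] as a list-mode FCS 3.1 file with
#' `$DATATYPE=F` (32-bit float), little-endian byte order, marker names in
#' `$PnS`, and an optional `$SPILLOVER` keyword.
#'
#' @param events an [event_matrix()] (any scale state; values are stored
#'   as-is).
#' @param path output file path.
#' @param spillover optional [spillover_matrix()] stored as `$SPILLOVER`.
#' @param extra_keywords named character vector of additional TEXT keywords.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, spillover = NULL, extra_keywords = NULL) {
  v <- events$values
  n <- nrow(v); p <- ncol(v)
  delim <- "/"

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (j in seq_len(p)) {
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dN", j)] <- events$channel_names[j]
    kw[sprintf("$P%dR", j)] <- format(max(262144, ceiling(max(abs(v[, j]), 1))),
                                      scientific = FALSE)
    if (!identical(events$marker_names[j], events$channel_names[j])) {
      kw[sprintf("$P%dS", j)] <- events$marker_names[j]
    }
  }
  if (!is.null(spillover)) {
    chs <- rownames(spillover)
    kw["$SPILLOVER"] <- paste(
      c(length(chs), chs, format(as.vector(t(unclass(spillover))), digits = 12)),
      collapse = ","
    )
  }
  if (!is.null(extra_keywords)) kw[names(extra_keywords)] <- extra_keywords

  header_len <- 58L  # "FCS3.1    " + 6 fields of 8 chars
  data_len <- 4L * n * p

  # $BEGINDATA/$ENDDATA live inside TEXT, whose length depends on them:
  # iterate until the offsets stabilise.
  text_of <- function(begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(begin_data),
             "$ENDDATA" = as.character(end_data))
    kw2 <- kw2[order(names(kw2))]
    paste0(delim, paste0(names(kw2), delim, unname(kw2), delim, collapse = ""))
  }
  begin_data <- header_len + nchar(text_of(0, 0)) + 1L
  for (it in 1:5) {
    txt <- text_of(begin_data, begin_data + data_len - 1L)
    bd <- header_len + nchar(txt)
    if (bd == begin_data) break
    begin_data <- bd
  }
  txt <- text_of(begin_data, begin_data + data_len - 1L)
  text_start <- header_len
  text_end <- header_len + nchar(txt) - 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  off <- function(x) formatC(x, width = 8, flag = " ")
  writeChar(paste0(off(text_start), off(text_end),
                   off(begin_data), off(begin_data + data_len - 1L),
                   off(0), off(0)), con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(v)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the TEXT segment and the list-mode DATA segment
#' (`$DATATYPE` F or D). Marker names are taken from `$PnS`, falling back to
#' `$PnN`. The event count is validated against `$TOT`.
#'
#' @param path path to an FCS file.
#' @return a list with elements `events` (a raw-scale [event_matrix()]),
#'   `spillover` (a [spillover_matrix()] or `NULL`) and `keywords` (named
#'   character vector of the full TEXT segment).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stopf("read_fcs: no such file: %s", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 10)
  if (!grepl("^FCS3\\.[01]", magic)) {
    stopf("read_fcs: not an FCS 3.0/3.1 file (version segment '%s')", magic)
  }
  offs <- suppressWarnings(as.numeric(trimws(
    vapply(1:6, function(i) readChar(con, 8), character(1))
  )))
  if (any(is.na(offs[1:2]))) stopf("read_fcs: malformed header offsets")
  text_start <- offs[1]; text_end <- offs[2]

  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))

  need <- function(k) {
    if (is.na(kw[k]) || !nzchar(kw[k] %||% "")) {
      stopf("read_fcs: required keyword %s missing", k)
    }
    unname(kw[k])
  }
  if (!"$TOT" %in% names(kw)) stopf("read_fcs: required keyword $TOT missing")
  if (!"$PAR" %in% names(kw)) stopf("read_fcs: required keyword $PAR missing")
  n <- as.integer(need("$TOT"))
  p <- as.integer(need("$PAR"))
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D")) stopf("read_fcs: unsupported $DATATYPE '%s'", dtype)
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  word <- if (dtype == "F") 4L else 8L

  data_start <- offs[3]
  data_end <- offs[4]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  expected <- as.numeric(n) * p * word
  avail <- min(data_end, sz - 1) - data_start + 1
  if (avail < expected) {
    stopf("read_fcs: data segment truncated: need %.0f bytes for $TOT=%d, have %.0f",
          expected, n, avail)
  }
  seek(con, data_start)
  raw_vals <- readBin(con, "numeric", n = n * p, size = word, endian = endian)
  if (length(raw_vals) < n * p) stopf("read_fcs: data segment truncated")
  v <- matrix(raw_vals, nrow = n, ncol = p, byrow = TRUE)

  chn <- vapply(seq_len(p), function(j) unname(need(sprintf("$P%dN", j))),
                character(1))
  mkn <- vapply(seq_len(p), function(j) {
    s <- kw[sprintf("$P%dS", j)]
    if (is.na(s) || !nzchar(s)) chn[j] else unname(s)
  }, character(1))

  spill <- NULL
  sp_key <- intersect(c("$SPILLOVER", "SPILL", "$COMP"), names(kw))
  if (length(sp_key)) {
    spill <- parse_spillover_keyword(kw[[sp_key[1]]])
  }
  list(events = event_matrix(v, chn, mkn, "raw"), spillover = spill,
       keywords = kw)
}

#' @noRd
parse_spillover_keyword <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  chs <- parts[2:(k + 1)]
  vals <- as.numeric(parts[(k + 2):(k + 1 + k * k)])
  S <- matrix(vals, nrow = k, ncol = k, byrow = TRUE,
              dimnames = list(chs, chs))
  spillover_matrix(S)
}
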