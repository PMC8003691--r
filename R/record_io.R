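#' Paired waveform record container
#'
#' A `bp_record` bundles the two synchronized channels (ABP in mmHg, PPG in
#' arbitrary units) sampled at a common rate with subject linkage and
#' demographics.
#'
#' @param record_id,subject_id identifiers.
#' @param fs sampling rate in Hz (125 for protocol-equivalent processing).
#' @param abp,ppg numeric series of equal length.
#' @param age,gender subject demographics (`NA` allowed; eligibility
#'   screening then drops the record).
#' @param start_offset seconds between the original recording start and
#'   this record's first sample.
#' @return A `bp_record` object.
#' @export
bp_record <- function(record_id, subject_id, fs, abp, ppg,
                      age = NA_real_, gender = NA_character_,
                      start_offset = 0) {
  stopifnot(length(abp) == length(ppg))
  structure(
    list(record_id = record_id, subject_id = subject_id, fs = fs,
         abp = as.numeric(abp), ppg = as.numeric(ppg),
         age = age, gender = gender, start_offset = start_offset),
    class = "bp_record"
  )
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record %s> subject %s, %.1f s @ %g Hz, age %s, %s\n",
              x$record_id, x$subject_id, length(x$abp) / x$fs, x$fs,
              ifelse(is.na(x$age), "?", format(round(x$age, 1))),
              ifelse(is.na(x$gender), "?", x$gender)))
  invisible(x)
}

#' Duration of a record in seconds
#' @param record a `bp_record`.
#' @return Numeric seconds.
#' @export
record_duration <- function(record) length(record$abp) / record$fs

#' @export
as.data.frame.bp_record <- function(x, ...) {
  data.frame(time = (seq_along(x$abp) - 1) / x$fs, abp = x$abp, ppg = x$ppg)
}

#' Write / read a record as plain two-column text
#'
#' The text format holds one `abp ppg` pair per line; metadata travels in a
#' small `#`-prefixed header so the file round-trips.
#'
#' @param record a `bp_record`.
#' @param path file path.
#' @return `write_record_text` returns `path` invisibly; `read_record_text`
#'   returns the `bp_record`.
#' @export
write_record_text <- function(record, path) {
  hdr <- sprintf("# %s %s %g %s %s %g", record$record_id, record$subject_id,
                 record$fs, format(record$age), record$gender,
                 record$start_offset)
  writeLines(c(hdr, paste(format(record$abp, digits = 10),
                          format(record$ppg, digits = 10))), path)
  invisible(path)
}

#' @rdname write_record_text
#' @param path file path.
#' @export
read_record_text <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  m <- utils::read.table(text = lines[-1])
  bp_record(meta[1], meta[2], as.numeric(meta[3]), m[[1]], m[[2]],
            age = suppressWarnings(as.numeric(meta[4])), gender = meta[5],
            start_offset = as.numeric(meta[6]))
}

#' Write / read a record in a WFDB-style layout
#'
#' A header file (`<record>.hea`: record name, signal count, sampling rate,
#' sample count, then one line per signal with file name, units and
#' description) plus a signal data file, mirroring the classic waveform
#' -database convention with a plain-text sample file.
#'
#' @param record a `bp_record`.
#' @param dir directory for the pair of files.
#' @return `write_record_wfdb` returns the header path invisibly;
#'   `read_record_wfdb` takes the header path and returns the `bp_record`.
#' @export
write_record_wfdb <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- file.path(dir, paste0(record$record_id, ".dat.txt"))
  hea <- file.path(dir, paste0(record$record_id, ".hea"))
  writeLines(paste(format(record$abp, digits = 10),
                   format(record$ppg, digits = 10)), dat)
  writeLines(c(
    sprintf("%s 2 %g %d", record$record_id, record$fs, length(record$abp)),
    sprintf("%s mmHg ABP", basename(dat)),
    sprintf("%s NU PLETH", basename(dat)),
    sprintf("# subject %s age %s gender %s offset %g", record$subject_id,
            format(record$age), record$gender, record$start_offset)
  ), hea)
  invisible(hea)
}

#' @rdname write_record_wfdb
#' @param header_path path to the `.hea` header file.
#' @export
read_record_wfdb <- function(header_path) {
  lines <- readLines(header_path)
  top <- strsplit(lines[1], " ")[[1]]
  sig <- strsplit(lines[2], " ")[[1]]
  meta <- strsplit(sub("^# ", "", lines[4]), " ")[[1]]
  m <- utils::read.table(file.path(dirname(header_path), sig[1]))
  bp_record(top[1], meta[2], as.numeric(top[3]), m[[1]], m[[2]],
            age = suppressWarnings(as.numeric(meta[4])), gender = meta[6],
            start_offset = as.numeric(meta[8]))
}

#' Screen records for protocol eligibility
#'
#' Keeps records at least 15 minutes long that carry both channels and a
#' subject age inside the 18-89 year analysis range. Records with missing
#' channel or demographic metadata are skipped with a warning.
#'
#' @param records list of `bp_record` objects.
#' @param min_duration minimum duration in seconds (default 900 = 15 min).
#' @param age_range inclusive age bounds in years.
#' @return Tibble of eligible records: `record_id`, `subject_id`,
#'   `duration`, `age`, `gender`, plus a list-column `record`.
#' @export
scan_eligible <- function(records, min_duration = 900, age_range = c(18, 89)) {
  keep <- purrr::map(records, function(r) {
    if (!inherits(r, "bp_record") || is.null(r$abp) || is.null(r$ppg) ||
        !length(r$abp) || !length(r$ppg)) {
      warning("record skipped: missing channel data")
      return(NULL)
    }
    if (is.na(r$age) || is.na(r$gender)) {
      warning("record ", r$record_id, " skipped: missing demographics")
      return(NULL)
    }
    dur <- record_duration(r)
    if (dur < min_duration) return(NULL)
    if (r$age < age_range[1] || r$age > age_range[2]) return(NULL)
    tibble::tibble(record_id = r$record_id, subject_id = r$subject_id,
                   duration = dur, age = r$age, gender = r$gender,
                   record = list(r))
  })
  dplyr::bind_rows(keep)
}

#' Propose a pair of 15-s segments 5 minutes apart
#'
#' Returns two half-open 15-s windows (exactly `15 * fs` samples each)
#' whose starts are 300 s apart, the first beginning at `cursor` seconds.
#'
#' @param record a `bp_record`.
#' @param cursor start of the first window, seconds from record start.
#' @param seg_len segment length in seconds.
#' @param gap start-to-start separation in seconds.
#' @return A `segment_pair` (list with `seg_a`, `seg_b` -- each a list of
#'   `abp`, `ppg`, `start` -- plus `gap`, `record_id`), or `NULL` when the
#'   record is exhausted at this cursor.
#' @export
propose_segment_pair <- function(record, cursor, seg_len = 15, gap = 300) {
  fs <- record$fs
  n <- length(record$abp)
  ends <- (cursor + gap + seg_len) * fs
  if (ends > n) return(NULL)
  grab <- function(start_s) {
    i0 <- round(start_s * fs) + 1L
    idx <- i0:(i0 + seg_len * fs - 1L)
    list(abp = record$abp[idx], ppg = record$ppg[idx], start = start_s)
  }
  structure(
    list(seg_a = grab(cursor), seg_b = grab(cursor + gap), gap = gap,
         record_id = record$record_id, cursor = cursor),
    class = "segment_pair"
  )
}

#' Segment acceptance loop
#'
#' Implements the retry protocol: the first proposal starts after the
#' 10-minute rest interval; each rejection advances the cursor by one
#' minute; the record is excluded when no further pair fits.
#'
#' @param record a `bp_record`.
#' @param quality_fn function taking a `segment_pair` and returning `TRUE`
#'   (accept) or `FALSE`, or a list with element `accepted`.
#' @param rest rest interval before the first proposal, seconds.
#' @param retry_step cursor advance after a rejection, seconds.
#' @param seg_len,gap forwarded to [propose_segment_pair()].
#' @return list with `accepted` (logical), `pair` (the accepted
#'   `segment_pair` or `NULL`), `attempts`, and `detail` (last value
#'   returned by `quality_fn`).
#' @export
acceptance_loop <- function(record, quality_fn, rest = 600, retry_step = 60,
                            seg_len = 15, gap = 300) {
  cursor <- rest
  attempts <- 0L
  detail <- NULL
  repeat {
    pair <- propose_segment_pair(record, cursor, seg_len = seg_len, gap = gap)
    if (is.null(pair)) {
      return(list(accepted = FALSE, pair = NULL, attempts = attempts,
                  detail = detail))
    }
    attempts <- attempts + 1L
    verdict <- quality_fn(pair)
    ok <- if (is.list(verdict)) isTRUE(verdict$accepted) else isTRUE(verdict)
    detail <- verdict
    if (ok) {
      return(list(accepted = TRUE, pair = pair, attempts = attempts,
                  detail = detail))
    }
    cursor <- cursor + retry_step
  }
}

#' Read a demographics table and attach it to records
#'
#' The table is delimited text with columns `subject_id`, `age`, `gender`.
#'
#' @param path file path to the delimited table.
#' @return `read_demographics` returns a tibble.
#' @export
read_demographics <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' @rdname read_demographics
#' @param records list of `bp_record` objects (possibly without
#'   demographics).
#' @param demographics tibble with `subject_id`, `age`, `gender`.
#' @return `attach_demographics` returns the records with `age`/`gender`
#'   filled in from the table by subject id.
#' @export
attach_demographics <- function(records, demographics) {
  purrr::map(records, function(r) {
    row <- demographics[demographics$subject_id == r$subject_id, ]
    if (nrow(row) == 1L) {
      r$age <- row$age[1]
      r$gender <- row$gender[1]
    }
    r
  })
}

#' Save / load the hierarchical processing container
#'
#' One container per record holds the raw accepted segments, the per-pulse
#' arrays, the computed average morphologies and metadata as a nested
#' structure, serialized to a single file.
#'
#' @param container nested list (e.g. the output of [process_record()]).
#' @param path file path.
#' @return `save_container` returns `path` invisibly; `load_container`
#'   returns the nested list.
#' @export
save_container <- function(container, path) {
  saveRDS(container, path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)
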