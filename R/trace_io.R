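#' Read a time-domain trace from CSV
#'
#' The on-disk dialect is a two-column CSV `time_ps,amplitude` with optional
#' `#key=value` metadata header lines (UTF-8, '.' decimal separator).
#' Recognised metadata keys are `label`, `n_scans`, `thickness_mm`,
#' `temperature_K` and `sample_id`; `thickness_mm` (with the latter two)
#' populates an [acquisition_meta()] record attached to the trace.
#'
#' @param path path to an existing CSV file.
#' @param sep field separator (default ",").
#' @return A [td_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta_kv <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no data rows in ", path, call. = FALSE)
  # optional column-name header
  first <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first[1:2]))))) body <- body[-1]
  df <- utils::read.table(text = body, sep = sep, header = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two numeric columns in ", path, call. = FALSE)
  tvals <- suppressWarnings(as.numeric(df[[1]]))
  avals <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(tvals) | is.na(avals))
  if (length(bad)) {
    stop(sprintf("non-numeric value in %s at data row %d", path, bad[1]),
         call. = FALSE)
  }
  meta <- NULL
  if (!is.null(meta_kv$thickness_mm)) {
    meta <- acquisition_meta(
      thickness_mm = as.numeric(meta_kv$thickness_mm),
      temperature_K = if (is.null(meta_kv$temperature_K)) 294
                      else as.numeric(meta_kv$temperature_K),
      sample_id = if (is.null(meta_kv$sample_id)) "" else meta_kv$sample_id
    )
  }
  td_trace(tvals, avals,
           label = if (is.null(meta_kv$label)) "" else meta_kv$label,
           n_scans = if (is.null(meta_kv$n_scans)) 1L
                     else as.integer(meta_kv$n_scans),
           meta = meta)
}

parse_meta_lines <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      # values may be quoted to protect separators
      if (grepl('^".*"$', val)) val <- gsub('""', '"', substr(val, 2, nchar(val) - 1))
      out[[key]] <- val
    }
  }
  out
}

#' Write a time-domain trace to CSV
#'
#' Inverse of [read_trace()]: emits `#key=value` metadata lines, a column
#' header, then the `time_ps,amplitude` rows at full double precision so the
#' round trip is bit-identical.
#'
#' @param trace a valid [td_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "td_trace")) stop("`trace` must be a td_trace", call. = FALSE)
  quote_val <- function(v) {
    v <- as.character(v)
    if (grepl('[",\n]', v)) paste0('"', gsub('"', '""', v), '"') else v
  }
  hdr <- character(0)
  if (nzchar(trace$label)) hdr <- c(hdr, paste0("#label=", quote_val(trace$label)))
  hdr <- c(hdr, paste0("#n_scans=", trace$n_scans))
  if (!is.null(trace$meta)) {
    hdr <- c(hdr,
             sprintf("#thickness_mm=%.17g", trace$meta$thickness_mm),
             sprintf("#temperature_K=%.17g", trace$meta$temperature_K))
    if (nzchar(trace$meta$sample_id)) {
      hdr <- c(hdr, paste0("#sample_id=", quote_val(trace$meta$sample_id)))
    }
  }
  rows <- sprintf("%.17g,%.17g", trace$time, trace$amplitude)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, "time_ps,amplitude", rows), con)
  invisible(path)
}
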