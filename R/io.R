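#' Read a pi-A isotherm file
#'
#' The on-disk format is a deliberately simple, instrument-agnostic CSV
#' dialect (proprietary trough-software exports are expected to be converted
#' externally):
#'
#' \preformatted{
#' # compound_id=DMPC
#' # molar_fraction_x2=0
#' # temperature_C=37
#' area_A2,pressure_mN_per_m
#' 130.0,0.02
#' 120.0,0.15
#' ...
#' }
#'
#' Header lines start with `#` and hold `key=value` metadata; values
#' containing special characters may be double-quoted. Unknown keys are
#' preserved in `meta`. The body is exactly two numeric columns named
#' `area_A2` and `pressure_mN_per_m`, UTF-8, `.` decimal separator, in
#' acquisition order. Parsing does not enforce compression monotonicity --
#' an expansion tail is accepted and noted in `meta$source`; use
#' [extract_compression_branch()] before analysis.
#'
#' @param path path to an isotherm file.
#' @return An [isotherm] object, points in file order.
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(trimws(lines), "#")
  meta <- parse_meta_lines(lines[is_hdr], path)
  body <- lines[!is_hdr]
  if (length(body) == 0L) stop("format error in ", path, ": no data rows",
                               call. = FALSE)
  # first body line must be the column header
  cols <- trimws(strsplit(body[[1L]], ",", fixed = TRUE)[[1L]])
  if (!identical(cols, c("area_A2", "pressure_mN_per_m")))
    stop("format error in ", path,
         ": expected column header 'area_A2,pressure_mN_per_m', got '",
         body[[1L]], "'", call. = FALSE)
  rows <- body[-1L]
  if (length(rows) < 4L)
    stop("insufficient data in ", path, ": fewer than 4 points",
         call. = FALSE)
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_ncol <- which(lengths(parts) != 2L)
  if (length(bad_ncol))
    stop("format error in ", path, " at data row ", bad_ncol[[1L]], ": '",
         rows[[bad_ncol[[1L]]]], "' does not have two columns",
         call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(parts)))),
              ncol = 2L, byrow = TRUE)
  bad <- which(rowSums(is.na(m)) > 0L)
  if (length(bad))
    stop("format error in ", path, " at data row ", bad[[1L]], ": '",
         rows[[bad[[1L]]]], "' is not numeric", call. = FALSE)

  known <- c("compound_id", "molar_fraction_x2", "temperature_C",
             "noise_sigma", "source")
  get <- function(key, default, as = identity) {
    if (!is.null(meta[[key]])) as(meta[[key]]) else default
  }
  source_txt <- get("source", "", as.character)
  # flag (do not repair) records whose area rises again at the tail
  if (any(diff(m[, 1L]) > 0)) {
    note <- "non-monotone area (expansion or jitter present)"
    source_txt <- if (nzchar(source_txt)) paste(source_txt, note, sep = "; ")
                  else note
  }
  isotherm(area = m[, 1L], pressure = m[, 2L],
           compound_id = get("compound_id", "unknown", as.character),
           molar_fraction_x2 = get("molar_fraction_x2", 0, as.numeric),
           temperature_C = get("temperature_C", 37, as.numeric),
           noise_sigma = get("noise_sigma", 0, as.numeric),
           source = source_txt,
           extra = meta[setdiff(names(meta), known)])
}

parse_meta_lines <- function(hdr, path) {
  meta <- list()
  for (ln in hdr) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (!nzchar(body)) next
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 0L)
      stop("format error in ", path, ": header line '", ln,
           "' is not 'key=value'", call. = FALSE)
    key <- trimws(substr(body, 1L, eq - 1L))
    val <- trimws(substr(body, eq + 1L, nchar(body)))
    # strip optional double quotes, un-escape embedded quotes
    if (nchar(val) >= 2L && startsWith(val, "\"") && endsWith(val, "\""))
      val <- gsub("\\\"", "\"", substr(val, 2L, nchar(val) - 1L),
                  fixed = TRUE)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num
                   else val
  }
  meta
}

#' Write a pi-A isotherm file
#'
#' Writes the CSV dialect documented in [read_isotherm()]. Numeric values
#' are written with enough digits (at least 8 significant) for
#' `read_isotherm(write_isotherm(iso, p))` to reproduce `iso` to better
#' than 1e-6 relative.
#'
#' @param iso an [isotherm] object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  validate_isotherm(iso)
  fmt_val <- function(v) {
    if (is.numeric(v)) return(format(v, digits = 10, scientific = FALSE,
                                     trim = TRUE))
    v <- as.character(v)
    if (grepl("[\",#=]|^\\s|\\s$|\\s", v))
      v <- paste0("\"", gsub("\"", "\\\"", v, fixed = TRUE), "\"")
    v
  }
  meta <- iso$meta
  hdr <- vapply(names(meta),
                function(k) paste0("# ", k, "=", fmt_val(meta[[k]])),
                character(1L))
  body <- sprintf("%.8g,%.8g", iso$area, iso$pressure)
  out <- c(hdr, "area_A2,pressure_mN_per_m", body)
  ok <- tryCatch({
    writeLines(out, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write isotherm to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Extract the monotone compression branch of an isotherm
#'
#' Thermodynamic analysis uses the compression run only. The rule is:
#' truncate the record at the point of global minimum area (everything after
#' it is expansion / hysteresis), then walk the remaining prefix keeping a
#' running minimum area and drop any point whose area exceeds that running
#' minimum by more than `area_jitter_tol` (barrier-position jitter);
#' finally merge points closer than the tolerance so the result is strictly
#' decreasing in area. Metadata is carried through unchanged. The operation
#' is idempotent.
#'
#' @param iso an [isotherm] object.
#' @param area_jitter_tol non-negative tolerance in A^2 below which a small
#'   backward area step is treated as jitter and merged (default 0.05).
#' @return An [isotherm] whose `area` is strictly decreasing.
#' @export
extract_compression_branch <- function(iso, area_jitter_tol = 0.05) {
  validate_isotherm(iso)
  stopifnot(area_jitter_tol >= 0)
  a0 <- iso$area
  p0 <- iso$pressure
  last <- which.min(a0) # global minimum area: end of compression
  a0 <- a0[seq_len(last)]
  p0 <- p0[seq_len(last)]
  a <- p <- numeric(0L)
  for (i in seq_along(a0)) {
    k <- length(a)
    if (k == 0L || a0[i] < a[k] - 1e-12) { # strictly advancing
      a <- c(a, a0[i])
      p <- c(p, p0[i])
    } else if (a0[i] <= a[k] + area_jitter_tol) {
      # small backward/stalled step: jitter, merge into the previous point
      a[k] <- (a[k] + a0[i]) / 2
      p[k] <- (p[k] + p0[i]) / 2
      if (k > 1L && a[k] >= a[k - 1L]) { # merged point must stay monotone
        a[k] <- a[k - 1L] - 1e-9
      }
    } # else: backward step beyond tolerance, dropped
  }
  if (length(a) < 4L)
    stop("insufficient data: fewer than 4 points survive ",
         "compression-branch extraction", call. = FALSE)
  out <- iso
  out$area <- a
  out$pressure <- p
  out
}
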