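#' Read a delimited table into a validated domain object
#'
#' One entry point for the four tabular inputs of the pipeline. The
#' delimiter (comma or tab) is auto-detected from the header row. Rows that
#' violate a schema invariant are rejected with their row numbers; the
#' function never drops rows silently (`n input = n accepted + n rejected`).
#'
#' Schemas and mandatory columns:
#' \describe{
#'   \item{phenotype}{`individual, population, region, sex, year, trait,
#'     value` (long format, one row per individual x trait). Duplicate
#'     (individual, trait) pairs and non-finite values are rejected;
#'     brightness traits must lie in \[0, 1\].}
#'   \item{locality}{`name, region, latitude, longitude` (+ optional
#'     `altitude`). Latitude in \[-90, 90\], longitude in \[-180, 180\],
#'     names unique.}
#'   \item{assay}{`assay_id, bird_id, population, duration, n_quarters,
#'     n_perches, decorated, time, event, arg`: one row per time-stamped
#'     event, assay metadata repeated; `decorated` is a `|`-separated list
#'     of decorated perch ids. Parsed into a list of assay logs.}
#'   \item{spectrum}{`sample` plus 36 reflectance columns named
#'     `wl_380 ... wl_730` (10 nm steps).}
#' }
#'
#' @param path file path.
#' @param schema one of `"phenotype"`, `"locality"`, `"assay"`, `"spectrum"`.
#' @return The corresponding domain object; rejected rows (if any) are
#'   attached as attribute `"rejects"` (data.frame of row numbers + reason).
#' @export
read_table <- function(path, schema = c("phenotype", "locality",
                                        "assay", "spectrum")) {
  schema <- match.arg(schema)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "\"", comment.char = "",
                   fileEncoding = "UTF-8")
  switch(schema,
         phenotype = validate_phenotypes(df),
         locality  = validate_localities(df),
         assay     = validate_assays(df),
         spectrum  = validate_spectra(df))
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

as_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    stop(sprintf("non-numeric value in numeric field '%s' (row %d: '%s')",
                 col, bad[1], x[bad[1]]), call. = FALSE)
  }
  out
}

finish <- function(df, keep, reasons, cls) {
  rej <- data.frame(row = which(!keep), reason = reasons[!keep],
                    stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c(cls, "data.frame")
  attr(out, "rejects") <- rej
  if (nrow(rej)) {
    warning(sprintf("%d row(s) rejected: %s", nrow(rej),
                    paste(sprintf("row %d (%s)", head(rej$row, 5),
                                  head(rej$reason, 5)), collapse = "; ")),
            call. = FALSE)
  }
  out
}

#' Build a phenotype table from a data.frame
#'
#' @param df data.frame with columns `individual, population, region, sex,
#'   year, trait, value`.
#' @return A `phenotype_table` (data.frame subclass), rejected rows in
#'   attribute `"rejects"`.
#' @export
validate_phenotypes <- function(df) {
  need_cols(df, c("individual", "population", "region", "sex", "year",
                  "trait", "value"), "phenotype")
  df$value <- as_num(df$value, "value")
  df$year <- as_num(df$year, "year")
  keep <- rep(TRUE, nrow(df)); why <- rep("", nrow(df))
  bad <- !is.finite(df$value)
  why[bad] <- "non-finite value"; keep <- keep & !bad
  dup <- duplicated(df[, c("individual", "trait")])
  why[dup & keep] <- "duplicate (individual, trait)"; keep <- keep & !dup
  isb <- grepl("brightness", df$trait, ignore.case = TRUE)
  oob <- isb & (df$value < 0 | df$value > 1)
  why[oob & keep] <- "brightness outside [0, 1]"; keep <- keep & !oob
  finish(df, keep, why, "phenotype_table")
}

validate_localities <- function(df) {
  need_cols(df, c("name", "region", "latitude", "longitude"), "locality")
  df$latitude <- as_num(df$latitude, "latitude")
  df$longitude <- as_num(df$longitude, "longitude")
  if (!"altitude" %in% names(df)) df$altitude <- NA_real_
  else df$altitude <- as_num(df$altitude, "altitude")
  if (anyDuplicated(df$name)) {
    stop("locality names must be unique", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(df)); why <- rep("", nrow(df))
  bad <- is.na(df$latitude) | abs(df$latitude) > 90
  why[bad] <- "latitude outside [-90, 90]"; keep <- keep & !bad
  bad2 <- is.na(df$longitude) | abs(df$longitude) > 180
  why[bad2 & keep] <- "longitude outside [-180, 180]"; keep <- keep & !bad2
  if (any(!keep)) {
    stop(sprintf("locality validation error: %s (row %s)",
                 why[!keep][1], which(!keep)[1]), call. = FALSE)
  }
  finish(df, keep, why, "locality_table")
}

#' Construct a behavioral assay log
#'
#' @param assay_id,bird_id,population identifiers.
#' @param duration assay duration in minutes (> 0).
#' @param events data.frame with columns `time` (minutes, nondecreasing,
#'   within \[0, duration\]), `event` (one of `hop`, `flight`, `move`,
#'   `enter_quarter`, `land_perch`, `enter_center`, `leave_center`) and
#'   `arg` (quarter / perch id where applicable, else `NA`).
#' @param n_quarters,n_perches arena configuration (defaults 4 and 6).
#' @param decorated integer ids of the decorated (novel-object) perches.
#' @return An object of class `assay_log`.
#' @export
assay_log <- function(assay_id, bird_id, population, duration, events,
                      n_quarters = 4L, n_perches = 6L, decorated = c(1L, 2L, 3L)) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "event", "arg") %in% names(events)))
  kinds <- c("hop", "flight", "move", "enter_quarter", "land_perch",
             "enter_center", "leave_center")
  if (!all(events$event %in% kinds)) {
    stop("unknown event kind: ",
         paste(setdiff(unique(events$event), kinds), collapse = ", "))
  }
  if (is.unsorted(events$time)) stop("event timestamps must be nondecreasing")
  if (nrow(events) && (min(events$time) < 0 || max(events$time) > duration)) {
    stop("event timestamps must lie within [0, duration]")
  }
  q <- events$arg[events$event == "enter_quarter"]
  if (length(q) && (anyNA(q) || any(q < 1 | q > n_quarters))) {
    stop("quarter id outside arena configuration")
  }
  p <- events$arg[events$event == "land_perch"]
  if (length(p) && (anyNA(p) || any(p < 1 | p > n_perches))) {
    stop("perch id outside arena configuration")
  }
  if (length(decorated) && any(decorated < 1 | decorated > n_perches)) {
    stop("decorated perch id outside arena configuration")
  }
  structure(list(assay_id = assay_id, bird_id = bird_id,
                 population = population, duration = duration,
                 n_quarters = as.integer(n_quarters),
                 n_perches = as.integer(n_perches),
                 decorated = as.integer(decorated), events = events),
            class = "assay_log")
}

validate_assays <- function(df) {
  need_cols(df, c("assay_id", "bird_id", "population", "duration",
                  "decorated", "time", "event", "arg"), "assay")
  df$duration <- as_num(df$duration, "duration")
  df$time <- as_num(df$time, "time")
  df$arg <- suppressWarnings(as.integer(df$arg))
  logs <- lapply(split(df, df$assay_id), function(d) {
    dec <- d$decorated[1]
    dec <- if (is.na(dec) || !nzchar(dec)) integer(0) else
      as.integer(strsplit(as.character(dec), "[|;]")[[1]])
    assay_log(d$assay_id[1], d$bird_id[1], d$population[1], d$duration[1],
              d[order(d$time), c("time", "event", "arg")],
              n_quarters = if ("n_quarters" %in% names(d)) d$n_quarters[1] else 4L,
              n_perches = if ("n_perches" %in% names(d)) d$n_perches[1] else 6L,
              decorated = dec)
  })
  logs[order(vapply(logs, `[[`, "", "assay_id"))]
}

#' Wavelength grid of the reflectance tables (380-730 nm, 10 nm steps)
#' @return Integer vector of the 36 wavelengths in nm.
#' @export
spectrum_wavelengths <- function() seq(380L, 730L, by = 10L)

#' Build a spectrum table from a matrix of reflectances
#'
#' @param m numeric matrix, samples x 36 wavelengths (380-730 nm in 10 nm
#'   steps); reflectance fractions, nonnegative.
#' @param samples optional sample names.
#' @return A `spectrum_table`: the matrix with wavelength column names.
#' @export
spectrum_table <- function(m, samples = rownames(m)) {
  m <- as.matrix(m)
  wl <- spectrum_wavelengths()
  if (ncol(m) != length(wl)) {
    stop(sprintf("spectrum must have exactly %d wavelength points, got %d",
                 length(wl), ncol(m)), call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("reflectance must be finite and nonnegative", call. = FALSE)
  }
  dimnames(m) <- list(samples %||% paste0("s", seq_len(nrow(m))),
                      paste0("wl_", wl))
  class(m) <- c("spectrum_table", "matrix", "array")
  m
}

validate_spectra <- function(df) {
  need_cols(df, "sample", "spectrum")
  wlc <- grep("^wl_", names(df), value = TRUE)
  m <- as.matrix(df[, wlc, drop = FALSE])
  for (j in seq_len(ncol(m))) m[, j] <- as_num(m[, j], wlc[j])
  ord <- order(as.integer(sub("wl_", "", wlc)))
  spectrum_table(m[, ord, drop = FALSE], samples = as.character(df$sample))
}
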