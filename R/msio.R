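# Spectrum / feature-table IO and probe-library construction.

#' Construct an MS/MS spectrum
#'
#' The core spectral container: a precursor, optional retention time, polarity
#' and a peak list sorted by ascending m/z. Peaks closer than 1e-6 m/z are
#' merged (intensities summed) so the no-duplicate invariant holds.
#'
#' @param id Spectrum identifier (carried as the node id downstream).
#' @param precursor_mz Precursor m/z (> 0).
#' @param peaks data.frame with numeric columns `mz` (> 0) and `intensity`
#'   (>= 0), or a 2-column matrix.
#' @param rt Retention time in seconds; `NA` allowed for library records.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(id, precursor_mz, peaks, rt = NA_real_,
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L, precursor_mz > 0)
  if (is.matrix(peaks)) peaks <- data.frame(mz = peaks[, 1], intensity = peaks[, 2])
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  peaks <- data.frame(mz = as.numeric(peaks$mz),
                      intensity = as.numeric(peaks$intensity))
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("peak m/z must be > 0")
    if (any(peaks$intensity < 0)) stop("peak intensity must be >= 0")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    # merge duplicates within 1e-6
    grp <- cumsum(c(TRUE, diff(peaks$mz) > 1e-6))
    if (max(grp) < nrow(peaks)) {
      peaks <- data.frame(
        mz = tapply(peaks$mz, grp, function(z) z[1]),
        intensity = tapply(peaks$intensity, grp, sum)
      )
    }
    rownames(peaks) <- NULL
  }
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 rt = as.numeric(rt), polarity = polarity, peaks = peaks),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum %s> precursor %.4f, rt %s s, %s, %d peaks\n",
              x$id, x$precursor_mz,
              if (is.na(x$rt)) "NA" else sprintf("%.1f", x$rt),
              x$polarity, nrow(x$peaks)))
  invisible(x)
}

#' Read MS/MS spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks. `PEPMASS` is required per block;
#' `RTINSECONDS`, `CHARGE` (sign gives polarity) and `TITLE` (the spectrum id)
#' are honoured when present.
#'
#' @param path MGF file path.
#' @param default_polarity Polarity assumed when no CHARGE line is present.
#' @return List of [msms_spectrum] objects.
#' @export
read_mgf <- function(path, default_polarity = "positive") {
  lines <- readLines(path, warn = FALSE)
  begins <- which(toupper(trimws(lines)) == "BEGIN IONS")
  ends <- which(toupper(trimws(lines)) == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- trimws(lines[(begins[i] + 1L):(ends[i] - 1L)])
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- getv("PEPMASS")
    if (is.na(pep)) stop("MGF block ", i, " missing PEPMASS")
    precursor <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    title <- getv("TITLE")
    id <- if (is.na(title) || !nzchar(title)) sprintf("spectrum_%d", i) else title
    charge <- getv("CHARGE")
    polarity <- if (is.na(charge)) default_polarity
                else if (grepl("-", charge, fixed = TRUE)) "negative" else "positive"
    pk <- block[!is_kv]
    peaks <- if (length(pk)) {
      parts <- strsplit(pk, "[ \t]+")
      mz <- as.numeric(vapply(parts, `[`, character(1), 1L))
      it <- as.numeric(vapply(parts, function(p) if (length(p) >= 2) p[2] else "0",
                              character(1)))
      if (anyNA(mz) || anyNA(it)) stop("malformed peak line in MGF block ", i)
      data.frame(mz = mz, intensity = it)
    } else data.frame(mz = numeric(0), intensity = numeric(0))
    out[[i]] <- msms_spectrum(id, precursor, peaks, rt = rt, polarity = polarity)
  }
  out
}

#' Write MS/MS spectra to an MGF file
#'
#' Canonical dialect: `TITLE` carries the spectrum id, `PEPMASS` the precursor,
#' `RTINSECONDS` when available, and `CHARGE=1+`/`1-` encoding polarity.
#' Round-trips with [read_mgf()].
#'
#' @param spectra List of [msms_spectrum] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "msms_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp$rt), con)
    writeLines(paste0("CHARGE=1", if (sp$polarity == "negative") "-" else "+"), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from an MSP library file (minimal adapter)
#'
#' Supports the common `Name:` / `PrecursorMZ:` / `Num Peaks:` dialect; peak
#' lines follow `Num Peaks:`. Retention time is left `NA` (library records
#' carry no chromatography).
#'
#' @param path MSP file path.
#' @param default_polarity Used when no `Ion_mode:`/`Ionmode:` field is present.
#' @return List of [msms_spectrum] objects.
#' @export
read_msp <- function(path, default_polarity = "positive") {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^name:", lines, ignore.case = TRUE)
  if (!length(starts)) return(list())
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    name <- trimws(sub("^name:", "", block[1], ignore.case = TRUE))
    pm_line <- grep("^(precursormz|precursor_mz)\\s*:", block, ignore.case = TRUE)
    if (!length(pm_line)) stop("MSP record '", name, "' missing PrecursorMZ")
    precursor <- as.numeric(trimws(sub("^[^:]*:", "", block[pm_line[1]])))
    mode_line <- grep("^(ion_?mode)\\s*:", block, ignore.case = TRUE)
    polarity <- default_polarity
    if (length(mode_line)) {
      v <- tolower(trimws(sub("^[^:]*:", "", block[mode_line[1]])))
      polarity <- if (grepl("^n", v)) "negative" else "positive"
    }
    np_line <- grep("^num ?peaks\\s*:", block, ignore.case = TRUE)
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
    if (length(np_line)) {
      pk <- trimws(block[(np_line[1] + 1L):length(block)])
      pk <- pk[nzchar(pk) & !grepl(":", pk)]
      if (length(pk)) {
        parts <- strsplit(pk, "[ \t;]+")
        peaks <- data.frame(
          mz = as.numeric(vapply(parts, `[`, character(1), 1L)),
          intensity = as.numeric(vapply(parts, `[`, character(1), 2L)))
      }
    }
    out[[i]] <- msms_spectrum(name, precursor, peaks, polarity = polarity)
  }
  out
}

#' Read an MS1 feature table
#'
#' Reads a delimited peak list of metabolic features (m/z, retention time,
#' intensity). Column names are configurable; retention times are normalized
#' to seconds.
#'
#' @param path CSV/TSV path (delimiter inferred from extension, `.tsv`/`.txt`
#'   read as tab-separated).
#' @param mz_col,rt_col,intensity_col,id_col Column names; `id_col = NULL`
#'   autogenerates ids `F1, F2, ...`.
#' @param rt_unit `"s"` or `"min"`; minutes are converted to seconds.
#' @return data.frame with columns `id`, `mz`, `rt` (seconds), `intensity`.
#' @export
read_feature_table <- function(path, mz_col = "mz", rt_col = "rt",
                               intensity_col = "intensity", id_col = NULL,
                               rt_unit = c("s", "min")) {
  rt_unit <- match.arg(rt_unit)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(mz_col, rt_col, intensity_col, id_col)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty feature table: ", path)
    return(data.frame(id = character(0), mz = numeric(0), rt = numeric(0),
                      intensity = numeric(0)))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric value in column '", col, "'")
    v
  }
  out <- data.frame(
    id = if (is.null(id_col)) sprintf("F%d", seq_len(nrow(df)))
         else as.character(df[[id_col]]),
    mz = num(mz_col),
    rt = num(rt_col) * if (rt_unit == "min") 60 else 1,
    intensity = num(intensity_col),
    stringsAsFactors = FALSE
  )
  if (any(out$mz <= 0)) stop("feature m/z must be > 0")
  if (any(out$rt < 0)) stop("feature rt must be >= 0")
  out
}

#' Build a probe spectral library
#'
#' Filters candidate reference spectra down to the target chemical classes and
#' polarity, emulating the construction of a pathway probe database from
#' public spectral libraries after compound-class assignment. Class labels are
#' supplied as a table (id -> class); no web classification is performed here.
#' Several spectra of one compound are retained as separate records.
#'
#' @param records List of records, each a list with elements `spectrum`
#'   ([msms_spectrum]), `compound_name`, and optionally `instrument`,
#'   `library_source`.
#' @param class_table data.frame mapping spectrum `id` to `chemical_class`.
#' @param target_classes Character vector of classes to retain.
#' @param polarity Keep only records of this polarity.
#' @return A `probe_library`: list with `records` (each gains
#'   `chemical_class`), `class_counts`, `instrument_counts`, and
#'   `n_dropped_no_class`.
#' @export
build_probe_library <- function(records, class_table, target_classes,
                                polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(all(c("id", "chemical_class") %in% names(class_table)))
  class_map <- stats::setNames(as.character(class_table$chemical_class),
                               as.character(class_table$id))
  kept <- list()
  n_no_class <- 0L
  for (rec in records) {
    sp <- rec$spectrum
    stopifnot(inherits(sp, "msms_spectrum"))
    if (sp$polarity != polarity) next
    cls <- class_map[sp$id]
    if (is.na(cls)) { n_no_class <- n_no_class + 1L; next }
    if (!cls %in% target_classes) next
    rec$chemical_class <- unname(cls)
    if (is.null(rec$instrument)) rec$instrument <- "unknown"
    if (is.null(rec$library_source)) rec$library_source <- "unknown"
    kept[[length(kept) + 1L]] <- rec
  }
  if (n_no_class > 0L)
    warning(n_no_class, " record(s) without a class mapping were dropped")
  classes <- vapply(kept, `[[`, character(1), "chemical_class")
  instruments <- vapply(kept, `[[`, character(1), "instrument")
  structure(list(records = kept,
                 polarity = polarity,
                 class_counts = if (length(kept)) table(classes) else table(character(0)),
                 instrument_counts = if (length(kept)) table(instruments) else table(character(0)),
                 n_dropped_no_class = n_no_class),
            class = "probe_library")
}

#' @export
print.probe_library <- function(x, ...) {
  cat(sprintf("<probe_library> %d records (%s mode), %d class(es)\n",
              length(x$records), x$polarity, length(x$class_counts)))
  invisible(x)
}

#' @export
length.probe_library <- function(x) length(x$records)

# Named list of probe spectra from a probe_library (or a plain spectrum list).
probe_spectra <- function(probes) {
  sps <- if (inherits(probes, "probe_library"))
    lapply(probes$records, `[[`, "spectrum") else probes
  stats::setNames(sps, vapply(sps, `[[`, character(1), "id"))
}
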