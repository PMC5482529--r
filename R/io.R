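# Delimited-text readers and writers. All files are whitespace- or
# comma-delimited numeric columns with '#' metadata header lines of the
# form "# key = value"; this matches how reduced SANS / DLS / rheology
# data circulate. Round trips are lossless to 12+ significant digits.

.parse_meta <- function(lines) {
  meta <- list()
  hdr <- grep("^\\s*#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

.read_numeric_table <- function(path, min_cols) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_meta(lines)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(data_idx)) stop_input("no data rows in ", path)
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop_input("malformed row at line ", i, " of ", path)
    vals
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1L)
    stop_input("inconsistent column count (first differing line ",
               data_idx[which(ncols != ncols[1])[1]], ") in ", path)
  if (ncols[1] < min_cols)
    stop_input("expected at least ", min_cols, " columns in ", path)
  list(data = do.call(rbind, rows), meta = meta)
}

.meta_num <- function(meta, key, default = NA_real_) {
  if (!is.null(meta[[key]]) && is.numeric(meta[[key]])) meta[[key]] else default
}

.write_table <- function(path, columns, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.na(meta[[k]]) && nzchar(format(meta[[k]])))
      writeLines(sprintf("# %s = %s", k, format(meta[[k]], digits = 15)), con)
  mat <- do.call(cbind, columns)
  writeLines(apply(mat, 1, function(r)
    paste(sprintf("%.15g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a reduced SANS profile from delimited text
#'
#' Expects 2 or 3 numeric columns `q, I[, sigma]` with optional
#' `# key = value` metadata headers (`temperature`, `concentration`,
#' `wavelength`). When the sigma column is absent, the
#' counting-statistics surrogate of [scattering_profile()] is synthesized
#' and reported with a message.
#'
#' @param path file path.
#' @param q_units `"nm"` (nm^-1, native) or `"ang"` (Angstrom^-1,
#'   converted by x10).
#' @return a [scattering_profile()].
#' @export
read_sans <- function(path, q_units = c("nm", "ang")) {
  q_units <- match.arg(q_units)
  tb <- .read_numeric_table(path, 2L)
  q <- tb$data[, 1]
  if (q_units == "ang") q <- q * 10
  sigma <- if (ncol(tb$data) >= 3L) tb$data[, 3] else NULL
  if (is.null(sigma))
    message("no sigma column; synthesizing sqrt(I)-scaled uncertainties")
  scattering_profile(q, tb$data[, 2], sigma,
                     temperature = .meta_num(tb$meta, "temperature"),
                     concentration = .meta_num(tb$meta, "concentration"),
                     wavelength = .meta_num(tb$meta, "wavelength"))
}

#' Write a scattering profile as 3-column delimited text
#' @param profile a [scattering_profile()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sans <- function(profile, path) {
  .write_table(path,
               list(profile$q, profile$intensity, profile$sigma),
               list(temperature = profile$temperature,
                    concentration = profile$concentration,
                    wavelength = profile$wavelength))
}

#' Read a DLS correlation trace (lag seconds, g\[, sigma\])
#' @inheritParams read_sans
#' @return a [correlation_trace()].
#' @export
read_dls <- function(path) {
  tb <- .read_numeric_table(path, 2L)
  correlation_trace(tb$data[, 1], tb$data[, 2],
                    sigma = if (ncol(tb$data) >= 3L) tb$data[, 3],
                    temperature = .meta_num(tb$meta, "temperature"),
                    concentration = .meta_num(tb$meta, "concentration"))
}

#' Write a DLS trace as delimited text
#' @param trace a [correlation_trace()].
#' @param path output path.
#' @export
write_dls <- function(trace, path) {
  cols <- list(trace$lag, trace$g)
  if (!is.null(trace$sigma)) cols <- c(cols, list(trace$sigma))
  .write_table(path, cols,
               list(temperature = trace$temperature,
                    concentration = trace$concentration))
}

#' Read a 1-D NMR spectrum (ppm, intensity)
#'
#' Standard metadata headers: `temperature`, `c_total`, `std_conc`,
#' `std_protons`, `gelator_protons`; the latter three may instead be
#' supplied as arguments (arguments win).
#'
#' @inheritParams read_sans
#' @param std_conc,std_protons,gelator_protons override the file metadata.
#' @return an [nmr_spectrum()].
#' @export
read_nmr <- function(path, std_conc = NULL, std_protons = NULL,
                     gelator_protons = NULL) {
  tb <- .read_numeric_table(path, 2L)
  nmr_spectrum(tb$data[, 1], tb$data[, 2],
               temperature = .meta_num(tb$meta, "temperature"),
               c_total = .meta_num(tb$meta, "c_total"),
               std_conc = std_conc %||% .meta_num(tb$meta, "std_conc"),
               std_protons = std_protons %||%
                 .meta_num(tb$meta, "std_protons", 9),
               gelator_protons = gelator_protons %||%
                 .meta_num(tb$meta, "gelator_protons", 5))
}

#' Write an NMR spectrum as delimited text
#' @param spectrum an [nmr_spectrum()].
#' @param path output path.
#' @export
write_nmr <- function(spectrum, path) {
  .write_table(path, list(spectrum$shift, spectrum$intensity),
               list(temperature = spectrum$temperature,
                    c_total = spectrum$c_total,
                    std_conc = spectrum$std_conc,
                    std_protons = spectrum$std_protons,
                    gelator_protons = spectrum$gelator_protons))
}

#' Read an AFM height map (whitespace-delimited rows of heights)
#'
#' Requires a `# pixel_size = <nm>` metadata header.
#'
#' @inheritParams read_sans
#' @return a [height_map()].
#' @export
read_afm <- function(path) {
  tb <- .read_numeric_table(path, 2L)
  px <- .meta_num(tb$meta, "pixel_size")
  if (is.na(px)) stop_input("AFM file needs a '# pixel_size = ...' header")
  height_map(tb$data, px)
}

#' Write an AFM height map as delimited text
#' @param map a [height_map()].
#' @param path output path.
#' @export
write_afm <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size = %s",
                     format(map$pixel_size, digits = 15)), con)
  writeLines(apply(map$heights, 1, function(r)
    paste(sprintf("%.15g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a rheology frequency sweep (omega, G', G'')
#' @inheritParams read_sans
#' @return a [rheo_sweep()].
#' @export
read_rheo <- function(path) {
  tb <- .read_numeric_table(path, 3L)
  rheo_sweep(tb$data[, 1], tb$data[, 2], tb$data[, 3],
             temperature = .meta_num(tb$meta, "temperature"),
             concentration = .meta_num(tb$meta, "concentration"),
             strain = .meta_num(tb$meta, "strain"))
}

#' Write a rheology sweep as delimited text
#' @param sweep a [rheo_sweep()].
#' @param path output path.
#' @export
write_rheo <- function(sweep, path) {
  .write_table(path, list(sweep$omega, sweep$g_prime, sweep$g_double_prime),
               list(temperature = sweep$temperature,
                    concentration = sweep$concentration,
                    strain = sweep$strain))
}

#' Write an analysis result as a flat key = value record
#'
#' Scalars and short vectors from fit/classification results are written
#' one `key = value` line each; numbers keep 15 significant digits.
#'
#' @param record a named list (nested one level for parameter sets).
#' @param path output path.
#' @export
write_result <- function(record, path) {
  flat <- list()
  for (k in names(record)) {
    v <- record[[k]]
    if (is.list(v)) {
      v <- v[!vapply(v, is.null, logical(1))]
      for (k2 in names(v))
        if (length(v[[k2]]) == 1L && is.atomic(v[[k2]]))
          flat[[paste0(k, ".", k2)]] <- v[[k2]]
    } else if (is.atomic(v) && length(v) >= 1L && !is.null(names(v))) {
      for (k2 in names(v)) flat[[paste0(k, ".", k2)]] <- v[[k2]]
    } else if (is.atomic(v) && length(v) == 1L) {
      flat[[k]] <- v
    }
  }
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) sprintf("%.15g", v) else format(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value record written by [write_result()]
#' @param path file path.
#' @return named list with numeric values where parseable.
#' @export
read_result <- function(path) {
  .parse_meta(paste0("# ", readLines(path, warn = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
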