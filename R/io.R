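# Reduced 1-D curve container and plain-text readers/writers.

#' Reduced 1-D scattering curve
#'
#' @param q scattering vector (1/A), strictly increasing.
#' @param intensity intensity (1/cm).
#' @param sigma 1-sigma uncertainties (1/cm), all > 0.
#' @param dq optional Gaussian resolution sigma per point (1/A).
#' @param metadata named list (radiation, f_d2o, temperature, label, ...).
#' @export
scattering_curve <- function(q, intensity, sigma, dq = NULL,
                             metadata = list()) {
  stopifnot(length(q) == length(intensity), length(q) == length(sigma))
  if (length(q) == 0) stop("empty curve", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (!is.null(dq)) stopifnot(length(dq) == length(q), all(dq >= 0))
  structure(list(q = q, intensity = intensity, sigma = sigma, dq = dq,
                 metadata = metadata), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  lab <- x$metadata$label %||% "scattering curve"
  cat(sprintf("<scattering_curve> %s: %d points, Q = %.4g..%.4g 1/A%s\n",
              lab, length(x$q), min(x$q), max(x$q),
              if (is.null(x$dq)) "" else ", with resolution column"))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity, sigma = x$sigma)
  if (!is.null(x$dq)) d$dq <- x$dq
  d
}

#' Read a reduced curve from whitespace-delimited ASCII
#'
#' Expects >= 3 numeric columns (Q in 1/A, I in 1/cm, sigma in 1/cm); an
#' optional 4th column is the resolution dQ.  Lines starting with `#` are
#' comments and are preserved in `metadata$comments`; `# key: value`
#' comments populate metadata fields.  Malformed rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @return a [scattering_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  meta <- list(comments = comments)
  kv <- regmatches(comments, regexec("^([A-Za-z_][A-Za-z0-9_.]*):\\s*(.+)$", comments))
  for (m in kv) if (length(m) == 3) {
    v <- utils::type.convert(m[3], as.is = TRUE)
    meta[[m[2]]] <- v
  }
  data_idx <- which(!is_comment & !is_blank)
  if (!length(data_idx)) stop("no data rows in '", path, "'", call. = FALSE)
  rows <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncols <- lengths(rows)
  bad <- data_idx[ncols < 3]
  if (length(bad))
    stop("malformed rows (fewer than 3 columns) at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  nc <- min(ncols)
  vals <- vapply(rows, function(r)
    suppressWarnings(as.numeric(r[seq_len(nc)])), numeric(nc))
  if (anyNA(vals)) {
    badl <- data_idx[apply(is.na(vals), 2, any)]
    stop("non-numeric values at line(s): ", paste(badl, collapse = ", "),
         call. = FALSE)
  }
  vals <- t(vals)
  scattering_curve(vals[, 1], vals[, 2], vals[, 3],
                   dq = if (nc >= 4) vals[, 4] else NULL, metadata = meta)
}

#' Write a curve to whitespace-delimited ASCII
#'
#' Scalar metadata entries are written as `# key: value` header comments.
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @param digits significant digits (default 8).
#' @export
write_curve <- function(curve, path, digits = 8) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c("# columns: q[1/A] intensity[1/cm] sigma[1/cm]",
           if (!is.null(curve$dq)) "# column 4: dq[1/A]")
  for (k in setdiff(names(curve$metadata), "comments")) {
    v <- curve$metadata[[k]]
    if (length(v) == 1 && (is.numeric(v) || is.character(v) || is.logical(v)))
      hdr <- c(hdr, sprintf("# %s: %s", k, format(v, digits = 15)))
  }
  d <- as.data.frame(curve)
  body <- do.call(paste, c(lapply(d, function(col) signif(col, digits)),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
}

#' Read a flat key-value configuration file
#'
#' Format: `key: value` lines, `#` comments, optional `[section]` headers
#' which prefix keys as `section.key`.  Values are auto-typed (numeric,
#' logical, or string; comma-separated values become vectors).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'",
                             call. = FALSE)
    key <- trimws(m[2])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    raw <- trimws(m[3])
    parts <- trimws(strsplit(raw, ",")[[1]])
    val <- utils::type.convert(parts, as.is = TRUE)
    out[[key]] <- val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config named list of scalars/vectors.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, paste(format(config[[k]], digits = 15),
                               collapse = ", "))
  }, character(1))
  writeLines(lines, path)
}
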