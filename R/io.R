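## Text formats
## ------------
## Trace files: two-column text (time_us, amplitude; optional third column
## noise_sigma).  Header lines start with '#'; 'key: value' headers are kept
## as metadata.  A '# time_unit: ns' header marks a nanosecond time column,
## converted to us on read.  Comma- and whitespace-separated dialects and
## CRLF line endings are accepted.
## Distribution files: two-column text (r_nm, density_per_nm), same header
## conventions.

read_numeric_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  meta <- list()
  for (h in hdr) {
    h2 <- sub("^\\s*#\\s*", "", h)
    if (grepl(":", h2, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", h2))
      val <- trimws(sub("^[^:]*:", "", h2))
      if (nzchar(key)) meta[[key]] <- val
    }
  }
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(trimws(body[i]), "[,\\s]+", perl = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      stop(sprintf("malformed numeric field at data line %d: '%s'", i, body[i]),
           call. = FALSE)
    }
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("inconsistent column counts in ", path, call. = FALSE)
  list(data = do.call(rbind, rows), meta = meta)
}

#' Read a DEER trace from a text file
#'
#' @param path file path.
#' @return a [deer_trace]; header metadata is kept in `meta`.
#' @export
read_deer_trace <- function(path) {
  tb <- read_numeric_table(path)
  x <- tb$data
  if (ncol(x) < 2L) stop("trace file needs at least two columns", call. = FALSE)
  t <- x[, 1L]
  if (identical(tolower(tb$meta$time_unit %||% "us"), "ns")) t <- t / 1000
  ns <- if (ncol(x) >= 3L) x[1L, 3L] else
    suppressWarnings(as.numeric(tb$meta$noise_sigma %||% NA))
  deer_trace(t, x[, 2L], noise_sigma = ns, meta = tb$meta)
}

#' Write a DEER trace to a text file
#'
#' @param trace a [deer_trace].
#' @param path file path.
#' @export
write_deer_trace <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# deerpop trace: time_us amplitude", con)
  for (key in names(trace$meta)) {
    val <- trace$meta[[key]]
    if (is.atomic(val) && length(val) == 1L) {
      writeLines(sprintf("# %s: %s", key, format(val, digits = 15)), con)
    }
  }
  if (!is.na(trace$noise_sigma)) {
    writeLines(sprintf("# noise_sigma: %s", format(trace$noise_sigma, digits = 15)), con)
  }
  writeLines(sprintf("%.15g %.15g", trace$t, trace$signal), con)
  invisible(path)
}

#' Read a distance distribution from a text file
#' @param path file path.
#' @return a [distance_distribution].
#' @export
read_distribution <- function(path) {
  tb <- read_numeric_table(path)
  x <- tb$data
  if (ncol(x) < 2L) stop("distribution file needs two columns", call. = FALSE)
  distance_distribution(x[, 1L], x[, 2L], normalize = FALSE)
}

#' Write a distance distribution to a text file
#' @param dist a [distance_distribution].
#' @param path file path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# deerpop distribution: r_nm density_per_nm", con)
  writeLines(sprintf("%.15g %.15g", dist$r, dist$density), con)
  invisible(path)
}

#' Read a conformer ensemble
#'
#' Two dialects: a plain XYZ text dialect (blocks of `x y z` rows in nm, one
#' row per site, conformers separated by blank lines, '#' comments; a
#' `# site_labels: 273 274 ...` header assigns labels), or a multi-model PDB
#' (MODEL/ENDMDL records, coordinates in Angstrom converted to nm; requires
#' the bio3d package, CA atoms used).
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @return a [conformer_ensemble].
#' @export
read_ensemble <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz")
  if (format == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading PDB ensembles requires the bio3d package", call. = FALSE)
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    sel <- bio3d::atom.select(pdb, elety = "CA")
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
    labs <- pdb$atom$resno[sel$atom]
    conf <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
    })
    return(conformer_ensemble(conf, labs))
  }
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  labline <- grep("^\\s*#\\s*site_labels\\s*:", lines, value = TRUE)
  labs <- if (length(labline)) {
    as.integer(strsplit(trimws(sub("^[^:]*:", "", labline[1L])), "\\s+")[[1L]])
  } else NULL
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  conf <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    m <- do.call(rbind, lapply(b, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,\\s]+", perl = TRUE)[[1L]]))
      if (length(v) != 3L || any(is.na(v))) {
        stop("malformed ensemble coordinate line: '", l, "'", call. = FALSE)
      }
      v
    }))
    conf[[length(conf) + 1L]] <- m
  }
  conformer_ensemble(conf, labs)
}

#' Write a conformer ensemble in the XYZ text dialect
#' @param ensemble a [conformer_ensemble].
#' @param path file path.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# deerpop ensemble: one x y z (nm) row per site, blank line between conformers", con)
  writeLines(paste("# site_labels:", paste(ensemble$site_labels, collapse = " ")), con)
  for (i in seq_along(ensemble$conformers)) {
    m <- ensemble$conformers[[i]]
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L]), con)
    if (i < length(ensemble$conformers)) writeLines("", con)
  }
  invisible(path)
}
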