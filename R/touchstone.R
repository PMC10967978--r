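# Touchstone one-port (.s1p) reader/writer.
#
# On write the most widely parsed dialect is used: frequency in Hz,
# real/imaginary data, "# HZ S RI R 50" option line. The reader accepts
# the RI, MA and DB dialects and all four frequency units.

#' Write a one-port Touchstone file
#'
#' @param path Output `.s1p` path.
#' @param freq_ghz Frequency vector, GHz.
#' @param s11 Complex reflection-coefficient vector.
#' @param comment Optional comment line(s) written with a `!` prefix.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(path, freq_ghz, s11, comment = NULL) {
  stopifnot(length(freq_ghz) == length(s11))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("!", comment), con)
  writeLines("# HZ S RI R 50", con)
  writeLines(sprintf("%.6f %.10e %.10e",
                     freq_ghz * 1e9, Re(s11), Im(s11)), con)
  invisible(path)
}

#' Read a one-port Touchstone file
#'
#' Supports the `RI`, `MA` (magnitude, angle in degrees) and `DB`
#' (dB-magnitude, angle in degrees) dialects with `Hz`, `kHz`, `MHz` or
#' `GHz` frequency units per the option line.
#'
#' @param path Input `.s1p` path.
#' @return List with `freq_ghz` (numeric) and `s11` (complex).
#' @export
read_touchstone <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  opt <- grep("^#", lines, value = TRUE)
  unit_scale <- 1e-9  # default Hz -> GHz
  fmt <- "RI"
  if (length(opt) > 0) {
    toks <- toupper(strsplit(trimws(sub("^#", "", opt[1])), "\\s+")[[1]])
    units <- c(HZ = 1e-9, KHZ = 1e-6, MHZ = 1e-3, GHZ = 1)
    u <- intersect(toks, names(units))
    if (length(u) > 0) unit_scale <- units[[u[1]]]
    f <- intersect(toks, c("RI", "MA", "DB"))
    if (length(f) > 0) fmt <- f[1]
  }
  data_lines <- lines[!grepl("^#", lines)]
  vals <- lapply(strsplit(data_lines, "\\s+"), as.numeric)
  vals <- do.call(rbind, vals)
  if (ncol(vals) < 3) stop("malformed .s1p data: need 3 columns")
  freq <- vals[, 1] * unit_scale
  s11 <- switch(fmt,
    RI = complex(real = vals[, 2], imaginary = vals[, 3]),
    MA = vals[, 2] * exp(1i * vals[, 3] * pi / 180),
    DB = 10^(vals[, 2] / 20) * exp(1i * vals[, 3] * pi / 180)
  )
  list(freq_ghz = freq, s11 = s11)
}

#' Write a sweep set as one .s1p per antenna
#'
#' Produces `<prefix>_ant<m>.s1p` for each antenna plus a JSON sidecar
#' `<prefix>_meta.json` with the acquisition label, seed and sweep spec.
#'
#' @param set A `sweep_set`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default the acquisition label).
#' @return Character vector of written `.s1p` paths.
#' @export
write_sweep_set <- function(set, dir, prefix = set$label) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- frequencies(set$spec)
  paths <- vapply(seq_len(nrow(set$s11)), function(m) {
    p <- file.path(dir, sprintf("%s_ant%02d.s1p", prefix, m))
    write_touchstone(p, f, set$s11[m, ],
                     comment = sprintf("antenna %d, %s acquisition",
                                       m, set$label))
    p
  }, character(1))
  meta <- list(label = set$label, seed = set$seed,
               spec = unclass(set$spec), n_antennas = nrow(set$s11))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE)
  paths
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix (`"empty"` or `"loaded"`).
#' @return A `sweep_set`.
#' @export
read_sweep_set <- function(dir, prefix) {
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spec <- sweep_spec(meta$spec$f_start, meta$spec$f_stop, meta$spec$n_points,
                     meta$spec$source_power_dbm)
  files <- file.path(dir, sprintf("%s_ant%02d.s1p", prefix,
                                  seq_len(meta$n_antennas)))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) stop("missing sweep file(s): ", missing[1])
  s11 <- t(vapply(files, function(p) read_touchstone(p)$s11,
                  complex(spec$n_points)))
  dimnames(s11) <- NULL
  sweep_set(spec, s11, meta$label,
            if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
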