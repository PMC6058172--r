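#' Read an observation table from delimited text
#'
#' Accepts comma- or tab-delimited text with a header row and the columns
#' `label`, `period`, `tfr`, `srb` (extra columns such as `phi_true` are kept).
#' Leading `# key: value` lines carry table metadata; the SRB unit declaration
#' is mandatory — either a `# srb_unit: b100g` / `# srb_unit: prop` metadata
#' line or the `srb_unit` argument (the argument wins). Values in proportion-
#' male units are converted to boys per 100 girls on load
#' (`100 m/(1 - m)`); no auto-detection is attempted, since a 1.06-vs-106
#' confusion would silently corrupt every downstream estimate.
#'
#' Rows failing validation (non-numeric `tfr`/`srb`, `tfr <= 0`, `srb` out of
#' unit range) are reported with their file line numbers and reading stops;
#' rows are never silently dropped.
#'
#' @param path File to read.
#' @param srb_unit `"b100g"` (boys per 100 girls) or `"prop"` (proportion of
#'   births male); overrides any metadata declaration.
#' @return An `observation_table` data.frame with attributes `srb_unit`
#'   (always `"b100g"` after conversion), `p` (benchmark declared in the
#'   file, if any) and `source`.
#' @export
read_observations <- function(path, srb_unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  # metadata must be a leading block
  body_start <- if (any(!is_meta)) which(!is_meta)[1L] else length(lines) + 1L
  meta_lines <- lines[seq_len(body_start - 1L)]
  meta <- parse_meta(meta_lines)

  unit <- srb_unit %||% meta$srb_unit
  if (is.null(unit))
    stop("SRB unit not declared: add a '# srb_unit: b100g|prop' line ",
         "or pass `srb_unit`", call. = FALSE)
  if (!unit %in% c("b100g", "prop"))
    stop("unknown srb_unit '", unit, "' (expected 'b100g' or 'prop')",
         call. = FALSE)

  body <- lines[body_start:length(lines)]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- utils::read.csv(text = paste(body, collapse = "\n"), sep = sep,
                        colClasses = "character", check.names = TRUE)
  need <- c("label", "period", "tfr", "srb")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  # file line number of each data row (header is body_start)
  file_line <- body_start + seq_len(nrow(df))
  errors <- character(0)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      errors <<- c(errors, sprintf("line %d: non-numeric %s '%s'",
                                   file_line[bad], col, df[[col]][bad]))
    v
  }
  tfr <- num("tfr"); srb <- num("srb")
  bad_tfr <- which(!is.na(tfr) & tfr <= 0)
  if (length(bad_tfr))
    errors <- c(errors, sprintf("line %d: tfr must be > 0 (got %s)",
                                file_line[bad_tfr], df$tfr[bad_tfr]))
  bad_srb <- which(!is.na(srb) &
                     (srb <= 0 | (unit == "prop" & srb >= 1)))
  if (length(bad_srb))
    errors <- c(errors, sprintf("line %d: srb out of range for unit '%s' (got %s)",
                                file_line[bad_srb], unit, df$srb[bad_srb]))
  if (length(errors))
    stop("invalid observation table ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)

  if (unit == "prop") srb <- 100 * srb / (1 - srb)
  out <- data.frame(label = df$label, period = df$period,
                    tfr = tfr, srb = srb)
  for (extra in setdiff(names(df), need)) {
    v <- suppressWarnings(as.numeric(df[[extra]]))
    out[[extra]] <- if (all(is.na(v) == is.na(df[[extra]]) |
                              df[[extra]] %in% c("NA", ""))) v else df[[extra]]
  }
  p_meta <- if (!is.null(meta$p)) as.numeric(meta$p) else NULL
  structure(out, class = c("observation_table", "data.frame"),
            srb_unit = "b100g", p = p_meta, source = meta$source)
}

#' Write an observation or propensity table to delimited text
#'
#' Writes a CSV (or TSV) with a leading `# key: value` metadata block: the
#' SRB unit (always `b100g` on output), the benchmark `p` used — so estimates
#' computed under different benchmarks are never merged unknowingly — and a
#' source note. Numeric fields are written with 17 significant digits, so a
#' write-then-read round trip is lossless.
#'
#' @param x An `observation_table`, `propensity_table`, or compatible
#'   data.frame.
#' @param path Output file.
#' @param sep `","` (default) or `"\t"`.
#' @param p Benchmark female-birth propensity to record; defaults to the
#'   table's own attribute when present.
#' @param source Free-text provenance note.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path, sep = ",", p = attr(x, "p"),
                               source = attr(x, "source")) {
  df <- as.data.frame(x)
  meta <- c("# srb_unit: b100g",
            if (!is.null(p)) sprintf("# p: %.17g", p),
            if (!is.null(source)) paste0("# source: ", source))
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- sprintf("%.17g", df[[col]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2L]]] <- trimws(m[3L])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
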