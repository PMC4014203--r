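#' Write / read a planar dose in the plain-text exchange format
#'
#' A self-describing ASCII format for 2D ion-chamber-array exports and
#' extracted planes: `#`-prefixed `key: value` header lines (`rows`, `cols`,
#' `pitch_mm`, `origin_mm`, `gantry_deg`, `units`) followed by `rows` lines
#' of `cols` whitespace-separated values each — line i holding
#' `values[i, ]`. Inactive elements are written as the sentinel token `*`.
#' Values are written with 9 significant digits, so a write/read round trip
#' reproduces the plane to that precision.
#'
#' @param plane a [planar_dose()].
#' @param file path to write / read.
#' @return `read_planar_ascii` returns a [planar_dose()];
#'   `write_planar_ascii` returns `file` invisibly.
#' @export
write_planar_ascii <- function(plane, file) {
  stopifnot(inherits(plane, "planar_dose"))
  d <- dim(plane$values)
  hdr <- c("# planar dose v1",
           sprintf("# rows: %d", d[1]),
           sprintf("# cols: %d", d[2]),
           sprintf("# pitch_mm: %.9g %.9g", plane$pitch[1], plane$pitch[2]),
           sprintf("# origin_mm: %.9g %.9g", plane$origin[1], plane$origin[2]),
           sprintf("# gantry_deg: %s",
                   if (is.na(plane$gantry_angle)) "NA"
                   else sprintf("%.9g", plane$gantry_angle)),
           "# units: cGy")
  body <- vapply(seq_len(d[1]), function(i) {
    row <- sprintf("%.9g", plane$values[i, ])
    row[!plane$active[i, ]] <- "*"
    paste(row, collapse = " ")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_planar_ascii
#' @export
read_planar_ascii <- function(file) {
  lines <- readLines(file)
  hdr <- parse_ascii_header(lines, file)
  need <- c("rows", "cols", "pitch_mm", "origin_mm")
  miss <- setdiff(need, names(hdr$fields))
  if (length(miss))
    stop(sprintf("%s: missing header field(s): %s", file,
                 paste(miss, collapse = ", ")))
  nr <- as.integer(hdr$fields$rows)
  nc <- as.integer(hdr$fields$cols)
  pitch <- as.double(strsplit(trimws(hdr$fields$pitch_mm), "\\s+")[[1]])
  origin <- as.double(strsplit(trimws(hdr$fields$origin_mm), "\\s+")[[1]])
  ga <- hdr$fields$gantry_deg
  ga <- if (is.null(ga) || trimws(ga) == "NA") NA_real_ else as.double(ga)
  body <- hdr$body
  if (length(body) != nr)
    stop(sprintf("%s: expected %d data rows, found %d", file, nr, length(body)))
  vals <- matrix(0, nr, nc)
  active <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) != nc)
      stop(sprintf("%s: row %d has %d values, expected %d (line %d)",
                   file, i, length(tok), nc, hdr$body_start + i - 1L))
    star <- tok == "*"
    active[i, ] <- !star
    tok[star] <- "0"
    vals[i, ] <- as.double(tok)
  }
  planar_dose(vals, pitch, origin, active, ga)
}

# Split `#`-prefixed "key: value" header lines from the data body.
parse_ascii_header <- function(lines, file) {
  ish <- grepl("^#", lines)
  nhdr <- match(FALSE, ish, nomatch = length(lines) + 1L) - 1L
  fields <- list()
  for (ln in lines[seq_len(nhdr)]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) fields[[m[2]]] <- m[3]
  }
  body <- lines[seq.int(nhdr + 1L, length.out = length(lines) - nhdr)]
  body <- body[nzchar(trimws(body))]
  list(fields = fields, body = body, body_start = nhdr + 1L)
}

#' Write / read a 3D dose grid in the plain-text exchange format
#'
#' Header lines (`dim`, `spacing_mm`, `origin_mm`, `frame`, `units`) followed
#' by the voxel values slice by slice: for each z index a `# slice k` marker
#' and then `ny` lines of `nx` values (line j of a slice holding
#' `values[, j, k]`). Structure masks use the same format with 0/1 values
#' and `units: mask`.
#'
#' @param dose a [dose_grid()].
#' @param file path to write / read.
#' @param units unit label written to the header.
#' @return `read_dose_ascii` returns a [dose_grid()]; the writer returns
#'   `file` invisibly.
#' @export
write_dose_ascii <- function(dose, file, units = "cGy") {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$values)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# dose grid v1",
               sprintf("# dim: %d %d %d", d[1], d[2], d[3]),
               sprintf("# spacing_mm: %.9g %.9g %.9g",
                       dose$spacing[1], dose$spacing[2], dose$spacing[3]),
               sprintf("# origin_mm: %.9g %.9g %.9g",
                       dose$origin[1], dose$origin[2], dose$origin[3]),
               sprintf("# frame: %s", dose$frame),
               sprintf("# units: %s", units)), con)
  for (k in seq_len(d[3])) {
    writeLines(sprintf("# slice: %d", k), con)
    sl <- dose$values[, , k, drop = FALSE]
    rows <- vapply(seq_len(d[2]), function(j)
      paste(sprintf("%.9g", sl[, j, 1]), collapse = " "), character(1))
    writeLines(rows, con)
  }
  invisible(file)
}

#' @rdname write_dose_ascii
#' @export
read_dose_ascii <- function(file) {
  lines <- readLines(file)
  get_field <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (!length(m)) stop(sprintf("%s: missing header field \"%s\"", file, key))
    sub(sprintf("^#\\s*%s:\\s*", key), "", m[1])
  }
  d <- as.integer(strsplit(trimws(get_field("dim")), "\\s+")[[1]])
  spacing <- as.double(strsplit(trimws(get_field("spacing_mm")), "\\s+")[[1]])
  origin <- as.double(strsplit(trimws(get_field("origin_mm")), "\\s+")[[1]])
  frame <- get_field("frame")
  data <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(data) != d[2] * d[3])
    stop(sprintf("%s: expected %d data rows, found %d",
                 file, d[2] * d[3], length(data)))
  vals <- array(0, d)
  r <- 1L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    tok <- strsplit(trimws(data[r]), "\\s+")[[1]]
    if (length(tok) != d[1])
      stop(sprintf("%s: slice %d row %d has %d values, expected %d",
                   file, k, j, length(tok), d[1]))
    vals[, j, k] <- as.double(tok)
    r <- r + 1L
  }
  dose_grid(vals, spacing, origin, frame)
}

#' Write / read an angular correction table as CSV
#'
#' Two-column CSV (`angle_deg`, `factor`) preceded by `#`-prefixed metadata
#' header lines carrying at least the SAD; further metadata entries round
#' trip as strings.
#'
#' @param table a [correction_table()].
#' @param file path to write / read.
#' @return `read_correction_csv` returns a [correction_table()]; the writer
#'   returns `file` invisibly.
#' @export
write_correction_csv <- function(table, file) {
  stopifnot(inherits(table, "correction_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# SAD_mm: %.9g", table$SAD), con)
  for (nm in names(table$meta))
    writeLines(sprintf("# %s: %s", nm, table$meta[[nm]]), con)
  writeLines("angle_deg,factor", con)
  writeLines(sprintf("%.9g,%.12g", table$angles, table$factors), con)
  invisible(file)
}

#' @rdname write_correction_csv
#' @export
read_correction_csv <- function(file) {
  lines <- readLines(file)
  ish <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[ish]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  SAD <- if (!is.null(meta$SAD_mm)) as.double(meta$SAD_mm) else 1000
  meta$SAD_mm <- NULL
  df <- utils::read.csv(textConnection(lines[!ish]))
  if (!all(c("angle_deg", "factor") %in% names(df)))
    stop(sprintf("%s: expected columns angle_deg, factor", file))
  correction_table(df$angle_deg, df$factor, SAD = SAD, meta = meta)
}
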