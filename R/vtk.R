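# Legacy ASCII VTK structured-points writer and reader.
#
# The dialect is fixed: "# vtk DataFile Version 3.0", a title line,
# ASCII, DATASET STRUCTURED_POINTS, DIMENSIONS/SPACING/ORIGIN,
# POINT_DATA n, SCALARS <name> unsigned_char 1, LOOKUP_TABLE default,
# then scalars with x varying fastest, then y, then z. ASCII (not
# binary) keeps the files diffable and byte-stable across runs.

.default_value_map <- function() c(background = 0L, negative = 100L, positive = 200L)

.fmt_num <- function(x) {
  # %.15g round-trips doubles of practical precision and is locale-stable
  vapply(x, function(v) sprintf("%.15g", v), character(1))
}

#' Write a label volume as a legacy VTK structured-points file
#'
#' Each voxel class is mapped to an 8-bit scalar through `value_map`
#' (default: background 0, negative 100, positive 200 — classes
#' separated by ~100 intensity so they are distinguishable in any
#' default transfer function). Scalars are emitted with x varying
#' fastest, then y, then z; output is byte-identical across repeated
#' runs on the same input.
#'
#' @param volume a [label_volume()].
#' @param value_map named integer vector with entries `background`,
#'   `negative`, `positive`, each in `[0, 255]`.
#' @param path output file path.
#' @param title title line written into the file header (single line).
#' @param scalar_name name of the SCALARS attribute.
#' @return `path`, invisibly.
#' @export
write_vtk_structured_points <- function(volume,
                                        value_map = NULL,
                                        path,
                                        title = "histovol label volume",
                                        scalar_name = "labels") {
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(value_map)) value_map <- .default_value_map()
  req <- c("background", "negative", "positive")
  if (!all(req %in% names(value_map))) {
    stop("value_map must define: background, negative, positive", call. = FALSE)
  }
  vm <- as.integer(value_map[req])
  if (anyNA(vm) || any(vm < 0) || any(vm > 255)) {
    stop("value_map values must be 8-bit integers in [0, 255]", call. = FALSE)
  }
  meta <- volume$meta
  d <- meta$dims
  # labels array is (ny, nx, nz); VTK wants x fastest -> permute to (nx, ny, nz)
  scalars <- vm[as.vector(aperm(volume$labels, c(2, 1, 3))) + 1L]
  n <- prod(d)
  header <- c(
    "# vtk DataFile Version 3.0",
    gsub("[\r\n]", " ", title),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("SPACING", paste(.fmt_num(meta$spacing), collapse = " ")),
    paste("ORIGIN", paste(.fmt_num(meta$origin), collapse = " ")),
    paste("POINT_DATA", n),
    paste("SCALARS", scalar_name, "unsigned_char 1"),
    "LOOKUP_TABLE default"
  )
  # 20 scalars per line keeps files readable without bloating line count
  per_line <- 20L
  idx <- ceiling(seq_along(scalars) / per_line)
  body <- vapply(split(scalars, idx), paste, character(1), collapse = " ")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, unname(body)), con, sep = "\n")
  invisible(path)
}

#' Read a legacy VTK structured-points file
#'
#' Parses exactly the dialect produced by
#' [write_vtk_structured_points()]: legacy ASCII header, unsigned_char
#' scalars with the default lookup table, x varying fastest. Any other
#' dataset type, data encoding or extra attribute is rejected with a
#' message citing the offending line.
#'
#' @param path file path.
#' @return List with `scalars` — an `(ny, nx, nz)` integer array in the
#'   package's image layout — and `meta`, a [volume_meta()].
#' @export
read_vtk_structured_points <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("VTK file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  bad <- function(i, why) {
    stop(sprintf("VTK parse error at line %d ('%s'): %s", i,
                 if (i <= length(lines)) lines[i] else "<eof>", why),
         call. = FALSE)
  }
  if (length(lines) < 10) stop("VTK file too short for a structured-points header",
                               call. = FALSE)
  if (!startsWith(lines[1], "# vtk DataFile Version")) {
    bad(1, "expected '# vtk DataFile Version ...'")
  }
  if (trimws(lines[3]) != "ASCII") bad(3, "only ASCII encoding is supported")
  if (trimws(lines[4]) != "DATASET STRUCTURED_POINTS") {
    bad(4, "only DATASET STRUCTURED_POINTS is supported")
  }
  parse_triple <- function(i, key, integer = FALSE) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 4 || parts[1] != key) {
      bad(i, sprintf("expected '%s <a> <b> <c>'", key))
    }
    v <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(v)) bad(i, "non-numeric values")
    if (integer) as.integer(v) else v
  }
  dims <- parse_triple(5, "DIMENSIONS", integer = TRUE)
  spacing <- parse_triple(6, "SPACING")
  origin <- parse_triple(7, "ORIGIN")
  pd <- strsplit(trimws(lines[8]), "[[:space:]]+")[[1]]
  if (length(pd) != 2 || pd[1] != "POINT_DATA") bad(8, "expected 'POINT_DATA <n>'")
  n <- as.numeric(pd[2])
  if (is.na(n) || n != prod(dims)) {
    bad(8, sprintf("POINT_DATA count %s does not equal nx*ny*nz = %d",
                   pd[2], prod(dims)))
  }
  sc <- strsplit(trimws(lines[9]), "[[:space:]]+")[[1]]
  if (length(sc) != 4 || sc[1] != "SCALARS" || sc[3] != "unsigned_char" ||
      sc[4] != "1") {
    bad(9, "expected 'SCALARS <name> unsigned_char 1'")
  }
  if (trimws(lines[10]) != "LOOKUP_TABLE default") {
    bad(10, "expected 'LOOKUP_TABLE default'")
  }
  body <- lines[-(1:10)]
  vals <- suppressWarnings(as.integer(strsplit(paste(body, collapse = " "),
                                               "[[:space:]]+")[[1]]))
  vals <- vals[!is.na(vals)]
  if (any(grepl("[^0-9[:space:]]", body))) {
    stop("VTK parse error: non-numeric content in scalar section", call. = FALSE)
  }
  if (length(vals) != n) {
    stop(sprintf("VTK parse error: %d scalars found, POINT_DATA declares %d",
                 length(vals), n), call. = FALSE)
  }
  if (min(vals) < 0 || max(vals) > 255) {
    stop("VTK parse error: unsigned_char scalar out of [0, 255]", call. = FALSE)
  }
  # x fastest -> fill (nx, ny, nz) then permute back to image layout
  grid <- aperm(array(vals, dim = dims), c(2, 1, 3))
  list(scalars = grid,
       meta = volume_meta(dims, spacing = spacing, origin = origin))
}
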