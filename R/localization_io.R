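#' Construct a localization table
#'
#' A localization table holds one SMLM acquisition: one row per
#' localization with its acquisition frame, coordinates in nanometres and,
#' optionally, a per-localization precision (the fitted position
#' uncertainty, also in nm). Tables are plain data frames of class
#' `"loc_table"`; the dimensionality (2 or 3) is determined by the presence
#' of a `z` column.
#'
#' @param frame integer vector of 1-based acquisition frame indices.
#' @param x,y numeric coordinates in nm.
#' @param z optional numeric axial coordinates in nm (makes the table 3D).
#' @param precision optional per-localization precision in nm (> 0).
#' @return A `data.frame` of class `"loc_table"` with columns `frame`, `x`,
#'   `y` and optionally `z`, `precision`.
#' @examples
#' tab <- loc_table(frame = c(1, 1, 2), x = c(0, 100, 25), y = c(0, 0, 25))
#' loc_dim(tab)
#' @export
loc_table <- function(frame, x, y, z = NULL, precision = NULL) {
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y))
  if (!is.null(z)) df$z <- as.numeric(z)
  if (!is.null(precision)) df$precision <- as.numeric(precision)
  class(df) <- c("loc_table", "data.frame")
  validate_loc_table(df)
  df
}

#' @rdname loc_table
#' @param table object to validate / query.
#' @export
validate_loc_table <- function(table) {
  stopifnot(is.data.frame(table))
  req <- c("frame", "x", "y")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "))
  coords <- loc_coords(table)
  bad <- which(!apply(is.finite(coords), 1, all))
  if (length(bad) > 0)
    stop("non-finite coordinate at row ", bad[1])
  if (nrow(table) > 0 && any(table$frame < 1))
    stop("frame indices must be >= 1 (row ",
         which(table$frame < 1)[1], ")")
  if (!is.null(table$precision) && nrow(table) > 0 &&
      any(!is.finite(table$precision) | table$precision <= 0))
    stop("precision must be finite and > 0 for every record (row ",
         which(!is.finite(table$precision) | table$precision <= 0)[1], ")")
  invisible(table)
}

#' @rdname loc_table
#' @export
loc_dim <- function(table) if ("z" %in% names(table)) 3L else 2L

#' Extract the coordinate matrix of a localization table
#'
#' @param table a [loc_table()] (or a bare numeric matrix, returned as-is).
#' @return numeric matrix with columns x, y and (for 3D tables) z.
#' @export
loc_coords <- function(table) {
  if (is.matrix(table)) return(table)
  cols <- c("x", "y", if ("z" %in% names(table)) "z")
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

# canonical CSV headers (ThunderSTORM-compatible dialect)
.canonical_cols <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                     z = "z [nm]", precision = "uncertainty [nm]")

#' Read a localization table from CSV
#'
#' Reads a comma-separated localization table as emitted by common SMLM
#' fitting software. The canonical dialect has a header row with columns
#' `frame`, `x [nm]`, `y [nm]` and optionally `z [nm]`, `uncertainty [nm]`;
#' `column_map` binds other header names to these fields, and `unit_scale`
#' converts coordinate units to nm (e.g. 1000 for tables in micrometres).
#' Rows are never silently dropped: a malformed row raises an error naming
#' it.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector or list mapping fields
#'   (`frame`, `x`, `y`, `z`, `precision`) to header names in the file.
#' @param unit_scale multiplicative factor converting file coordinate (and
#'   precision) units to nm; must be > 0.
#' @return A [loc_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_localizations(loc_table(1:2, c(0, 25), c(0, 25)), f)
#' read_localizations(f)
#' @export
read_localizations <- function(path, column_map = NULL, unit_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.numeric(unit_scale), unit_scale > 0)
  cmap <- .canonical_cols
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown) > 0)
      stop("column_map refers to unknown field(s): ",
           paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  raw <- read.csv(path, check.names = FALSE)
  get_col <- function(field, required) {
    nm <- cmap[[field]]
    if (!nm %in% names(raw)) {
      if (required) stop("missing mapped column '", nm, "' for field '",
                         field, "' in ", path)
      return(NULL)
    }
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]))
    if (length(bad) > 0)
      stop("unparseable value in column '", nm, "' at row ", bad[1])
    v
  }
  frame <- get_col("frame", TRUE)
  x <- get_col("x", TRUE) * unit_scale
  y <- get_col("y", TRUE) * unit_scale
  z <- get_col("z", FALSE)
  if (!is.null(z)) z <- z * unit_scale
  prec <- get_col("precision", FALSE)
  if (!is.null(prec)) prec <- prec * unit_scale
  loc_table(frame, x, y, z = z, precision = prec)
}

#' Write a localization table to CSV
#'
#' Writes the canonical comma-separated dialect (`frame`, `x [nm]`,
#' `y [nm]`, and `z [nm]` / `uncertainty [nm]` when present) at full float
#' precision, so that [read_localizations()] round-trips the table exactly.
#'
#' @param table a [loc_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  validate_loc_table(table)
  fields <- c("frame", "x", "y",
              if ("z" %in% names(table)) "z",
              if ("precision" %in% names(table)) "precision")
  out <- data.frame(frame = as.integer(table$frame))
  for (f in setdiff(fields, "frame"))
    out[[f]] <- sprintf("%.17g", table[[f]])
  names(out) <- .canonical_cols[fields]
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write localizations to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %dD, frames %s\n",
              nrow(x), loc_dim(x),
              if (nrow(x) > 0) paste(range(x$frame), collapse = "-") else "-"))
  if (nrow(x) > 0) print(head(as.data.frame(x), 4))
  invisible(x)
}
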