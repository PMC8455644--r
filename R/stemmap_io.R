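## Delimited-text I/O for stem tables, plot metadata and result tables.
## CSV vs TSV is auto-detected from the file extension; column names of
## external deposits are adapted via a user-supplied mapping (list or
## YAML file) rather than hard-coded.

FOREST_TYPES <- c("EB", "DB", "BC", "EC")
SUCCESSION_STAGES <- c("OG", "OS", "S")

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_file <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE,
           check.names = FALSE)
}

apply_mapping <- function(df, mapping) {
  if (is.null(mapping)) return(df)
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- yaml::read_yaml(mapping)
  for (std in names(mapping)) {
    src <- mapping[[std]]
    if (src %in% names(df)) names(df)[names(df) == src] <- std
  }
  df
}

#' Read and validate a stem table
#'
#' Reads a delimited stem map (one row per tree) and validates every row.
#' Required columns: `plot_id`, `species`, `x`, `y` and at least one of
#' `gbh` / `dbh` (cm).  Invalid rows are never dropped silently: they are
#' collected, with line numbers and reasons, in the `"rejected"` attribute
#' of the returned data frame, and a summary message is emitted.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param mapping optional named list (or path to a YAML file) mapping the
#'   standard column names to the file's column names, e.g.
#'   `list(species = "spcode")`.
#' @param plots optional plot metadata (from [read_plot_metadata()]); when
#'   supplied, coordinates are checked against each plot's dimensions.
#' @return data.frame of accepted stems with attributes `"rejected"`
#'   (data.frame: line, reason) and `"n_total"`.
#' @export
read_stem_table <- function(path, mapping = NULL, plots = NULL) {
  df <- apply_mapping(read_delim_file(path), mapping)
  required <- c("plot_id", "species", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (!("gbh" %in% names(df)) && !("dbh" %in% names(df)))
    missing_cols <- c(missing_cols, "gbh/dbh")
  if (length(missing_cols))
    abort_invalid("stem table is missing required column(s): ",
                  paste(missing_cols, collapse = ", "))
  if (!("gbh" %in% names(df))) df$gbh <- NA_real_
  if (!("dbh" %in% names(df))) df$dbh <- NA_real_
  for (cc in c("x", "y", "gbh", "dbh"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))

  reason <- rep(NA_character_, nrow(df))
  bad_num <- !is.finite(df$x) | !is.finite(df$y)
  reason[bad_num] <- "unparseable or missing coordinate"
  no_size <- is.na(reason) & !is.finite(df$gbh) & !is.finite(df$dbh)
  reason[no_size] <- "neither gbh nor dbh present"
  bad_size <- is.na(reason) &
    ((is.finite(df$gbh) & df$gbh <= 0) | (is.finite(df$dbh) & df$dbh <= 0))
  reason[bad_size] <- "non-positive size"
  if (!is.null(plots)) {
    wmap <- setNames(plots$width, plots$plot_id)
    hmap <- setNames(plots$height, plots$plot_id)
    w <- wmap[df$plot_id]; h <- hmap[df$plot_id]
    unknown <- is.na(reason) & is.na(w)
    reason[unknown] <- "unknown plot_id"
    outside <- is.na(reason) &
      (df$x < 0 | df$y < 0 | df$x > w | df$y > h)
    reason[outside] <- "coordinate outside plot"
  } else {
    outside <- is.na(reason) & (df$x < 0 | df$y < 0)
    reason[outside] <- "coordinate outside plot"
  }

  keep <- is.na(reason)
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header
                         reason = reason[!keep], stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(rejected))
    message(nrow(rejected), " of ", nrow(df),
            " stem rows rejected (see attr(x, 'rejected'))")
  structure(out, rejected = rejected, n_total = nrow(df))
}

#' Read and validate plot metadata
#'
#' Required columns: `plot_id`, `width`, `height`, `altitude`,
#' `temperature`, `precipitation`, `snow_depth`, `forest_type`
#' (EB/DB/BC/EC) and `succession` (OG/OS/S).  Any invalid row raises a
#' validation error (plot metadata is small and must be fully correct).
#'
#' @inheritParams read_stem_table
#' @return validated data.frame of plot metadata.
#' @export
read_plot_metadata <- function(path, mapping = NULL) {
  df <- apply_mapping(read_delim_file(path), mapping)
  required <- c("plot_id", "width", "height", "altitude", "temperature",
                "precipitation", "snow_depth", "forest_type", "succession")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_invalid("plot metadata is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  num <- c("width", "height", "altitude", "temperature", "precipitation",
           "snow_depth")
  for (cc in num) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (any(!is.finite(df$width) | !is.finite(df$height) |
          df$width <= 0 | df$height <= 0))
    abort_invalid("plot dimensions must be positive")
  if (any(!is.finite(df$snow_depth) | df$snow_depth < 0))
    abort_invalid("snow_depth must be >= 0")
  if (any(!df$forest_type %in% FOREST_TYPES))
    abort_invalid("forest_type must be one of ",
                  paste(FOREST_TYPES, collapse = "/"))
  if (any(!df$succession %in% SUCCESSION_STAGES))
    abort_invalid("succession must be one of ",
                  paste(SUCCESSION_STAGES, collapse = "/"))
  if (anyDuplicated(df$plot_id))
    abort_invalid("duplicated plot_id in metadata")
  df
}

#' Write a result table as delimited text
#'
#' Writes any of the package's tables (stems, plot metadata, fits,
#' summaries) as CSV or TSV (chosen by extension) with a header row.
#' Floating-point columns keep 15 significant digits so that a read-back
#' reproduces the values at test tolerance.
#'
#' @param records data.frame to write.
#' @param path output path (`.csv`, `.tsv` or `.txt`).
#' @param allow_empty write an empty table instead of erroring.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) abort_invalid("records must be a data.frame")
  if (nrow(records) == 0 && !allow_empty)
    abort_invalid("refusing to write an empty table ",
                  "(set allow_empty = TRUE to override)")
  rec <- records
  for (cc in names(rec)) {
    if (is.double(rec[[cc]]))
      rec[[cc]] <- formatC(rec[[cc]], digits = 15, format = "g")
  }
  ok <- tryCatch({
    write.table(rec, path, sep = delim_for(path), row.names = FALSE,
                quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_invalid("cannot write ", path, ": ",
                                 conditionMessage(ok))
  invisible(path)
}

#' Read back a generic result table
#'
#' Companion to [write_table()]; no validation beyond parsing.
#' @param path path written by [write_table()].
#' @return data.frame.
#' @export
read_table_file <- function(path) {
  read_delim_file(path)
}
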