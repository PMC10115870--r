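#' Stimulation tables
#'
#' One row per stimulation event: a subject identifier, an MNI world
#' coordinate in mm, and one binary outcome flag per behavioural category.
#' Because each locus is probed with several tasks, more than one behaviour
#' flag may be set on a single row (the classification is not exclusive).
#'
#' @name stim_io
NULL

STIM_COORD_COLS <- c("x_mm", "y_mm", "z_mm")

#' Read a stimulation table
#'
#' @param path delimited text file (TSV or CSV, sniffed from the header line)
#'   with header columns `subject_id`, `x_mm`, `y_mm`, `z_mm` and one
#'   `{0,1}`-valued column per behaviour.
#' @param behaviours optional character vector naming the behaviour columns;
#'   by default every column beyond the four required ones.
#' @return a `data.frame` of class `stim_table` with attribute `behaviours`.
#' @export
read_stimulation_table <- function(path, behaviours = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", STIM_COORD_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("stimulation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(behaviours)) behaviours <- setdiff(names(df), required)
  if (!length(behaviours))
    stop("stimulation table has no behaviour columns", call. = FALSE)
  miss_b <- setdiff(behaviours, names(df))
  if (length(miss_b))
    stop("stimulation table is missing behaviour column(s): ",
         paste(miss_b, collapse = ", "), call. = FALSE)

  for (col in STIM_COORD_COLS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric coordinate in column '%s' at row %d", col,
                   bad[1]), call. = FALSE)
    df[[col]] <- v
  }
  for (col in behaviours) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("behaviour flag outside {0,1} in column '%s' at row %d",
                   col, bad[1]), call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  df$subject_id <- as.character(df$subject_id)
  as_stim_table(df, behaviours)
}

#' Construct a stimulation table from a data frame
#' @param df data frame with the required columns.
#' @param behaviours behaviour column names.
#' @return a `stim_table`.
#' @export
as_stim_table <- function(df, behaviours) {
  stopifnot(all(c("subject_id", STIM_COORD_COLS, behaviours) %in% names(df)))
  structure(df, behaviours = behaviours,
            class = c("stim_table", "data.frame"))
}

#' Write a stimulation table as TSV
#' @param records a `stim_table`.
#' @param path destination path.
#' @export
write_stimulation_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Behaviour column names of a stimulation table
#' @param records a `stim_table`.
#' @return character vector of behaviour names.
#' @export
stim_behaviours <- function(records) attr(records, "behaviours")

#' World coordinates of a stimulation table
#' @param records a `stim_table`.
#' @return n x 3 matrix of MNI mm coordinates.
#' @export
stim_coords <- function(records)
  as.matrix(as.data.frame(records)[, STIM_COORD_COLS])
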