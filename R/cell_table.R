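# Cell tables and intensity matrices: the pipeline's universal substrate.
# A cell table is a data.frame with reserved columns cell_id, region, x, y;
# every other numeric column is a marker channel.

RESERVED_COLUMNS <- c("cell_id", "region", "x", "y")

#' Construct a cell table
#'
#' @param cell_id unique cell identifiers.
#' @param region tissue region id per cell (windows and spillover never cross
#'   regions).
#' @param x,y spatial coordinates in arbitrary tissue units.
#' @param intensities numeric matrix or data.frame, one column per marker.
#' @return a `cell_table` (data.frame subclass).
#' @export
cell_table <- function(cell_id, region, x, y, intensities) {
  intensities <- as.data.frame(intensities)
  stop_if_not(!anyDuplicated(cell_id), "duplicate cell_id")
  stop_if_not(nrow(intensities) == length(cell_id),
              "intensity rows must match cell count")
  stop_if_not(!any(names(intensities) %in% RESERVED_COLUMNS),
              "marker names collide with reserved columns")
  tab <- data.frame(cell_id = cell_id, region = region, x = x, y = y,
                    intensities, check.names = FALSE)
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Marker column names of a cell table
#' @param table a `cell_table`.
#' @return character vector of marker names.
#' @export
marker_names <- function(table) {
  setdiff(names(table), RESERVED_COLUMNS)
}

#' Extract the cells-by-markers intensity matrix
#'
#' @param table a `cell_table`.
#' @param treatment tag recording which treatment produced the values
#'   ("raw" for untransformed data).
#' @return an `intensity_matrix`: numeric matrix with cell ids as rownames,
#'   marker names as colnames and a `treatment` attribute.
#' @export
intensity_matrix <- function(table, treatment = "raw") {
  mk <- marker_names(table)
  m <- as.matrix(table[, mk, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table$cell_id)
  attr(m, "treatment") <- treatment
  class(m) <- c("intensity_matrix", class(m))
  m
}

#' Which treatment produced an intensity matrix
#' @param m an `intensity_matrix`.
#' @return treatment name string.
#' @export
treatment_of <- function(m) {
  t <- attr(m, "treatment")
  if (is.null(t)) "raw" else t
}

#' Read a cell table from CSV/TSV
#'
#' Requires columns cell_id, region, x, y; all remaining numeric columns are
#' auto-detected as markers. Column order is irrelevant.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(RESERVED_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in ", path, call. = FALSE)
  mk <- setdiff(names(df), RESERVED_COLUMNS)
  for (col in mk) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric marker value in column '", col, "' at row ", bad,
           call. = FALSE)
    }
  }
  cell_table(df$cell_id, df$region, df$x, df$y, df[, mk, drop = FALSE])
}

#' Write a cell table to CSV
#' @param table a `cell_table`.
#' @param path output file.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Replace the marker intensities of a cell table
#' @param table a `cell_table`.
#' @param m matrix with identical shape and marker order.
#' @return updated `cell_table`.
#' @keywords internal
set_intensities <- function(table, m) {
  mk <- marker_names(table)
  stop_if_not(identical(colnames(m), mk), "marker mismatch")
  table[, mk] <- as.data.frame(unclass(m))[, mk]
  table
}
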