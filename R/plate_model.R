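## Data model and text I/O for dual-reporter screen plates.
##
## A screen dataset is a long tibble with one row per well and the columns
## arm, plate_id, row, col, compound_id, role, nluc, fluc, concentration.
## Coordinates are 0-based internally (row 0-15, col 0-23); text I/O speaks
## the plate-reader convention (row letters A-P, 1-based column numbers).

#' Construct and validate a screen dataset
#'
#' Assembles per-well luminescence measurements for one or both reporter
#' arms into a validated long table. Reporter arm `"V1"` carries the
#' +1 nt frameshift construct (microexon inclusion expresses Firefly
#' luciferase) and `"V2"` the reciprocal −1 nt construct (inclusion
#' expresses NanoLuc), so a genuine splicing modulator moves the two arms'
#' luminescence ratios concordantly while a single-luciferase artifact
#' moves them discordantly.
#'
#' @param wells Data frame with columns `arm` ("V1"/"V2"), `plate_id`,
#'   `row` (integer 0-15), `col` (integer 0-23), `compound_id` (character,
#'   `NA` for controls/empty wells), `role` (one of `"sample"`,
#'   `"neg_control"`, `"pos_control"`, `"empty"`), `nluc`, `fluc`
#'   (non-negative luminescence counts, `NA` for empty wells) and
#'   optionally `concentration` (molar).
#'
#' @return A tibble of class `screen_dataset`.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   arm = "V1", plate_id = "P1", row = 0:1, col = 0L,
#'   compound_id = c("cpdA", NA), role = c("sample", "neg_control"),
#'   nluc = c(100, 120), fluc = c(200, 90)
#' )
#' screen_dataset(wells)
screen_dataset <- function(wells) {
  wells <- as_tibble(wells)
  required <- c("arm", "plate_id", "row", "col", "compound_id", "role",
                "nluc", "fluc")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("screen dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"concentration" %in% names(wells)) wells$concentration <- NA_real_
  wells$arm <- as.character(wells$arm)
  wells$plate_id <- as.character(wells$plate_id)
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$compound_id <- as.character(wells$compound_id)
  wells$role <- normalize_role(wells$role)
  wells$nluc <- as.numeric(wells$nluc)
  wells$fluc <- as.numeric(wells$fluc)
  wells$concentration <- as.numeric(wells$concentration)

  bad_arm <- setdiff(unique(wells$arm), c("V1", "V2"))
  if (length(bad_arm) > 0) {
    abort(paste0("unknown reporter arm(s): ", paste(bad_arm, collapse = ", ")))
  }
  out_of_range <- wells$row < 0L | wells$row >= PLATE_NROW |
    wells$col < 0L | wells$col >= PLATE_NCOL
  if (any(out_of_range, na.rm = TRUE)) {
    abort("well coordinates outside the 16 x 24 plate grid")
  }
  key <- paste(wells$arm, wells$plate_id, wells$row, wells$col, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- wells[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf("duplicate well: arm %s plate %s well %s",
                  dup$arm, dup$plate_id, format_well(dup$row, dup$col)))
  }
  neg_lum <- (wells$nluc < 0 | wells$fluc < 0)
  if (any(neg_lum, na.rm = TRUE)) {
    bad <- wells[which(neg_lum)[1], ]
    abort(sprintf("negative luminescence at plate %s well %s",
                  bad$plate_id, format_well(bad$row, bad$col)))
  }
  if (any(wells$role == "sample" & is.na(wells$compound_id))) {
    abort("sample wells must carry a compound_id")
  }
  wells$nluc[wells$role == "empty"] <- NA_real_
  wells$fluc[wells$role == "empty"] <- NA_real_
  class(wells) <- c("screen_dataset", class(wells))
  wells
}

#' @export
print.screen_dataset <- function(x, ...) {
  n_plates <- nrow(unique(as_tibble(x)[, c("arm", "plate_id")]))
  cat(sprintf("<screen_dataset> %d wells, %d plate(s), arms: %s\n",
              nrow(x), n_plates,
              paste(sort(unique(x$arm)), collapse = ", ")))
  NextMethod()
}

normalize_role <- function(role) {
  role <- tolower(trimws(as.character(role)))
  lookup <- c(
    sample = "sample", cpd = "sample", compound = "sample", trt = "sample",
    neg_control = "neg_control", neg = "neg_control", dmso = "neg_control",
    negative = "neg_control", neg_ctrl = "neg_control",
    pos_control = "pos_control", pos = "pos_control", positive = "pos_control",
    pos_ctrl = "pos_control", tsa = "pos_control", scriptaid = "pos_control",
    empty = "empty", blank = "empty"
  )
  out <- unname(lookup[role])
  if (anyNA(out)) {
    bad <- unique(role[is.na(out)])
    abort(paste0("unknown well role(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Convert between 0-based well indices and plate-reader labels
#'
#' `format_well()` renders 0-based `(row, col)` as the usual "A01" style
#' label; `parse_well_rows()` / `parse_well_cols()` accept either letter /
#' 1-based labels ("B", "3") or 0-based integers and return 0-based
#' integers. Numeric columns are interpreted as 1-based labels whenever the
#' rows of the same table are letters, matching plate-reader exports.
#'
#' @param row,col 0-based integer indices.
#' @return `format_well()`: character labels like "B03".
#' @export
format_well <- function(row, col) {
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

parse_well_rows <- function(row) {
  if (is.numeric(row)) return(as.integer(row))
  row <- trimws(as.character(row))
  if (all(grepl("^[A-Pa-p]$", row))) {
    return(match(toupper(row), LETTERS) - 1L)
  }
  if (all(grepl("^-?[0-9]+$", row))) return(as.integer(row))
  abort("row labels must be letters A-P or 0-based integers")
}

parse_well_cols <- function(col, rows_were_letters) {
  if (is.character(col)) {
    if (!all(grepl("^-?[0-9]+$", trimws(col)))) {
      abort("column labels must be numeric")
    }
    col <- as.integer(trimws(col))
  }
  col <- as.integer(col)
  if (rows_were_letters) col - 1L else col
}

#' Read a per-well screen table from delimited text
#'
#' Reads one row per well from a CSV or TSV file (delimiter chosen by file
#' extension), normalizes well roles and coordinates, and returns a
#' validated [screen_dataset()]. Row/column labels may be plate-reader
#' style ("B", "3", stored 0-based as row 1, col 2) or already 0-based
#' integers. Compound annotations may live in the same file or in a
#' separate plate map keyed by `(plate_id, row, col)`.
#'
#' @param path Path to a delimited text file with columns for arm, plate,
#'   row, column, compound, role and the two luminescence channels.
#' @param schema Optional named character vector mapping the canonical
#'   column names (`arm`, `plate_id`, `row`, `col`, `compound_id`, `role`,
#'   `nluc`, `fluc`, `concentration`) to the names used in the file, e.g.
#'   `c(nluc = "Nano", fluc = "Firefly")`.
#' @param platemap Optional path to a plate-map CSV with columns
#'   `plate_id,row,col,compound_id,role` (and optionally `concentration`),
#'   joined onto the measurement table.
#' @return A [screen_dataset()].
#' @export
read_screen_table <- function(path, schema = NULL, platemap = NULL) {
  raw <- read_delimited(path)
  raw <- apply_schema(raw, schema)
  if (!is.null(platemap)) {
    map <- read_delimited(platemap)
    map <- apply_schema(map, schema)
    map <- normalize_coords(map)
    raw <- normalize_coords(raw)
    raw <- dplyr::left_join(raw, map,
                            by = c("plate_id", "row", "col"),
                            suffix = c("", ".map"))
    for (field in c("compound_id", "role", "concentration")) {
      mapped <- paste0(field, ".map")
      if (mapped %in% names(raw)) {
        raw[[field]] <- raw[[mapped]]
        raw[[mapped]] <- NULL
      }
    }
  } else {
    raw <- normalize_coords(raw)
  }
  screen_dataset(raw)
}

read_delimited <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

apply_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  for (canonical in names(schema)) {
    file_col <- schema[[canonical]]
    if (file_col %in% names(df)) {
      names(df)[names(df) == file_col] <- canonical
    }
  }
  df
}

normalize_coords <- function(df) {
  rows_were_letters <- is.character(df$row) &&
    all(grepl("^[A-Pa-p]$", trimws(df$row)))
  df$row <- parse_well_rows(df$row)
  df$col <- parse_well_cols(df$col, rows_were_letters)
  df
}

#' Write a screen dataset back to delimited text
#'
#' Emits one row per well with plate-reader style row letters and 1-based
#' column numbers. `read_screen_table()` on the written file reproduces
#' the dataset exactly.
#'
#' @param dataset A [screen_dataset()].
#' @param path Output path; `.tsv`/`.txt` write tab-separated, anything
#'   else comma-separated.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(dataset, path) {
  out <- as_tibble(dataset)
  out$row <- LETTERS[out$row + 1L]
  out$col <- out$col + 1L
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Construct a plate matrix with a control mask
#'
#' A `plate_matrix` holds one scalar per well (a luminescence ratio or a
#' polish residual) together with a logical mask. Masked wells (controls
#' and empties) are excluded from every median computed during polishing
#' and scaling, but still receive the row/column/overall subtractions so
#' that control wells end up with comparable B-scores.
#'
#' @param values Numeric matrix (default geometry 16 x 24); `NA` marks
#'   missing wells.
#' @param mask Logical matrix of the same dimensions; `TRUE` excludes the
#'   well from median computations. Defaults to all `FALSE`.
#' @param plate_id,arm Optional identifiers carried along for reporting.
#' @return A `plate_matrix` object.
#' @export
plate_matrix <- function(values, mask = NULL, plate_id = NULL, arm = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    abort("mask must be a logical matrix with the same dimensions as values")
  }
  if (!any(!mask & !is.na(values))) {
    abort("plate must contain at least one unmasked, non-missing value")
  }
  structure(list(values = values, mask = mask,
                 plate_id = plate_id, arm = arm),
            class = "plate_matrix")
}

#' @export
print.plate_matrix <- function(x, ...) {
  cat(sprintf("<plate_matrix> %d x %d, %d masked, %d missing%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              sum(is.na(x$values)),
              if (!is.null(x$plate_id)) paste0(" [", x$arm, " ", x$plate_id, "]")
              else ""))
  invisible(x)
}

#' Compute a plate's luminescence-ratio matrix for one reporter arm
#'
#' For arm V1 the per-well ratio is Firefly/NanoLuc; for the reciprocal V2
#' construct it is NanoLuc/Firefly, so in both orientations a higher ratio
#' means more microexon inclusion. Control and empty wells are masked;
#' wells with a zero or missing denominator are set missing with a warning
#' and drop out of all downstream medians.
#'
#' @param wells Rows of a [screen_dataset()] belonging to a single plate
#'   and a single arm.
#' @param arm `"V1"` or `"V2"`; defaults to the (unique) `arm` column.
#' @param log2_transform If `TRUE`, return log2 ratios instead of raw
#'   ratios. Default `FALSE`: the polish operates on raw ratios.
#' @return A [plate_matrix()] with `mask = (role != "sample")`.
#' @export
compute_ratio_plate <- function(wells, arm = NULL, log2_transform = FALSE) {
  wells <- as_tibble(wells)
  if (is.null(arm)) arm <- unique(wells$arm)
  if (length(arm) != 1L || !arm %in% c("V1", "V2")) {
    abort("wells must belong to a single arm, V1 or V2")
  }
  if (length(unique(wells$plate_id)) != 1L) {
    abort("wells must belong to a single plate")
  }
  num <- if (arm == "V1") wells$fluc else wells$nluc
  den <- if (arm == "V1") wells$nluc else wells$fluc
  ratio <- num / den
  bad_den <- wells$role != "empty" & (is.na(den) | den <= 0)
  if (any(bad_den)) {
    warn(sprintf(
      "plate %s (%s): %d well(s) with zero/missing denominator set missing",
      wells$plate_id[1], arm, sum(bad_den)))
    ratio[bad_den] <- NA_real_
  }
  if (log2_transform) ratio <- log2(ratio)
  values <- matrix(NA_real_, PLATE_NROW, PLATE_NCOL)
  mask <- matrix(TRUE, PLATE_NROW, PLATE_NCOL)
  idx <- cbind(wells$row + 1L, wells$col + 1L)
  values[idx] <- ratio
  mask[idx] <- wells$role != "sample"
  plate_matrix(values, mask, plate_id = wells$plate_id[1], arm = arm)
}
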