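#' Read an NCBI-style names.dmp taxonomy dump
#'
#' Parses the taxonomy-dump dialect: four fields per row —
#' \code{tax_id}, \code{name_txt}, \code{unique_name} (may be empty) and
#' \code{name_class} — separated by tab-pipe-tab (\code{"\\t|\\t"}) with
#' rows terminated by tab-pipe. Malformed rows (wrong field count) are
#' reported with their line numbers and skipped.
#'
#' @param path path to a names.dmp-style file.
#' @param quiet suppress the per-line skip messages.
#' @return a tibble with columns \code{tax_id}, \code{name_txt},
#'   \code{unique_name}, \code{name_class}; the number of skipped rows is
#'   attached as attribute \code{"skipped"} alongside attribute
#'   \code{"skipped_lines"} with their line numbers.
#' @export
read_names_dump <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read dump file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- tibble::tibble(
      tax_id = character(), name_txt = character(),
      unique_name = character(), name_class = character()
    )
    attr(out, "skipped") <- 0L
    attr(out, "skipped_lines") <- integer()
    return(out)
  }
  body <- sub("\t\\|$", "", lines)
  parts <- stringi::stri_split_fixed(body, "\t|\t")
  nf <- lengths(parts)
  bad <- which(nf != 4L)
  if (length(bad) && !quiet) {
    message(
      "skipping ", length(bad), " malformed row(s) at line(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  good <- parts[nf == 4L]
  m <- if (length(good)) {
    do.call(rbind, good)
  } else {
    matrix(character(), ncol = 4)
  }
  out <- tibble::tibble(
    tax_id = m[, 1], name_txt = m[, 2],
    unique_name = m[, 3], name_class = m[, 4]
  )
  attr(out, "skipped") <- length(bad)
  attr(out, "skipped_lines") <- bad
  out
}

#' Write records in the names.dmp dialect
#'
#' Inverse of [read_names_dump()]: well-formed records round-trip
#' byte-exactly.
#'
#' @param records a data frame with columns \code{tax_id}, \code{name_txt},
#'   \code{unique_name}, \code{name_class}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_names_dump <- function(records, path) {
  need <- c("tax_id", "name_txt", "unique_name", "name_class")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  rows <- paste0(
    records$tax_id, "\t|\t", records$name_txt, "\t|\t",
    records$unique_name, "\t|\t", records$name_class, "\t|"
  )
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CSV checklist
#'
#' Reads a checklist supplied as CSV with a header row, extracting a
#' scientific-name column and carrying every other column through
#' untouched. Record ids are taken from \code{id_column} when given,
#' otherwise synthesized from the row ordinal. Input is decoded as UTF-8;
#' set \code{encoding = "latin1"} for Latin-1 sources. Mojibake (UTF-8
#' read as Latin-1 and re-encoded, e.g. \code{"BrullÃ©"}) is never
#' auto-repaired — it is surfaced in the \code{encoding_suspect} column so
#' the source can be fixed.
#'
#' @param path path to a CSV file.
#' @param name_column name of the column holding the name-strings.
#' @param id_column optional name of an id column.
#' @param encoding \code{"UTF-8"} (default) or \code{"latin1"}.
#' @return a tibble with columns \code{record_id}, \code{name_string},
#'   \code{encoding_suspect}, plus every other input column.
#' @export
read_checklist <- function(path, name_column = "scientificName",
                           id_column = NULL, encoding = "UTF-8") {
  if (!file.exists(path)) stop("cannot read checklist: ", path)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = encoding),
    progress = FALSE, show_col_types = FALSE
  )
  if (!name_column %in% names(df)) {
    stop(
      "name column '", name_column, "' not found; available columns: ",
      paste(names(df), collapse = ", ")
    )
  }
  if (!is.null(id_column) && !id_column %in% names(df)) {
    stop(
      "id column '", id_column, "' not found; available columns: ",
      paste(names(df), collapse = ", ")
    )
  }
  ids <- if (is.null(id_column)) {
    as.character(seq_len(nrow(df)))
  } else {
    df[[id_column]]
  }
  if (anyDuplicated(ids)) stop("record ids are not unique in ", path)
  name_string <- df[[name_column]]
  extra <- df[, setdiff(names(df), c(name_column, id_column)), drop = FALSE]
  out <- tibble::tibble(
    record_id = ids,
    name_string = name_string,
    encoding_suspect = stringi::stri_detect_regex(
      name_string, "Ã[©¡¶¼±¤«¨³º¸‰Š]|Â[°·]"
    )
  )
  cbind_tbl(out, extra)
}

cbind_tbl <- function(a, b) {
  if (ncol(b)) {
    for (nm in names(b)) a[[nm]] <- b[[nm]]
  }
  a
}
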