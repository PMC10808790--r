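# Role-tagged analysis table: one state/outcome column, one asymmetry
# predictor, one bifurcation predictor; listwise deletion on the role
# columns.

#' Construct a study table
#'
#' Tags one column of a data frame as the state (outcome), one as the
#' asymmetry predictor and one as the bifurcation predictor, coerces
#' them to numeric, and drops every row with a missing or non-numeric
#' value in any role column (listwise deletion).  Empty strings, `"NA"`
#' and unparseable tokens count as missing; the decimal separator is
#' always the point.
#'
#' @param data A data frame.
#' @param state,asymmetry,bifurcation Column names for the three roles.
#' @return An object of class `"study_table"`: a list with the screened
#'   `data`, the role map `roles`, `n_raw`, `n_analyzed`, and
#'   `deletion_log` (row indices of `data` that were removed).
#' @examples
#' d <- data.frame(engagement = rnorm(5, 10, 2), liking = rnorm(5, 10, 2),
#'                 disorder = rnorm(5, 10, 2))
#' study_table(d, "engagement", "liking", "disorder")
#' @export
study_table <- function(data, state = "engagement", asymmetry = "liking",
                        bifurcation = "disorder") {
  if (!is.data.frame(data)) stop_schema("'data' must be a data frame")
  roles <- c(state = state, asymmetry = asymmetry, bifurcation = bifurcation)
  missing_cols <- setdiff(unname(roles), names(data))
  if (length(missing_cols))
    stop_schema(paste0("missing role column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(unname(roles)))
    stop_schema("role columns must be distinct")
  n_raw <- nrow(data)
  num <- lapply(data[unname(roles)], to_numeric)
  keep <- Reduce(`&`, lapply(num, function(v) !is.na(v) & is.finite(v)))
  if (!any(keep)) stop_schema("no complete rows after listwise deletion")
  screened <- data[keep, , drop = FALSE]
  for (r in unname(roles)) screened[[r]] <- to_numeric(data[[r]])[keep]
  rownames(screened) <- NULL
  for (nm in names(roles)) {
    v <- screened[[roles[[nm]]]]
    if (length(v) > 1 && stats::sd(v) == 0)
      warning("role column '", roles[[nm]], "' (", nm, ") is constant; ",
              "model fitting will fail", call. = FALSE)
  }
  structure(list(data = screened, roles = roles, n_raw = n_raw,
                 n_analyzed = sum(keep),
                 deletion_log = which(!keep)),
            class = "study_table")
}

to_numeric <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- trimws(as.character(v))
  v[v %in% c("", "NA", "NaN", "na", ".")] <- NA_character_
  suppressWarnings(as.numeric(v))
}

#' Read a delimited file into a study table
#'
#' Parses a CSV/TSV file with a header row (delimiter sniffed from the
#' header unless given) and applies the screening of [study_table()].
#'
#' @inheritParams study_table
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` sniffs `,`, tab, or `;`.
#' @return A `study_table`.
#' @export
read_study_table <- function(path, state = "engagement", asymmetry = "liking",
                             bifurcation = "disorder", sep = NULL) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  study_table(raw, state = state, asymmetry = asymmetry,
              bifurcation = bifurcation)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d analyzed rows (of %d; %d removed by listwise deletion)\n",
              x$n_analyzed, x$n_raw, length(x$deletion_log)))
  cat("Roles:", paste(names(x$roles), "=", x$roles, collapse = ", "), "\n")
  invisible(x)
}

as_study_table <- function(x, ...) {
  if (inherits(x, "study_table")) return(x)
  if (is.data.frame(x)) return(study_table(x, ...))
  stop_schema("cannot coerce object to a study_table")
}

# Named list of the three role vectors.
study_columns <- function(tab) {
  stopifnot(inherits(tab, "study_table"))
  list(state = tab$data[[tab$roles[["state"]]]],
       asymmetry = tab$data[[tab$roles[["asymmetry"]]]],
       bifurcation = tab$data[[tab$roles[["bifurcation"]]]])
}

check_nonconstant <- function(v) {
  for (nm in names(v)) {
    if (stats::sd(v[[nm]]) == 0)
      stop_identifiability(paste0("the ", nm,
        " column is constant; the model is not identifiable"))
  }
  invisible(TRUE)
}
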