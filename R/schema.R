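#' ICF core-set schemas and qualifier matrices
#'
#' An ICF core set is an ordered list of ICF categories, each identified by a
#' code (one of the letters b/s/d/e followed by three digits, e.g. `b410`),
#' carrying a component implied by the letter, a short description and its
#' ICF chapter. Patient assessments attach to each category a qualifier in
#' 0--4 (0 = no impairment/difficulty/barrier ... 4 = complete), with the
#' conventional codes 8 = "not specified" and 9 = "not applicable".
#'
#' @name icf-schema
NULL

# letter -> component mapping implied by the ICF coding scheme
.icf_components <- c(
  b = "body_function",
  s = "body_structure",
  d = "activity_participation",
  e = "environment"
)

#' Qualifier values a score file may contain
#' @keywords internal
.qualifier_values <- c(0L, 1L, 2L, 3L, 4L, 8L, 9L)

#' Component implied by an ICF code
#'
#' @param code character vector of ICF codes (`b`/`s`/`d`/`e` + 3 digits).
#' @return character vector of components (`body_function`, `body_structure`,
#'   `activity_participation`, `environment`).
#' @examples
#' icf_component(c("b410", "e575"))
#' @export
icf_component <- function(code) {
  bad <- !grepl("^[bsde][0-9]{3}$", code)
  if (any(bad)) {
    stop("malformed ICF code(s): ", paste(code[bad], collapse = ", "),
         call. = FALSE)
  }
  unname(.icf_components[substr(code, 1L, 1L)])
}

#' Load an ICF core-set schema
#'
#' Reads a schema CSV with columns `code,component,description,chapter`
#' (header optional). `source` may be the name of a bundled schema --
#' currently `"cihd"`, the 46-category core set for chronic ischemic heart
#' disease -- or a path to a schema file. File order is preserved and fixes
#' the category order of every downstream matrix.
#'
#' @param source bundled schema name or path to a CSV file.
#' @return a data frame of class `icf_schema` with columns `code`,
#'   `component`, `description`, `chapter`.
#' @examples
#' sch <- load_schema("cihd")
#' nrow(sch)                       # 46
#' sch$description[sch$code == "b410"]
#' @export
load_schema <- function(source) {
  path <- if (file.exists(source)) {
    source
  } else {
    p <- system.file("extdata", paste0(source, ".csv"), package = "icfnet")
    if (!nzchar(p)) stop("schema source not found: ", source, call. = FALSE)
    p
  }
  first <- readLines(path, n = 1L)
  has_header <- startsWith(first, "code,")
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!has_header) {
    if (ncol(df) != 4L) {
      stop("schema file must have 4 columns (code,component,description,chapter)",
           call. = FALSE)
    }
    names(df) <- c("code", "component", "description", "chapter")
  }
  bad <- which(!grepl("^[bsde][0-9]{3}$", df$code))
  if (length(bad)) {
    stop("malformed ICF code at row ", bad[1L], ": '", df$code[bad[1L]], "'",
         call. = FALSE)
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup)) {
    stop("duplicate ICF code(s) in schema: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  implied <- icf_component(df$code)
  mism <- which(df$component != implied)
  if (length(mism)) {
    stop("component of '", df$code[mism[1L]], "' does not match its code letter",
         call. = FALSE)
  }
  class(df) <- c("icf_schema", "data.frame")
  df
}

#' @export
print.icf_schema <- function(x, ...) {
  cat("ICF core-set schema:", nrow(x), "categories (",
      paste(sprintf("%s: %d", names(table(x$component)), table(x$component)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Construct a qualifier matrix
#'
#' A qualifier matrix is an integer matrix of ICF qualifier scores, patients
#' in rows and categories in columns, entries restricted to
#' `{0,1,2,3,4,8,9}`. Codes 8 ("not specified") and 9 ("not applicable")
#' are treated as missing by all numeric downstream steps but preserved
#' verbatim on read/write round trips.
#'
#' @param values integer matrix with entries in `{0..4, 8, 9}`.
#' @param patient_ids row identifiers (defaults to existing rownames).
#' @param category_codes ICF codes for the columns (defaults to colnames).
#' @return an integer matrix of class `qualifier_matrix` with patient ids as
#'   rownames and category codes as colnames.
#' @export
qualifier_matrix <- function(values, patient_ids = rownames(values),
                             category_codes = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(category_codes)) {
    stop("category codes are required", call. = FALSE)
  }
  if (length(patient_ids) != nrow(values) ||
      length(category_codes) != ncol(values)) {
    stop("id/code lengths do not match matrix dimensions", call. = FALSE)
  }
  icf_component(category_codes)  # validates the code pattern
  storage.mode(values) <- "integer"
  bad <- which(matrix(!(values %in% .qualifier_values), nrow(values)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("invalid qualifier value %s for patient '%s', category '%s'",
                 values[i, j], patient_ids[i], category_codes[j]),
         call. = FALSE)
  }
  dimnames(values) <- list(patient_ids, category_codes)
  class(values) <- c("qualifier_matrix", class(values))
  values
}

#' Read a cohort qualifier-score file
#'
#' Expects a UTF-8 CSV with header `patient_id,<code>,...` and one row per
#' patient. All category codes are validated against `schema`; all values
#' against the qualifier set `{0..4, 8, 9}`. Row and column order are
#' preserved.
#'
#' @param path CSV file path.
#' @param schema an `icf_schema`; every file column must be one of its codes.
#' @return a [qualifier_matrix()].
#' @export
read_qualifier_matrix <- function(path, schema) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "patient_id") {
    stop("first column of a score file must be 'patient_id'", call. = FALSE)
  }
  codes <- names(df)[-1L]
  unknown <- setdiff(codes, schema$code)
  if (length(unknown)) {
    stop("unknown ICF code(s) in score file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  qualifier_matrix(values, patient_ids = as.character(df$patient_id),
                   category_codes = codes)
}

#' Write a cohort qualifier-score file
#'
#' Inverse of [read_qualifier_matrix()]: round-tripping a valid matrix
#' through write/read is the identity.
#'
#' @param m a [qualifier_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qualifier_matrix <- function(m, path) {
  stopifnot(inherits(m, "qualifier_matrix"))
  df <- data.frame(patient_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Missingness mask of a qualifier matrix
#'
#' TRUE exactly where the score is 8 ("not specified") or 9
#' ("not applicable"); both are treated as missing downstream.
#'
#' @param m a [qualifier_matrix()] or plain integer matrix.
#' @return logical matrix of the same dimensions.
#' @export
missing_mask <- function(m) {
  mask <- matrix(m %in% c(8L, 9L), nrow = nrow(m), dimnames = dimnames(m))
  mask
}
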