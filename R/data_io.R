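#' Read per-well proportions of functional HSCs
#'
#' Reads a comma-separated table of single-cell expansion results: one row per
#' cultured well, giving the fraction of CD201+CD150+KSL cells among all
#' expanded cells after culture. Columns `age_weeks`, `mouse_id`, `well_id`
#' and `proportion` are required; extra columns are dropped. Every row is
#' validated (proportion in \[0, 1\], positive age, unique
#' (age, mouse, well) key) and a malformed file never yields a partial table.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with columns `age_weeks` (numeric, weeks),
#'   `mouse_id`, `well_id` (character) and `proportion` (numeric in \[0, 1\]).
#' @seealso [read_census()], [write_table()], [generate_wells()]
#' @export
read_well_proportions <- function(path) {
  df <- read_delim_checked(path, c("age_weeks", "mouse_id", "well_id",
                                   "proportion"))
  df$age_weeks <- as.numeric(df$age_weeks)
  df$mouse_id <- as.character(df$mouse_id)
  df$well_id <- as.character(df$well_id)
  df$proportion <- as.numeric(df$proportion)
  validate_well_proportions(df)
  df
}

#' Read HSC / KSL census time courses
#'
#' Reads a comma-separated table of bone-marrow cell counts over age: one row
#' per (age, bone, mouse), giving the number of CD34-CD150+KSL cells
#' (`hsc_count`, the stem compartment S) and of KSL cells (`ksl_count`,
#' modelled as S + P). Bones are restricted to femur, pelvis and sternum, and
#' `hsc_count <= ksl_count` is enforced because HSCs are a KSL subset.
#'
#' @param path Path to a CSV file with columns `age_weeks`, `bone`,
#'   `mouse_id`, `hsc_count`, `ksl_count`.
#' @return A validated data frame with those five columns.
#' @export
read_census <- function(path) {
  df <- read_delim_checked(path, c("age_weeks", "bone", "mouse_id",
                                   "hsc_count", "ksl_count"))
  df$age_weeks <- as.numeric(df$age_weeks)
  df$bone <- as.character(df$bone)
  df$mouse_id <- as.character(df$mouse_id)
  df$hsc_count <- as.numeric(df$hsc_count)
  df$ksl_count <- as.numeric(df$ksl_count)
  validate_census(df)
  df
}

#' Write a result table as delimited text
#'
#' Writes any result data frame as comma-separated UTF-8 with a header row.
#' Numeric columns are rendered with 17 significant digits so that a
#' read-back reproduces the written doubles exactly.
#'
#' @param records Nonempty data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty data frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write table to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

## shared CSV reader: header check, no partial results
read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  df[required]
}

validate_well_proportions <- function(df) {
  check_numeric_col(df, "age_weeks", lower = 0, strict_lower = TRUE)
  check_numeric_col(df, "proportion", lower = 0, upper = 1)
  key <- paste(df$age_weeks, df$mouse_id, df$well_id, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("validation error: duplicate (age_weeks, mouse_id, well_id) key in row(s) ",
         paste(rows, collapse = ", "))
  }
  invisible(df)
}

validate_census <- function(df) {
  check_numeric_col(df, "age_weeks", lower = 0, strict_lower = TRUE)
  check_numeric_col(df, "hsc_count", lower = 0)
  check_numeric_col(df, "ksl_count", lower = 0)
  bad_bone <- which(!df$bone %in% c("femur", "pelvis", "sternum"))
  if (length(bad_bone))
    stop("format error: unknown bone in row(s) ",
         paste(bad_bone, collapse = ", "),
         " (column 'bone' must be femur, pelvis or sternum)")
  bad <- which(df$hsc_count > df$ksl_count)
  if (length(bad))
    stop("validation error: hsc_count > ksl_count in row(s) ",
         paste(bad, collapse = ", "),
         " (HSCs are a subset of KSL cells)")
  invisible(df)
}

check_numeric_col <- function(df, col, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  x <- df[[col]]
  bad <- which(!is.finite(x) |
                 (if (strict_lower) x <= lower else x < lower) |
                 x > upper)
  if (length(bad))
    stop("validation error: column '", col, "' out of range in row(s) ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
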