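#' Long-format survey CPUE table
#'
#' Validates a long-format table of trawl-survey catch per unit effort
#' (individuals per hauling hour): one record per (quarter, subarea, class),
#' where the class is an age class or a length class.  A 0-based
#' `quarter_step` index over the interleaved Q1/Q3 sequence is attached
#' (first surveyed year, Q1 = step 0).
#'
#' @param df data frame with columns `year`, `quarter` (1 or 3, or
#'   `"Q1"`/`"Q3"`), `subarea`, `class_id`, `cpue`.
#' @param class_kind `"age"` or `"length"`.
#' @return a `survey_table` data frame with columns `quarter_step`, `year`,
#'   `quarter`, `subarea`, `class_id`, `cpue`.
#' @export
survey_table <- function(df, class_kind = c("age", "length")) {
  class_kind <- match.arg(class_kind)
  need <- c("year", "quarter", "subarea", "class_id", "cpue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  q <- parse_quarter(df$quarter)
  if (any(is.na(q) | !(q %in% c(1L, 3L))))
    stop("quarter labels must be Q1 or Q3 after filtering", call. = FALSE)
  cpue <- as.numeric(df$cpue)
  bad <- which(!is.finite(cpue) | cpue < 0)
  if (length(bad))
    stop("validation error: negative or non-finite cpue at row ", bad[1],
         call. = FALSE)
  year <- as.integer(df$year)
  out <- data.frame(quarter_step = 2L * (year - min(year)) + (q == 3L),
                    year = year,
                    quarter = paste0("Q", q),
                    subarea = as.character(df$subarea),
                    class_id = df$class_id,
                    cpue = cpue,
                    stringsAsFactors = FALSE)
  key <- paste(out$quarter_step, out$subarea, out$class_id)
  if (anyDuplicated(key))
    stop("validation error: duplicate (quarter, subarea, class) records",
         call. = FALSE)
  out <- out[order(out$quarter_step, out$subarea, out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("survey_table", "data.frame"),
            class_kind = class_kind, filter_log = character())
}

parse_quarter <- function(q) {
  if (is.character(q) || is.factor(q)) q <- sub("^[Qq]", "", as.character(q))
  suppressWarnings(as.integer(q))
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table (%s classes)> %d records, %d quarters, %d subareas\n",
              attr(x, "class_kind"), nrow(x),
              length(unique(x$quarter_step)), length(unique(x$subarea))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a survey CPUE table from CSV
#'
#' Reads a comma-separated, UTF-8, headered export of CPUE-per-class-per-
#' subarea records.  Only first- and third-quarter hauls are retained (survey
#' coverage in Q2/Q4 is too sparse to use); dropped rows are reported via a
#' warning with a count.  Column names can be remapped for exports that use
#' different headers.
#'
#' @param path CSV file path.
#' @param class_kind `"age"` or `"length"`.
#' @param col_map named character vector mapping the canonical names
#'   `year`, `quarter`, `subarea`, `class`, `cpue` to the file's headers.
#' @return a [survey_table()].
#' @export
read_survey_table <- function(path, class_kind = c("age", "length"),
                              col_map = NULL) {
  class_kind <- match.arg(class_kind)
  map <- c(year = "year", quarter = "quarter", subarea = "subarea",
           class = "class", cpue = "cpue")
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(map), names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data.frame(year = df[[map["year"]]],
                   quarter = df[[map["quarter"]]],
                   subarea = df[[map["subarea"]]],
                   class_id = df[[map["class"]]],
                   cpue = df[[map["cpue"]]],
                   stringsAsFactors = FALSE)
  q <- parse_quarter(df$quarter)
  drop <- !(q %in% c(1L, 3L))
  if (any(drop)) {
    warning(sprintf("dropped %d record(s) outside quarters Q1/Q3", sum(drop)),
            call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  tab <- survey_table(df, class_kind)
  attr(tab, "filter_log") <-
    c(attr(tab, "filter_log"),
      if (any(drop)) sprintf("read: dropped %d non-Q1/Q3 record(s)", sum(drop)))
  tab
}

#' Write a survey table to CSV
#'
#' Values are written with full round-trip precision, so writing and
#' re-reading reproduces every record exactly.
#'
#' @param tab a [survey_table()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_survey_table <- function(tab, path) {
  stopifnot(inherits(tab, "survey_table"))
  out <- data.frame(year = tab$year,
                    quarter = sub("^Q", "", tab$quarter),
                    subarea = tab$subarea,
                    class = tab$class_id,
                    cpue = sprintf("%.17g", tab$cpue))  # exact round trip
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Apply the survey coverage filters
#'
#' Two rules, applied in order: (1) subareas whose CPUE is zero at every time
#' step are removed (areas the species never inhabited); (2) quarters
#' surveyed in fewer than `min_grids` distinct subareas are removed (too few
#' grids for a stable spatial-variability estimate).  Every removal is
#' recorded in the table's `filter_log` attribute.  A warning is raised when
#' fewer than 30 quarters remain, the practical floor for state-space
#' reconstruction on these data.
#'
#' @param tab a [survey_table()].
#' @param min_grids minimum number of distinct surveyed subareas per quarter.
#' @return the filtered `survey_table`.
#' @export
filter_survey <- function(tab, min_grids = 10L) {
  stopifnot(inherits(tab, "survey_table"))
  log <- attr(tab, "filter_log")
  kind <- attr(tab, "class_kind")
  tot <- tapply(tab$cpue, tab$subarea, sum)
  dead <- names(tot)[tot == 0]
  if (length(dead)) {
    tab <- tab[!(tab$subarea %in% dead), , drop = FALSE]
    log <- c(log, sprintf("filter: removed all-zero subarea '%s'", dead))
  }
  ngrid <- tapply(tab$subarea, tab$quarter_step,
                  function(s) length(unique(s)))
  thin <- as.integer(names(ngrid)[ngrid < min_grids])
  if (length(thin)) {
    tab <- tab[!(tab$quarter_step %in% thin), , drop = FALSE]
    log <- c(log, sprintf(
      "filter: removed quarter_step %d (%d < %d surveyed subareas)",
      thin, ngrid[as.character(thin)], min_grids))
  }
  if (nrow(tab) == 0) stop("empty-data error: no records survive filtering",
                           call. = FALSE)
  n_steps <- length(unique(tab$quarter_step))
  if (n_steps < 30)
    warning(sprintf(
      "only %d quarters remain; state-space reconstruction needs n >= 30",
      n_steps), call. = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("survey_table", "data.frame")
  attr(tab, "class_kind") <- kind
  attr(tab, "filter_log") <- log
  tab
}
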