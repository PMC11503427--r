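# Cohort data model: one row per measurement occasion (period, TSH, fT4,
# anti-TPO, urinary iodine). Measurements are deliberately unlinked across
# occasions: no subject identifier is modelled.

#' Gestational period labels
#'
#' The four measurement periods, in their natural order: first, second and
#' third trimester, then two months postpartum.
#'
#' @return Character vector `c("T1", "T2", "T3", "PP")`.
#' @export
period_levels <- function() c("T1", "T2", "T3", "PP")

# canonical column set; `schema` arguments map these names onto file columns
.cohort_columns <- c("sample_id", "period", "gest_week", "tsh_uIU_mL",
                     "ft4_ng_dL", "anti_tpo_U_mL", "anti_tpo_pos", "ui_ug_L")

#' Map gestational week to trimester
#'
#' Weeks 0--13 are the first trimester, 14--26 the second, and 27 onwards the
#' third. Postpartum occasions carry no week and must be labelled directly.
#'
#' @param week integer gestational week(s), 0--45.
#' @return factor with levels [period_levels()] (never `"PP"`).
#' @export
period_from_week <- function(week) {
  stopifnot(is.numeric(week))
  bad <- !is.na(week) & (week < 0 | week > 45 | week != floor(week))
  if (any(bad))
    stop("gestational week must be an integer in 0..45; offending value(s): ",
         paste(week[bad], collapse = ", "))
  lab <- ifelse(is.na(week), NA_character_,
                ifelse(week <= 13, "T1", ifelse(week <= 26, "T2", "T3")))
  factor(lab, levels = period_levels(), ordered = TRUE)
}

.as_period <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  up <- toupper(trimws(x))
  up[up %in% c("POSTPARTUM", "POST-PARTUM")] <- "PP"
  known <- is.na(up) | up %in% period_levels()
  if (!all(known))
    stop("unknown period label(s): ",
         paste(unique(up[!known]), collapse = ", "),
         " (expected T1, T2, T3 or PP)")
  factor(up, levels = period_levels(), ordered = TRUE)
}

#' Construct a validated cohort
#'
#' A cohort is a data frame with the canonical columns `sample_id`, `period`,
#' `gest_week`, `tsh_uIU_mL`, `ft4_ng_dL`, `anti_tpo_U_mL`, `anti_tpo_pos`
#' and `ui_ug_L`, carrying a free-text provenance trail of the filters that
#' have been applied to it. Missing measurements are `NA`; analyses use
#' pairwise-complete rows for the variables they touch.
#'
#' @param data data frame holding at least `sample_id` and `period` (or
#'   `gest_week`); other canonical columns are filled with `NA` when absent.
#' @return object of class `cohort` (a data frame).
#' @export
cohort <- function(data) {
  stopifnot(is.data.frame(data))
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in .cohort_columns)
    if (is.null(df[[col]]))
      df[[col]] <- rep(if (col == "anti_tpo_pos") NA else NA_real_,
                       nrow(df))
  if (all(is.na(df$period)) && !all(is.na(df$gest_week)) && nrow(df) > 0)
    df$period <- period_from_week(df$gest_week)
  df$sample_id <- as.character(df$sample_id)
  df$period <- .as_period(df$period)
  for (col in c("gest_week", "tsh_uIU_mL", "ft4_ng_dL", "anti_tpo_U_mL",
                "ui_ug_L"))
    df[[col]] <- as.numeric(df[[col]])
  df$anti_tpo_pos <- as.logical(df$anti_tpo_pos)
  df <- df[, .cohort_columns, drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("cohort", "data.frame"),
                   provenance = character())
  validate_cohort(out)
  out
}

#' Validate cohort invariants
#'
#' Checks uniqueness of sample identifiers, validity of period labels and
#' positivity/sign constraints on the measurements (`tsh > 0`, `ft4 > 0`,
#' `ui >= 0`, `anti_tpo >= 0` where present).
#'
#' @param x a [cohort].
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  if (nrow(x) > 0 && any(is.na(x$period)))
    stop("rows without a valid period: ",
         paste(which(is.na(x$period)), collapse = ", "))
  chk <- function(col, ok, what) {
    v <- x[[col]]
    bad <- !is.na(v) & !ok(v)
    if (any(bad))
      stop(col, " must be ", what, "; offending row(s): ",
           paste(which(bad), collapse = ", "))
  }
  chk("tsh_uIU_mL", function(v) v > 0, "> 0")
  chk("ft4_ng_dL", function(v) v > 0, "> 0")
  chk("ui_ug_L", function(v) v >= 0, ">= 0")
  chk("anti_tpo_U_mL", function(v) v >= 0, ">= 0")
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples\n", nrow(x)))
  tab <- table(x$period)
  cat("  by period:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:\n", paste("   -", prov, collapse = "\n"),
                        "\n")
  invisible(x)
}

#' Provenance trail of a cohort
#'
#' @param x a [cohort].
#' @return character vector of applied-filter descriptions, oldest first.
#' @export
provenance <- function(x) attr(x, "provenance")

.add_provenance <- function(x, msg) {
  attr(x, "provenance") <- c(attr(x, "provenance"), msg)
  x
}

.subset_cohort <- function(x, keep) {
  out <- structure(as.data.frame(x)[keep, , drop = FALSE],
                   class = c("cohort", "data.frame"),
                   provenance = attr(x, "provenance"))
  rownames(out) <- NULL
  out
}

#' Read a cohort from delimited text
#'
#' Reads an RFC-4180-style CSV with a header row. Columns are located by the
#' canonical names (see [cohort]) unless `schema` renames them. The period may
#' be given directly (labels `T1`/`T2`/`T3`/`PP`) or via integer gestational
#' week; when both are present and disagree, the direct label wins and a
#' warning is emitted.
#'
#' @param path file to read.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(sample_id = "id", tsh_uIU_mL =
#'   "tsh")`.
#' @return a validated [cohort].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    miss <- setdiff(schema, names(raw))
    if (length(miss))
      stop("schema error: mapped column(s) missing from file: ",
           paste(miss, collapse = ", "))
    names(raw)[match(schema, names(raw))] <- names(schema)
  }
  need <- c("sample_id")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error: required column(s) missing: ",
         paste(miss, collapse = ", "))
  if (!any(c("period", "gest_week") %in% names(raw)))
    stop("schema error: required column(s) missing: period (or gest_week)")

  df <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  num_col <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA_real_, nrow(raw)))
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !is.na(v)
    if (any(bad))
      stop(sprintf("column '%s': non-numeric value '%s' at row %d",
                   col, v[which(bad)[1]], which(bad)[1]))
    out
  }
  df$gest_week <- num_col("gest_week")
  for (col in c("tsh_uIU_mL", "ft4_ng_dL", "anti_tpo_U_mL", "ui_ug_L"))
    df[[col]] <- num_col(col)
  if (!is.null(raw$anti_tpo_pos)) {
    v <- toupper(trimws(raw$anti_tpo_pos))
    v[v == ""] <- NA_character_
    flag <- rep(NA, nrow(raw))
    flag[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
    flag[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- is.na(flag) & !is.na(v)
    if (any(bad))
      stop(sprintf("column 'anti_tpo_pos': unparseable value '%s' at row %d",
                   v[which(bad)[1]], which(bad)[1]))
    df$anti_tpo_pos <- flag
  }

  from_label <- if (is.null(raw$period)) {
    factor(rep(NA_character_, nrow(raw)), levels = period_levels(),
           ordered = TRUE)
  } else {
    lab <- trimws(raw$period)
    lab[lab == ""] <- NA_character_
    .as_period(lab)
  }
  from_week <- period_from_week(df$gest_week)
  period <- from_label
  use_week <- is.na(from_label) & !is.na(from_week)
  period[use_week] <- from_week[use_week]
  clash <- !is.na(from_label) & !is.na(from_week) & from_label != from_week
  if (any(clash)) {
    warning(sprintf(
      "period label and gestational week disagree for %d row(s); keeping the label",
      sum(clash)))
  }
  df$period <- period

  out <- cohort(df)
  .add_provenance(out, sprintf("read %d rows from %s", nrow(out),
                               basename(path)))
}

#' Write a cohort as delimited text
#'
#' Writes the canonical columns as CSV with a header row; missing values
#' become empty cells. The file re-reads to an identical cohort
#' ([read_cohort] round trip).
#'
#' @param x a [cohort].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  validate_cohort(x)
  df <- as.data.frame(x)
  df$period <- as.character(df$period)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive anti-TPO positivity from antibody level
#'
#' An occasion is anti-TPO positive when the antibody concentration is
#' strictly over the cutoff (34 U/mL by convention). Rows that already carry
#' a positivity flag keep it; rows with neither a flag nor a level are an
#' error.
#'
#' @param x a [cohort].
#' @param cutoff positivity cutoff, U/mL.
#' @return the cohort with `anti_tpo_pos` filled in.
#' @export
derive_anti_tpo_positivity <- function(x, cutoff = 34) {
  stopifnot(inherits(x, "cohort"), is.numeric(cutoff), length(cutoff) == 1)
  need <- is.na(x$anti_tpo_pos)
  orphan <- need & is.na(x$anti_tpo_U_mL)
  if (any(orphan))
    stop("neither anti-TPO level nor positivity flag for row(s): ",
         paste(which(orphan), collapse = ", "))
  x$anti_tpo_pos[need] <- x$anti_tpo_U_mL[need] > cutoff
  .add_provenance(x, sprintf(
    "anti-TPO positivity derived for %d row(s) at > %g U/mL", sum(need),
    cutoff))
}
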