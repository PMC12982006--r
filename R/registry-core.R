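#' Column dictionary of the delivery-record table
#'
#' One row per column of the patient-level registry table: name, storage
#' type, allowed categories (for enumerated fields), and whether the field is
#' one of the mandatory obstetric variables whose absence excludes a record.
#'
#' @return A data frame with columns `column`, `type`, `levels`, `mandatory`.
#' @export
registry_columns <- function() {
  col <- function(column, type, levels = NA_character_, mandatory = FALSE)
    data.frame(column = column, type = type, levels = levels,
               mandatory = mandatory, stringsAsFactors = FALSE)
  rbind(
    col("facility_id", "character"),
    col("year", "integer"),
    col("ga_days", "integer", mandatory = TRUE),
    col("birth_order", "integer"),
    col("n_fetuses", "integer", mandatory = TRUE),
    col("stillbirth_status", "enum",
        "livebirth|stillbirth_known|unknown_timing"),
    col("parity", "integer", mandatory = TRUE),
    col("infertility_treatment", "integer", mandatory = TRUE),
    col("neonatal_sex", "enum", "M|F", mandatory = TRUE),
    col("maternal_age", "numeric", mandatory = TRUE),
    col("birth_weight", "numeric", mandatory = TRUE),
    col("blood_loss", "numeric", mandatory = TRUE),
    col("maternal_survival", "integer", mandatory = TRUE),
    col("tpl", "integer"), col("hdp", "integer"), col("pprom", "integer"),
    col("previa", "integer"), col("multiple", "integer"),
    col("fgr", "integer"), col("abruption", "integer"),
    col("transfer_in", "integer"), col("cesarean", "integer"),
    col("cesarean_grade1", "integer"),
    col("acs_checkbox", "integer"),
    col("acs_dose", "enum", "12|24|36|48"),
    col("acs_interval", "enum", "lt48h|48h_7d|7d_1mo|gt1mo")
  )
}

mandatory_fields <- function() {
  d <- registry_columns()
  d$column[d$mandatory]
}

#' Read / write a patient-level registry table
#'
#' Delimited text (tab-separated by default) with the header of
#' [registry_columns()].  Reading validates the schema: a missing column is a
#' schema error; a value outside an enumerated field's categories is a parse
#' error naming the row and field.  `acs_dose` and `acs_interval` may be
#' empty (missing).
#'
#' @param path Path to the records table.
#' @param facilities_path Optional path to the facility attributes table
#'   (`facility_id`, `care_level`, `designated_city`).
#' @param sep Field delimiter (`"\t"` or `","`).
#' @param registry An `acs_registry` (list with `records` and `facilities`),
#'   or a bare records data frame.
#' @return `read_registry()` returns an `acs_registry`; `write_registry()`
#'   returns `path` invisibly.
#' @export
read_registry <- function(path, facilities_path = NULL, sep = "\t") {
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           quote = "\"", comment.char = "")
  dict <- registry_columns()
  missing_cols <- setdiff(dict$column, names(rec))
  if (length(missing_cols))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (k in which(dict$type == "enum")) {
    cn <- dict$column[k]
    lev <- strsplit(dict$levels[k], "|", fixed = TRUE)[[1]]
    bad <- which(!is.na(rec[[cn]]) & !(as.character(rec[[cn]]) %in% lev))
    if (length(bad))
      stop(sprintf("parse error: invalid value '%s' for field `%s` at row %d",
                   rec[[cn]][bad[1]], cn, bad[1]), call. = FALSE)
  }
  fac <- if (!is.null(facilities_path)) {
    utils::read.table(facilities_path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  } else {
    ids <- unique(rec$facility_id)
    data.frame(facility_id = ids,
               care_level = rep(NA_character_, length(ids)),
               designated_city = rep(NA, length(ids)),
               stringsAsFactors = FALSE)
  }
  structure(list(records = rec, facilities = fac), class = "acs_registry")
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path, facilities_path = NULL, sep = "\t") {
  rec <- if (is.data.frame(registry)) registry else registry$records
  utils::write.table(rec, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(facilities_path) && !is.data.frame(registry))
    utils::write.table(registry$facilities, facilities_path, sep = sep,
                       row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Identify ACS recipients
#'
#' A delivery counts as an ACS recipient if the registry checkbox is ticked
#' *or* a total dose *or* an administration-to-delivery interval is
#' documented -- documentation of either detail field overrides an unticked
#' checkbox.
#'
#' @param records Delivery-record data frame.
#' @return Logical vector along rows of `records`.
#' @export
is_acs_recipient <- function(records) {
  (!is.na(records$acs_checkbox) & records$acs_checkbox == 1L) |
    !is.na(records$acs_dose) |
    !is.na(records$acs_interval)
}

#' Apply the patient-level exclusion cascade
#'
#' Drops, in fixed order: exact duplicate rows; stillbirths or perinatal
#' deaths of unknown timing; neonates other than the first-born of a multiple
#' pregnancy; and records missing any mandatory obstetric field.  Each record
#' is counted at its first failing step, so the log's excluded counts plus the
#' retained count always reproduce the input count.
#'
#' @param records Delivery-record data frame (or an `acs_registry`).
#' @param duplicate_key Columns defining a duplicate; default all columns
#'   (exact row equality).
#' @return List with `records` (retained rows) and `log` (class
#'   `exclusion_log`: named counts `input`, `duplicates`,
#'   `unknown_timing`, `non_first_born`, `missing_mandatory`, `retained`).
#' @export
apply_exclusions <- function(records, duplicate_key = NULL) {
  if (inherits(records, "acs_registry")) records <- records$records
  n_in <- nrow(records)
  keydf <- if (is.null(duplicate_key)) records else records[duplicate_key]
  dup <- duplicated(keydf)
  unk <- !dup & records$stillbirth_status == "unknown_timing"
  nfb <- !dup & !unk & records$birth_order > 1L
  mm <- !dup & !unk & !nfb &
    !stats::complete.cases(records[mandatory_fields()])
  keep <- !(dup | unk | nfb | mm)
  log <- structure(
    list(input = n_in,
         duplicates = sum(dup),
         unknown_timing = sum(unk),
         non_first_born = sum(nfb),
         missing_mandatory = sum(mm),
         retained = sum(keep)),
    class = "exclusion_log")
  list(records = records[keep, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  input records                 %8d\n", x$input))
  cat(sprintf("  - duplicate rows              %8d\n", x$duplicates))
  cat(sprintf("  - stillbirth, unknown timing  %8d\n", x$unknown_timing))
  cat(sprintf("  - non-first-born (multiples)  %8d\n", x$non_first_born))
  cat(sprintf("  - missing mandatory field     %8d\n", x$missing_mandatory))
  cat(sprintf("  retained                      %8d\n", x$retained))
  invisible(x)
}

#' @export
as.data.frame.exclusion_log <- function(x, ...) {
  data.frame(step = names(unclass(x)), count = unlist(unclass(x)),
             row.names = NULL)
}

#' Subset used by the sensitivity analysis
#'
#' Removes pregnancies complicated by placental abruption and deliveries by
#' Grade 1 (most urgent) cesarean section -- cases in which there may be no
#' opportunity to administer ACS.  Idempotent; intended to run on records
#' already passed through [apply_exclusions()], after which the whole
#' metrics/model pipeline is recomputed.
#'
#' @param records Delivery-record data frame.
#' @return The subset data frame.
#' @export
sensitivity_subset <- function(records) {
  if (inherits(records, "acs_registry")) records <- records$records
  drop <- (!is.na(records$abruption) & records$abruption == 1L) |
    (!is.na(records$cesarean_grade1) & records$cesarean_grade1 == 1L)
  records[!drop, , drop = FALSE]
}
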