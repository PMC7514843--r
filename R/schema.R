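#' Categorical variable specification
#'
#' A variable of the preprocessed accident schema: a short code, a finite set
#' of integer value codes with human-readable labels, the partition the
#' variable applies to, and whether missing values occur for it.
#'
#' @param name Short variable code (e.g. `"ACT_TY"`).
#' @param values Integer vector of admissible codes (unique, non-empty).
#' @param labels Character vector of meanings, parallel to `values`.
#' @param applies_to One of `"both"`, `"intersection"`, `"non_intersection"`:
#'   which partition of the urban-accident data the variable is recorded for.
#' @param missing_allowed Logical; whether records may leave this variable
#'   unobserved.
#' @return A `variable_spec` object (a list).
#' @export
variable_spec <- function(name, values, labels = as.character(values),
                          applies_to = "both", missing_allowed = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  values <- as.integer(values)
  if (length(values) == 0L) stop("variable '", name, "': empty value set")
  if (anyDuplicated(values)) stop("variable '", name, "': duplicated codes")
  if (length(labels) != length(values))
    stop("variable '", name, "': labels must parallel values")
  applies_to <- match.arg(applies_to, c("both", "intersection", "non_intersection"))
  structure(list(name = name, values = values, labels = as.character(labels),
                 applies_to = applies_to,
                 missing_allowed = isTRUE(missing_allowed)),
            class = "variable_spec")
}

#' Assemble an accident schema from variable specifications
#'
#' @param specs List of [variable_spec()] objects; the last entry must be the
#'   class variable `SEV` with values `1` (slight) and `2` (fatal).
#' @return An `accident_schema`: a named list of specs.
#' @export
accident_schema <- function(specs) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicated variable names in schema")
  if (!"SEV" %in% nms) stop("schema must contain the class variable SEV")
  sev <- specs[[which(nms == "SEV")]]
  if (sev$missing_allowed) stop("SEV may not allow missing values")
  names(specs) <- nms
  structure(specs, class = "accident_schema")
}

#' The preprocessed urban-accident schema
#'
#' Returns the full categorical schema of the preprocessed Spanish DGT
#' urban-accident data for novice drivers: 22 predictor variables plus the
#' binary severity class `SEV` (1 = slight injury, 2 = fatal injury, i.e.
#' killed or seriously injured within 30 days). Intersection type (`I_T`) and
#' priority regulation (`PR`) are recorded only for accidents at
#' intersections; the road tracing (`TR_N_INT`) only away from intersections.
#'
#' @return An `accident_schema` with 23 entries.
#' @export
#' @examples
#' sch <- table1_schema()
#' sch$SEV$values
#' sch$I_T$applies_to
table1_schema <- function() {
  accident_schema(list(
    variable_spec("SE", 1:4,
      c("winter", "spring", "summer", "autumn")),
    variable_spec("F_T", 1:4,
      c("0:01-6:00", "6:01-12:00", "12:01-18:00", "18:01-0:00")),
    variable_spec("S_W", 1:4,
      c("Monday", "Friday", "Tuesday-Thursday", "weekend")),
    variable_spec("I_L", 1:2,
      c("one vehicle", "more than one vehicle")),
    variable_spec("TR_N_INT", 1:2,
      c("straight line", "curve"),
      applies_to = "non_intersection", missing_allowed = TRUE),
    variable_spec("I_T", 1:4,
      c("T or X", "X or +", "roundabout", "exit/entrance link"),
      applies_to = "intersection"),
    variable_spec("PR", 1:7,
      c("traffic officer directions", "semaphore", "stop signal",
        "pedestrian crossing signal", "road signs", "general rule", "other"),
      applies_to = "intersection", missing_allowed = TRUE),
    variable_spec("RO_SU", 1:5,
      c("dry and clean", "wet", "snowy/frozen", "oily", "other state"),
      missing_allowed = TRUE),
    variable_spec("LUM", 1:4,
      c("broad daylight", "twilight", "night, sufficient illumination",
        "night, insufficient illumination")),
    variable_spec("WE_CO", 1:4,
      c("good weather", "fog", "light rain", "adverse weather"),
      missing_allowed = TRUE),
    variable_spec("RES_VIS", 1:7,
      c("no restrictions", "buildings", "land configuration",
        "weather conditions", "glare", "dust", "other restrictions"),
      missing_allowed = TRUE),
    variable_spec("PAV", 0:1,
      c("pavements", "no pavements"), missing_allowed = TRUE),
    variable_spec("ACT_TY", 1:5,
      c("collision", "running over a pedestrian", "overturn", "road exit",
        "other accident")),
    variable_spec("AG_FR", 1:4,
      c("<=20 years", "21-27 years", "28-59 years", "60+ years")),
    variable_spec("SEX", 1:2, c("man", "woman"), missing_allowed = TRUE),
    variable_spec("MAN", 1:8,
      c("following the road", "overtaking", "turning",
        "entering from another road", "crossing an intersection",
        "driving in reverse", "abrupt gear shift", "other maneuver"),
      missing_allowed = TRUE),
    variable_spec("SP_IN", 1:3,
      c("too fast", "too slow", "appropriate speed"), missing_allowed = TRUE),
    variable_spec("DR_INFR", 0:5,
      c("no violation", "failed to observe a sign", "wrong side of road",
        "forbidden overtaking", "security distance", "other infraction"),
      missing_allowed = TRUE),
    variable_spec("OL_VEH", 1:2,
      c("<=2 years old", ">=3 years old"), missing_allowed = TRUE),
    variable_spec("VEH_TY", 1:4,
      c("motorbike", "car", "heavy vehicle", "other vehicle"),
      missing_allowed = TRUE),
    variable_spec("AN", 1:2, c("no anomaly", "anomaly"),
      missing_allowed = TRUE),
    variable_spec("O_L", 1:3,
      c("driver only", "two", "more than two")),
    variable_spec("SEV", 1:2, c("slight injury", "fatal injury"))
  ))
}

#' Predictor variables of a schema applicable to a partition
#' @param schema An `accident_schema`.
#' @param partition `"both"`, `"intersection"` or `"non_intersection"`.
#' @return Character vector of predictor names (class variable excluded).
#' @export
schema_predictors <- function(schema, partition = "both") {
  partition <- match.arg(partition, c("both", "intersection", "non_intersection"))
  keep <- vapply(schema, function(s) {
    s$name != "SEV" &&
      (partition == "both" || s$applies_to == "both" || s$applies_to == partition)
  }, logical(1))
  names(schema)[keep]
}

.schema_subset <- function(schema, partition) {
  keep <- c(schema_predictors(schema, partition), "SEV")
  accident_schema(unname(schema[keep]))
}

#' Weighted categorical accident records
#'
#' Bundles a table of integer-coded records (with `NA` as the missing marker),
#' their schema, per-record non-negative weights, and the partition the data
#' belong to. Validation is row-level: every non-missing code must belong to
#' its variable's value set, the class is never missing, and offending rows
#' are reported individually.
#'
#' @param data A data.frame of integer codes; columns for schema variables plus
#'   `SEV`. Extra columns (e.g. an intersection indicator) are carried along
#'   unvalidated.
#' @param schema An `accident_schema` (default [table1_schema()]).
#' @param weights Non-negative per-record weights, default 1.
#' @param partition Which partition the records belong to.
#' @param validate Set `FALSE` to skip row validation (internal use).
#' @return An `accident_dataset`.
#' @export
accident_dataset <- function(data, schema = table1_schema(),
                             weights = rep(1, nrow(data)),
                             partition = "both", validate = TRUE) {
  partition <- match.arg(partition, c("both", "intersection", "non_intersection"))
  stopifnot(is.data.frame(data))
  if (!"SEV" %in% names(data)) stop("data must contain the class column SEV")
  if (length(weights) != nrow(data)) stop("weights must have one entry per record")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (nrow(data) > 0 && sum(weights) <= 0) stop("total weight must be positive")
  vars <- intersect(names(schema), names(data))
  for (v in vars) data[[v]] <- as.integer(data[[v]])
  if (validate && nrow(data) > 0) {
    problems <- character(0)
    for (v in vars) {
      bad <- which(!is.na(data[[v]]) & !(data[[v]] %in% schema[[v]]$values))
      if (length(bad))
        problems <- c(problems, sprintf("row %d: %s=%s not in value set",
                                        bad, v, data[[v]][bad]))
    }
    bad <- which(is.na(data$SEV))
    if (length(bad))
      problems <- c(problems, sprintf("row %d: SEV missing", bad))
    if (length(problems)) {
      stop("invalid records:\n  ", paste(utils::head(problems, 20L),
                                         collapse = "\n  "),
           if (length(problems) > 20L) sprintf("\n  ... and %d more",
                                               length(problems) - 20L))
    }
  }
  structure(list(data = data, schema = schema, weights = as.numeric(weights),
                 partition = partition),
            class = "accident_dataset")
}

#' @export
print.accident_dataset <- function(x, ...) {
  cat(sprintf("accident_dataset: %d records, %d schema variables, partition=%s\n",
              nrow(x$data), length(x$schema) - 1L, x$partition))
  if (nrow(x$data) > 0) {
    tab <- table(factor(x$data$SEV, levels = x$schema$SEV$values))
    cat(sprintf("  severity: %s slight, %s fatal (%.1f%% fatal)\n",
                tab[1], tab[2], 100 * tab[2] / sum(tab)))
  }
  invisible(x)
}

#' Number of records
#' @param ds An `accident_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(ds) nrow(ds$data)

#' Derive the binary accident severity from casualty counts
#'
#' An accident is fatal (class 2) when anyone was killed or seriously injured
#' (at the crash or within 30 days); otherwise it is a slight injury (class 1).
#'
#' @param killed,serious,slight Non-negative integer casualty counts
#'   (vectorized).
#' @return Integer vector of severity classes in `{1, 2}`.
#' @export
#' @examples
#' derive_severity(killed = 0, serious = 0, slight = 3)  # 1
#' derive_severity(killed = 1, serious = 0, slight = 0)  # 2
derive_severity <- function(killed, serious, slight = 0L) {
  counts <- cbind(killed, serious, slight)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("casualty counts must be non-negative integers")
  ifelse(killed > 0 | serious > 0, 2L, 1L)
}

#' Select the novice-driver urban cohort
#'
#' Keeps the records of drivers with three or fewer years of experience
#' (`driver_type == 1`) in urban areas, then drops the two selection columns.
#' Records with a missing `driver_type` or urban flag are excluded with a
#' warning.
#'
#' @param data A data.frame with schema columns plus `driver_type`
#'   (1 = three years' experience or less, 2 = more) and `urban` (1/`TRUE` =
#'   urban area).
#' @param schema An `accident_schema`.
#' @param driver_col,urban_col Names of the two selection columns.
#' @return An `accident_dataset` of the cohort.
#' @export
filter_cohort <- function(data, schema = table1_schema(),
                          driver_col = "driver_type", urban_col = "urban") {
  stopifnot(is.data.frame(data))
  if (!all(c(driver_col, urban_col) %in% names(data)))
    stop("data must carry '", driver_col, "' and '", urban_col, "' columns")
  dt <- data[[driver_col]]
  ub <- data[[urban_col]]
  miss <- is.na(dt) | is.na(ub)
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing cohort fields excluded")
    data <- data[!miss, , drop = FALSE]
    dt <- dt[!miss]; ub <- ub[!miss]
  }
  keep <- dt == 1 & (as.integer(ub) == 1L | isTRUE(ub) | ub == TRUE)
  out <- data[keep, setdiff(names(data), c(driver_col, urban_col)), drop = FALSE]
  rownames(out) <- NULL
  accident_dataset(out, schema = schema, partition = "both")
}

#' Split a cohort into intersection and non-intersection datasets
#'
#' Accidents at intersections have different characteristics and are analyzed
#' separately. The split is exhaustive and disjoint; each partition drops the
#' variables that do not apply to it (`TR_N_INT` at intersections; `I_T` and
#' `PR` away from them) along with the indicator column. Records with a
#' missing indicator are excluded with a warning.
#'
#' @param ds An `accident_dataset` with partition `"both"`.
#' @param indicator Name of the indicator column (1 = intersection,
#'   0 = not at an intersection).
#' @return A list with elements `intersection` and `non_intersection`.
#' @export
split_by_intersection <- function(ds, indicator = "INT") {
  stopifnot(inherits(ds, "accident_dataset"))
  if (!indicator %in% names(ds$data))
    stop("dataset has no intersection indicator column '", indicator, "'")
  flag <- ds$data[[indicator]]
  miss <- is.na(flag)
  if (any(miss)) warning(sum(miss), " record(s) with missing intersection indicator excluded")
  take <- function(part, sel) {
    sch <- .schema_subset(ds$schema, part)
    cols <- intersect(names(ds$data), c(names(sch),
                                        setdiff(names(ds$data),
                                                c(names(ds$schema), indicator))))
    out <- ds$data[sel, cols, drop = FALSE]
    rownames(out) <- NULL
    accident_dataset(out, schema = sch, weights = ds$weights[sel],
                     partition = part)
  }
  list(intersection = take("intersection", !miss & flag == 1),
       non_intersection = take("non_intersection", !miss & flag != 1))
}

#' Write accident records as delimited text
#'
#' Comma-separated, header row of variable codes, empty cell for a missing
#' value. Weights are not written; the format stores unit-weight records.
#'
#' @param ds An `accident_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accident_data <- function(ds, path) {
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read accident records from delimited text
#'
#' @param path CSV file written by [write_accident_data()] (or following the
#'   same dialect: header of variable codes, empty cell = missing).
#' @param schema An `accident_schema` used for validation.
#' @param partition Partition the file holds.
#' @return An `accident_dataset` with unit weights.
#' @export
read_accident_data <- function(path, schema = table1_schema(),
                               partition = "both") {
  data <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  accident_dataset(data, schema = schema, partition = partition)
}

#' Write a schema as YAML
#' @param schema An `accident_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unname(schema), unclass), path)
  invisible(path)
}

#' Read a schema from YAML
#' @param path YAML file written by [write_schema()].
#' @return An `accident_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  accident_schema(lapply(raw, function(s)
    variable_spec(s$name, s$values, s$labels, s$applies_to, s$missing_allowed)))
}
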