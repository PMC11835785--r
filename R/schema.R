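#' Define a discretized clinical variable
#'
#' A variable is a named, ordered set of categorical states, optionally
#' backed by the numeric cut points used to discretize a measurement.
#' Interval convention (matching the cohort table the model was designed
#' around): the first band is closed at its lower end, interior upper ends
#' are closed, and the top band is open-ended. So with edges `c(100, 125)`
#' the bands are `[0, 100]`, `(100, 125]`, `(125, Inf)`.
#'
#' @param name Identifier string (canonical lowercase token).
#' @param states Character vector of at least two unique state labels,
#'   in order.
#' @param bin_edges Optional strictly increasing numeric cut points; when
#'   present there must be `length(bin_edges) + 1` states.
#' @return An object of class `bnaf_variable`.
#' @export
variable_spec <- function(name, states, bin_edges = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L) {
    stop("variable '", name, "' needs at least 2 states", call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("variable '", name, "' has duplicated state labels", call. = FALSE)
  }
  if (!is.null(bin_edges)) {
    bin_edges <- as.numeric(bin_edges)
    if (is.unsorted(bin_edges, strictly = TRUE)) {
      stop("bin_edges must be strictly increasing", call. = FALSE)
    }
    if (length(states) != length(bin_edges) + 1L) {
      stop("variable '", name, "': ", length(bin_edges),
           " edges imply ", length(bin_edges) + 1L, " states, got ",
           length(states), call. = FALSE)
    }
  }
  structure(list(name = name, states = states, bin_edges = bin_edges),
            class = "bnaf_variable")
}

#' Define a domain schema
#'
#' The ordered collection of discretized variables a cohort is recorded
#' over, with one of them designated as the outcome.
#'
#' @param variables List of [variable_spec()] objects.
#' @param outcome Name of the outcome variable.
#' @return An object of class `bnaf_schema`.
#' @export
domain_schema <- function(variables, outcome) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  ok <- vapply(variables, inherits, logical(1L), what = "bnaf_variable")
  if (!all(ok)) stop("all variables must be built by variable_spec()", call. = FALSE)
  nms <- vapply(variables, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("variable names must be unique", call. = FALSE)
  if (!outcome %in% nms) {
    stop("outcome '", outcome, "' is not among the variables", call. = FALSE)
  }
  names(variables) <- nms
  structure(list(variables = variables, outcome = outcome),
            class = "bnaf_schema")
}

#' @export
print.bnaf_schema <- function(x, ...) {
  cat("Domain schema:", length(x$variables), "variables, outcome =",
      x$outcome, "\n")
  for (v in x$variables) {
    cat("  ", v$name, ": ", paste(v$states, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

schema_names <- function(schema) names(schema$variables)

schema_states <- function(schema, name) schema$variables[[name]]$states

schema_cardinalities <- function(schema) {
  vapply(schema$variables, function(v) length(v$states), integer(1L))
}

#' Size of a schema's joint state space
#'
#' @param schema A [domain_schema()].
#' @return Product of the per-variable state counts.
#' @export
state_space_size <- function(schema) prod(schema_cardinalities(schema))

#' The default 12-variable clinical schema
#'
#' Demographic and clinical variables of an AF-ablation cohort, discretized:
#' sex, age band (cut at 45 and 65 years), the binary comorbidities
#' alcoholism / smoking / diabetes / high blood pressure / obstructive sleep
#' apnea, BMI class (WHO cuts at 25 and 30 kg/m2), preablation AF type,
#' indexed left-atrial volume band (cut at 100 and 125 mL/m2), epicardial
#' fat band (cut at 2.7 and 4.6 cm3), and the outcome, AF relapse after the
#' blanking period. Joint state space: 2^8 * 3^4 = 20,736 cells.
#'
#' @return A [domain_schema()] with outcome `relapse`.
#' @export
build_default_schema <- function() {
  domain_schema(list(
    variable_spec("sex", c("female", "male")),
    variable_spec("age", c("le45", "46to65", "over65"), bin_edges = c(45, 65)),
    variable_spec("alcoholism", c("false", "true")),
    variable_spec("smoking", c("false", "true")),
    variable_spec("diabetes", c("false", "true")),
    variable_spec("hbp", c("false", "true")),
    variable_spec("osa", c("false", "true")),
    variable_spec("bmi", c("normal", "overweight", "obese"),
                  bin_edges = c(25, 30)),
    variable_spec("af_type", c("paroxysmal", "persistent")),
    variable_spec("la_volume", c("le100", "100to125", "over125"),
                  bin_edges = c(100, 125)),
    variable_spec("epicardial_fat", c("le2.7", "2.7to4.6", "over4.6"),
                  bin_edges = c(2.7, 4.6)),
    variable_spec("relapse", c("false", "true"))
  ), outcome = "relapse")
}

discretize_value <- function(value, spec) {
  if (is.null(spec$bin_edges)) {
    if (is.logical(value)) value <- tolower(as.character(value))
    value <- as.character(value)
    if (!value %in% spec$states) {
      stop("'", value, "' is not a state of '", spec$name, "' (allowed: ",
           paste(spec$states, collapse = ", "), ")", call. = FALSE)
    }
    return(value)
  }
  value <- as.numeric(value)
  if (is.na(value)) stop("non-numeric value for '", spec$name, "'", call. = FALSE)
  if (value < 0) stop("negative measurement for '", spec$name, "'", call. = FALSE)
  # first band [0, e1]; interior bands (e_{i-1}, e_i]; top band (e_k, Inf)
  band <- findInterval(value, spec$bin_edges, left.open = TRUE) + 1L
  spec$states[[band]]
}

#' Discretize one raw clinical record into schema states
#'
#' Numeric measurements (age, BMI, left-atrial volume, epicardial fat) are
#' binned with the band edges of their [variable_spec()]; a value exactly on
#' an interior edge falls in the lower band (the interval's closed upper
#' end). Logical fields map to `"false"`/`"true"`; character fields must
#' already be valid state labels.
#'
#' @param raw Named list of numeric / logical / character measurements, one
#'   entry per schema variable (the outcome may be omitted).
#' @param schema A [domain_schema()].
#' @return Named character vector of state labels.
#' @export
discretize_record <- function(raw, schema = build_default_schema()) {
  stopifnot(is.list(raw) || (is.vector(raw) && !is.null(names(raw))))
  raw <- as.list(raw)
  unknown <- setdiff(names(raw), schema_names(schema))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(names(raw), function(nm) {
    discretize_value(raw[[nm]], schema$variables[[nm]])
  }, character(1L))
  names(out) <- names(raw)
  out
}

#' Build a validated cohort
#'
#' A cohort is a rectangular table of complete categorical patient records:
#' one row per patient, one factor column per schema variable, levels equal
#' to the schema states. Cells are checked against the schema; missing
#' values are rejected.
#'
#' @param df A data.frame of state labels (character or factor).
#' @param schema A [domain_schema()].
#' @return A data.frame of factors with attributes `schema` and class
#'   `bnaf_cohort`.
#' @export
as_cohort <- function(df, schema = build_default_schema()) {
  stopifnot(is.data.frame(df))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- df[nms]
  for (nm in nms) {
    states <- schema_states(schema, nm)
    col <- as.character(out[[nm]])
    bad <- which(is.na(col) | !col %in% states)
    if (length(bad)) {
      stop("column '", nm, "', row ", bad[1L], ": '", col[bad[1L]],
           "' is not one of {", paste(states, collapse = ", "), "}",
           call. = FALSE)
    }
    out[[nm]] <- factor(col, levels = states)
  }
  rownames(out) <- NULL
  attr(out, "schema") <- schema
  class(out) <- c("bnaf_cohort", "data.frame")
  out
}

cohort_schema <- function(cohort) {
  sc <- attr(cohort, "schema")
  if (is.null(sc)) stop("not a bnaf cohort (no schema attribute)", call. = FALSE)
  sc
}

# row subset preserving the cohort class and schema (duplicates allowed,
# so a bootstrap multiset is a valid training table)
cohort_subset <- function(cohort, idx) {
  schema <- cohort_schema(cohort)
  out <- as.data.frame(lapply(cohort, function(col) col[idx]),
                       check.names = FALSE)
  names(out) <- names(cohort)
  rownames(out) <- NULL
  attr(out, "schema") <- schema
  class(out) <- c("bnaf_cohort", "data.frame")
  out
}

# integer state codes, n x p matrix in schema column order
cohort_codes <- function(cohort) {
  m <- matrix(0L, nrow(cohort), length(cohort),
              dimnames = list(NULL, names(cohort)))
  for (j in seq_along(cohort)) m[, j] <- as.integer(cohort[[j]])
  m
}

#' Read / write a cohort CSV
#'
#' Plain UTF-8 comma-separated files: header of canonical variable names,
#' cells holding canonical state labels, booleans serialized `true`/`false`.
#'
#' @param path File path.
#' @param schema A [domain_schema()].
#' @return `read_cohort_csv` returns a cohort; `write_cohort_csv` returns
#'   `path` invisibly.
#' @export
read_cohort_csv <- function(path, schema = build_default_schema()) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  as_cohort(df, schema)
}

#' @rdname read_cohort_csv
#' @param cohort A cohort built by [as_cohort()].
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(lapply(cohort, as.character),
                      stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a schema as JSON
#'
#' @param schema A [domain_schema()].
#' @param path File path.
#' @return `read_schema_json` returns a [domain_schema()].
#' @export
write_schema_json <- function(schema, path) {
  vars <- lapply(schema$variables, function(v) {
    out <- list(name = v$name, states = v$states)
    if (!is.null(v$bin_edges)) out$bin_edges <- v$bin_edges
    out
  })
  jsonlite::write_json(list(variables = unname(vars), outcome = schema$outcome),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  vars <- lapply(x$variables, function(v) {
    variable_spec(v$name, v$states, bin_edges = v$bin_edges)
  })
  domain_schema(vars, x$outcome)
}
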