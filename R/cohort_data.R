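#' Standardize a partially administered cognitive score to the 0-30 scale
#'
#' Cognitive test scores (MMSE-style) are sometimes recorded out of fewer
#' than 30 items when a patient cannot attempt every item for reasons
#' unrelated to cognition (e.g. 24/29). The adjusted score rescales the
#' observed proportion correct to the full 0-30 range:
#' \code{numerator / denominator * 30}, kept fractional.
#'
#' @param numerator Integer vector, number of items answered correctly.
#' @param denominator Integer vector, number of items asked.
#' @return Numeric vector of adjusted scores in \code{[0, 30]}.
#' @examples
#' standardize_score(24, 29) # 24.82759
#' @export
standardize_score <- function(numerator, denominator) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must have the same length")
  bad <- is.na(numerator) | is.na(denominator) | denominator <= 0 |
    numerator < 0 | numerator > denominator | denominator > 30
  if (any(bad))
    stop("invalid record(s) at position(s) ", paste(which(bad), collapse = ", "),
         ": need 0 <= numerator <= denominator <= 30 and denominator > 0")
  numerator / denominator * 30
}

#' Assemble a longitudinal treated-cohort dataset
#'
#' Bundles per-visit outcome records, per-subject baseline characteristics
#' and (optionally) trial-eligibility flags into a single object used by
#' the model-fitting functions. Records carry observation times in years
#' relative to the treatment offer (offer at \code{t = 0}). If
#' \code{adjusted_score} is absent from \code{records} it is computed from
#' \code{numerator}/\code{denominator} via [standardize_score()]; records
#' may instead supply \code{adjusted_score} directly (e.g. simulated data)
#' with the count columns left \code{NA}.
#'
#' @param records Data frame with columns \code{subject_id},
#'   \code{time_years} and either \code{adjusted_score} or both
#'   \code{numerator} and \code{denominator}.
#' @param baselines Optional data frame, one row per subject, with
#'   \code{subject_id} plus whatever baseline fields the eligibility
#'   criteria reference.
#' @param eligible Optional logical vector named by subject id (the
#'   eligibility indicator S_i), or \code{NULL} if not yet flagged.
#' @return An object of class \code{cohort_dataset}: a list with elements
#'   \code{records}, \code{baselines}, \code{eligible}.
#' @export
cohort_dataset <- function(records, baselines = NULL, eligible = NULL) {
  records <- as.data.frame(records)
  need <- c("subject_id", "time_years")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(records$subject_id)) {
    stop("missing subject_id in records row(s) ",
         paste(which(is.na(records$subject_id)), collapse = ", "))
  }
  if (!is.numeric(records$time_years) || anyNA(records$time_years))
    stop("time_years must be numeric and non-missing")
  if (!"numerator" %in% names(records)) records$numerator <- NA_integer_
  if (!"denominator" %in% names(records)) records$denominator <- NA_integer_
  if (!"adjusted_score" %in% names(records)) records$adjusted_score <- NA_real_
  fill <- is.na(records$adjusted_score)
  if (any(fill)) {
    if (anyNA(records$denominator[fill]))
      stop("records without adjusted_score must carry numerator and denominator")
    records$adjusted_score[fill] <-
      standardize_score(records$numerator[fill], records$denominator[fill])
  }
  records <- records[c("subject_id", "time_years", "numerator", "denominator",
                       "adjusted_score")]
  if (!is.null(baselines)) {
    baselines <- as.data.frame(baselines)
    if (!"subject_id" %in% names(baselines))
      stop("baselines must contain subject_id")
    if (anyDuplicated(baselines$subject_id))
      stop("baselines must have one row per subject")
    orphan <- setdiff(unique(records$subject_id), baselines$subject_id)
    if (length(orphan))
      stop("record subject(s) absent from baselines: ",
           paste(utils::head(orphan, 5), collapse = ", "))
  }
  if (!is.null(eligible)) {
    if (is.null(names(eligible)))
      stop("eligible must be a named logical vector (names = subject ids)")
    eligible <- as.logical(eligible) |> stats::setNames(names(eligible))
  }
  structure(list(records = records, baselines = baselines,
                 eligible = eligible),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  ns <- length(unique(x$records$subject_id))
  cat("cohort_dataset:", nrow(x$records), "records on", ns, "subjects\n")
  cat("  time range:",
      sprintf("[%.2f, %.2f] years", min(x$records$time_years),
              max(x$records$time_years)), "\n")
  if (!is.null(x$eligible))
    cat("  trial eligible:", sum(x$eligible), "of", length(x$eligible), "\n")
  invisible(x)
}

#' Apply the cohort inclusion filters
#'
#' Retains outcome records with score denominator at or above
#' \code{min_denominator} and observation time inside the window (both
#' bounds inclusive). Records carrying an adjusted score but no denominator
#' (already-standardized or simulated data) are subject only to the time
#' window. Subjects with at least one retained record stay in the dataset;
#' others are dropped from records, baselines and eligibility flags alike.
#'
#' @param dataset A \code{cohort_dataset}.
#' @param min_denominator Minimum items asked for a score to count
#'   (default 24).
#' @param window Numeric length-2, years relative to offer; default
#'   \code{c(-1, 3)}.
#' @return A filtered \code{cohort_dataset}. Filtering is idempotent.
#' @export
apply_inclusion_filters <- function(dataset, min_denominator = 24,
                                    window = c(-1, 3)) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be finite with window[1] < window[2]")
  r <- dataset$records
  keep_den <- is.na(r$denominator) | r$denominator >= min_denominator
  keep_t <- r$time_years >= window[1] & r$time_years <= window[2]
  r <- r[keep_den & keep_t, , drop = FALSE]
  if (nrow(r) == 0L) warning("no records remain after filtering")
  ids <- unique(r$subject_id)
  b <- dataset$baselines
  if (!is.null(b)) b <- b[b$subject_id %in% ids, , drop = FALSE]
  e <- dataset$eligible
  if (!is.null(e)) e <- e[names(e) %in% ids]
  cohort_dataset(r, b, e)
}

#' Baseline score per subject
#'
#' The operational baseline is the adjusted score of the record closest to
#' the treatment offer (\code{t = 0}); ties broken towards the earlier
#' record.
#'
#' @param dataset A \code{cohort_dataset}.
#' @return Named numeric vector of baseline scores, one per subject.
#' @export
baseline_scores <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  r <- dataset$records
  out <- vapply(split(r, r$subject_id), function(d) {
    d <- d[order(abs(d$time_years), d$time_years), , drop = FALSE]
    d$adjusted_score[1]
  }, numeric(1))
  out
}

#' Construct trial-eligibility criteria
#'
#' A criteria set is a list of predicates over baseline fields; a subject is
#' eligible iff every predicate holds. Supported operators: \code{range}
#' (inclusive bounds \code{args = c(lo, hi)}), \code{in_set} (membership in
#' \code{args}), \code{equals} (\code{args} a single value).
#'
#' @param ... Predicates, each a list with elements \code{field}, \code{op},
#'   \code{args}.
#' @return Object of class \code{eligibility_criteria}.
#' @examples
#' crit <- eligibility_criteria(
#'   list(field = "age_years", op = "range", args = c(40, 94)),
#'   list(field = "baseline_score", op = "range", args = c(10, 26)),
#'   list(field = "diagnosis_code", op = "in_set",
#'        args = c("alzheimers", "alzheimers_cvd")),
#'   list(field = "has_caregiver", op = "equals", args = TRUE),
#'   list(field = "has_other_major_psychiatric_disorder", op = "equals",
#'        args = FALSE))
#' @export
eligibility_criteria <- function(...) {
  crits <- list(...)
  for (cr in crits) {
    if (!all(c("field", "op", "args") %in% names(cr)))
      stop("each criterion needs field, op and args")
    if (!cr$op %in% c("range", "in_set", "equals"))
      stop("unknown op '", cr$op, "' (use range, in_set or equals)")
    if (cr$op == "range" && length(cr$args) != 2)
      stop("range criterion needs args of length 2")
  }
  structure(crits, class = "eligibility_criteria")
}

#' Read eligibility criteria from a YAML or JSON config file
#'
#' The file holds a top-level list \code{criteria}, each entry with
#' \code{field}, \code{op} and \code{args} as in [eligibility_criteria()].
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{eligibility_criteria} object.
#' @examples
#' read_criteria(system.file("extdata", "trial_eligibility.yaml",
#'                           package = "cohortborrow"))
#' @export
read_criteria <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$criteria)) stop("config must contain a 'criteria' list")
  do.call(eligibility_criteria, cfg$criteria)
}

#' Flag trial eligibility of cohort subjects
#'
#' Evaluates a criteria set against each subject's baseline row. A subject
#' is eligible (S_i = 1) iff all predicates hold. Subjects with a missing
#' value in any referenced field are handled per \code{missing_policy}:
#' the default flags them ineligible with a warning, keeping the
#' eligibility indicator total over subjects.
#'
#' @param baselines Data frame, one row per subject, with \code{subject_id}.
#' @param criteria An \code{eligibility_criteria} object.
#' @param missing_policy One of \code{"ineligible"} (default) or
#'   \code{"error"}.
#' @return Named logical vector of eligibility flags.
#' @export
flag_eligibility <- function(baselines, criteria,
                             missing_policy = c("ineligible", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(criteria, "eligibility_criteria"))
  baselines <- as.data.frame(baselines)
  fields <- vapply(criteria, `[[`, character(1), "field")
  unknown <- setdiff(fields, names(baselines))
  if (length(unknown))
    stop("criteria reference unknown baseline field(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(baselines)
  ok <- rep(TRUE, n)
  any_na <- rep(FALSE, n)
  for (cr in criteria) {
    v <- baselines[[cr$field]]
    res <- switch(cr$op,
      range  = v >= cr$args[1] & v <= cr$args[2],
      in_set = v %in% cr$args & !is.na(v),
      equals = v == cr$args[[1]])
    any_na <- any_na | is.na(res)
    ok <- ok & !is.na(res) & res
  }
  if (any(any_na)) {
    if (missing_policy == "error")
      stop("missing baseline field value(s) for subject(s) ",
           paste(baselines$subject_id[any_na], collapse = ", "))
    warning(sum(any_na), " subject(s) with missing baseline fields flagged ",
            "ineligible")
  }
  stats::setNames(ok, as.character(baselines$subject_id))
}

#' Read / write a cohort dataset as CSV
#'
#' The records file has columns \code{subject_id}, \code{time_years},
#' \code{numerator}, \code{denominator}, \code{adjusted_score}; the
#' optional baselines file has \code{subject_id} plus baseline fields and,
#' if eligibility has been flagged, an \code{eligible} column. A
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param path Path of the records CSV.
#' @param baselines_path Optional path of the baselines CSV.
#' @return \code{read_cohort_csv} returns a \code{cohort_dataset};
#'   \code{write_cohort_csv} returns its input invisibly.
#' @export
read_cohort_csv <- function(path, baselines_path = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("records CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in intersect(c("time_years", "numerator", "denominator",
                          "adjusted_score"), names(rec))) {
    v <- rec[[col]]
    if (!is.numeric(v) && !all(is.na(v)))
      stop("non-numeric values in column ", col, " of ", path)
  }
  baselines <- eligible <- NULL
  if (!is.null(baselines_path)) {
    baselines <- utils::read.csv(baselines_path, stringsAsFactors = FALSE)
    if ("eligible" %in% names(baselines)) {
      eligible <- stats::setNames(as.logical(baselines$eligible),
                                  as.character(baselines$subject_id))
      baselines$eligible <- NULL
    }
  }
  cohort_dataset(rec, baselines, eligible)
}

#' @rdname read_cohort_csv
#' @param dataset A \code{cohort_dataset}.
#' @export
write_cohort_csv <- function(dataset, path, baselines_path = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  if (!is.null(baselines_path)) {
    b <- dataset$baselines
    if (is.null(b))
      b <- data.frame(subject_id = unique(dataset$records$subject_id))
    if (!is.null(dataset$eligible))
      b$eligible <- unname(dataset$eligible[as.character(b$subject_id)])
    utils::write.csv(b, baselines_path, row.names = FALSE)
  }
  invisible(dataset)
}
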