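# Long-format longitudinal data container and its IO / preprocessing verbs.
#
# A `long_data` object is a validated long-format data.frame (one row per
# person-occasion) that remembers which columns play which role.  Occasions
# must be consecutive integers within person: the AR(1) residual process gives
# rho^|lag| its meaning only on an equally spaced grid, so gaps are a hard
# error rather than a silent misinterpretation.

#' Construct a validated long-format longitudinal dataset
#'
#' @param data a data.frame in long format (one row per person-occasion).
#' @param outcome name of the numeric outcome column.
#' @param id name of the person identifier column.
#' @param time name of the integer occasion-index column.  Occasions must be
#'   consecutive integers within each person (any starting value).
#' @param predictors character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @return an object of class `long_data`: the data.frame (rows ordered by
#'   person, then occasion) with attributes recording the column roles, the
#'   total number of rows `n_total`, and any preprocessing constants.
#' @examples
#' d <- data.frame(id = rep(1:2, each = 3), day = rep(1:3, 2),
#'                 mood = rnorm(6), stress = runif(6))
#' ld <- long_data(d, outcome = "mood", id = "id", time = "day",
#'                 predictors = "stress")
#' n_persons(ld)
#' @export
long_data <- function(data, outcome, id, time, predictors = character()) {
  stopifnot(is.data.frame(data))
  need <- c(outcome, id, time, predictors)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)
  for (cl in c(outcome, time, predictors)) {
    if (!is.numeric(data[[cl]]))
      stop("column '", cl, "' must be numeric")
    if (anyNA(data[[cl]]))
      stop("column '", cl, "' contains missing values (row ",
           which(is.na(data[[cl]]))[1], ")")
  }
  if (anyNA(data[[id]])) stop("missing person identifiers")
  tt <- data[[time]]
  if (any(tt != round(tt))) stop("occasion index must be integer-valued")
  ord <- order(match(data[[id]], unique(data[[id]])), tt)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  # per-person occasion checks: strictly increasing consecutive integers
  sp <- split(seq_len(nrow(data)), factor(data[[id]], levels = unique(data[[id]])))
  for (pid in names(sp)) {
    ti <- data[[time]][sp[[pid]]]
    if (anyDuplicated(ti))
      stop("duplicate (id, time) pair for person '", pid, "' at time ",
           ti[duplicated(ti)][1])
    dt <- diff(ti)
    if (length(dt) && any(dt != 1))
      stop("occasion gap for person '", pid, "': times ",
           ti[which(dt != 1)[1]], " to ", ti[which(dt != 1)[1] + 1],
           " are not consecutive")
  }
  structure(data,
            outcome = outcome, id = id, time = time,
            predictors = predictors,
            n_total = nrow(data),
            preprocessing = list(),
            class = c("long_data", "data.frame"))
}

#' @export
print.long_data <- function(x, ...) {
  cat("Long-format longitudinal dataset\n")
  cat("  persons:   ", n_persons(x), "\n", sep = "")
  cat("  rows:      ", nrow(x), "\n", sep = "")
  cat("  outcome:   ", attr(x, "outcome"), "\n", sep = "")
  cat("  predictors:", if (length(attr(x, "predictors")))
        paste(attr(x, "predictors"), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Number of persons in a long_data object
#' @param ld a `long_data` object.
#' @export
n_persons <- function(ld) length(unique(ld[[attr(ld, "id")]]))

#' @export
as.data.frame.long_data <- function(x, ...) {
  at <- attributes(x)
  attributes(x) <- c(at[c("names", "row.names")], list(class = "data.frame"))
  x
}

# Internal: split a long_data into per-person series.  Each element carries
# the person id, occasion indices, outcome vector and the raw predictor rows.
ld_split <- function(ld) {
  idc <- attr(ld, "id")
  ids <- unique(ld[[idc]])
  lapply(ids, function(pid) {
    rows <- ld[ld[[idc]] == pid, , drop = FALSE]
    list(id = pid,
         times = rows[[attr(ld, "time")]],
         y = rows[[attr(ld, "outcome")]],
         P = as.matrix(rows[attr(ld, "predictors")]))
  })
}

#' Read a long-format CSV
#'
#' Reads a CSV with one row per person-occasion and validates it into a
#' [long_data()] object.
#'
#' @param path path to the CSV file.
#' @inheritParams long_data
#' @return a `long_data` object.
#' @export
read_long_csv <- function(path, outcome, id, time, predictors = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_data(d, outcome = outcome, id = id, time = time, predictors = predictors)
}

#' Write a long-format CSV
#'
#' Companion writer emitting the same dialect [read_long_csv()] consumes,
#' so that read -> write -> read is the identity.
#'
#' @param ld a `long_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ld, path) {
  stopifnot(inherits(ld, "long_data"))
  utils::write.csv(as.data.frame(ld), path, row.names = FALSE)
  invisible(path)
}

#' Person-mean centering and standardization of predictors
#'
#' Time-varying predictors are replaced by their within-person-mean-centered
#' versions and the person means are appended as new time-constant columns
#' (named `<var>_pm`).  With `standardize = TRUE` every predictor is then
#' divided by its standard deviation across all rows (population SD, i.e.
#' denominator n), so each column has unit SD over the pooled sample.
#' All constants are recorded in the `preprocessing` attribute so that the
#' transformation can be replayed on new data.
#'
#' @param ld a `long_data` object.
#' @param time_varying names of the time-varying predictor columns to
#'   person-mean-center.
#' @param standardize logical; z-scale all predictors after centering.
#' @return a new `long_data` with transformed predictors.
#' @export
preprocess_predictors <- function(ld, time_varying = character(),
                                  standardize = FALSE) {
  stopifnot(inherits(ld, "long_data"))
  preds <- attr(ld, "predictors")
  bad <- setdiff(time_varying, preds)
  if (length(bad)) stop("unknown predictor column(s): ",
                        paste(bad, collapse = ", "))
  d <- as.data.frame(ld)
  idc <- attr(ld, "id")
  rec <- list(time_varying = time_varying, person_means = list(),
              sds = NULL, sd_denominator = "n")
  for (v in time_varying) {
    pm <- ave(d[[v]], d[[idc]], FUN = mean)
    d[[v]] <- d[[v]] - pm
    d[[paste0(v, "_pm")]] <- pm
    agg <- unique(data.frame(id = d[[idc]], mean = pm))
    rec$person_means[[v]] <- stats::setNames(agg$mean, agg$id)
    preds <- c(preds, paste0(v, "_pm"))
  }
  if (standardize) {
    sds <- vapply(preds, function(v) {
      x <- d[[v]]
      sqrt(mean((x - mean(x))^2))
    }, numeric(1))
    zero <- names(sds)[sds <= 0]
    if (length(zero))
      stop("zero-variance predictor under standardize: ",
           paste(zero, collapse = ", "))
    for (v in preds) d[[v]] <- d[[v]] / sds[[v]]
    rec$sds <- sds
  }
  out <- long_data(d, outcome = attr(ld, "outcome"), id = idc,
                   time = attr(ld, "time"), predictors = preds)
  attr(out, "preprocessing") <- rec
  out
}

#' Split into training sample, Task-1 holdout, and new persons
#'
#' The training sample is the first `n_train_persons` persons restricted to
#' their first `n_train_times` occasions.  Their remaining occasions form the
#' Task-1 holdout (future occasions of trained persons); all other persons
#' with their full series form the new-person test set used for Tasks 2 and 3.
#'
#' @param ld a `long_data` object.
#' @param n_train_persons number of persons in the training sample (in the
#'   dataset's person order).
#' @param n_train_times number of occasions per training person.
#' @return list with elements `train`, `test_task1` and `test_newpersons`,
#'   each a `long_data` (possibly with zero rows).
#' @export
split_train_test <- function(ld, n_train_persons, n_train_times) {
  stopifnot(inherits(ld, "long_data"))
  idc <- attr(ld, "id")
  ids <- unique(ld[[idc]])
  if (n_train_persons > length(ids))
    stop("n_train_persons (", n_train_persons, ") exceeds the number of persons (",
         length(ids), ")")
  train_ids <- ids[seq_len(n_train_persons)]
  d <- as.data.frame(ld)
  occ <- stats::ave(seq_along(d[[idc]]), d[[idc]], FUN = seq_along)
  in_train_person <- d[[idc]] %in% train_ids
  take <- function(rows) {
    out <- d[rows, , drop = FALSE]
    long_data(out, outcome = attr(ld, "outcome"), id = idc,
              time = attr(ld, "time"), predictors = attr(ld, "predictors"))
  }
  res <- list(
    train = take(in_train_person & occ <= n_train_times),
    test_task1 = take(in_train_person & occ > n_train_times),
    test_newpersons = take(!in_train_person)
  )
  res
}
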