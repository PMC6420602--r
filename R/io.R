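## Reading-order mirror about the vertical midline: within each of the
## eight 24-2 rows the point order is reversed. Used to fold left-eye (OS)
## charts onto the packaged right-eye orientation.
.mirror_map <- function() {
  lens <- c(4L, 6L, 8L, 9L, 9L, 8L, 6L, 4L)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  unlist(mapply(function(s, k) s + rev(seq_len(k)), starts, lens,
                SIMPLIFY = FALSE))
}

.num_fmt <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a long-format visual-field series CSV
#'
#' Expects columns \code{eye_id}, \code{time_years}, \code{location_id},
#' \code{sensitivity_db} and optionally \code{eye} (\code{OD}/\code{OS};
#' \code{OS} charts are mirrored about the vertical midline onto the
#' packaged right-eye orientation). Blind-spot rows are dropped with a
#' message; each remaining visit must cover all 52 retained locations.
#' An optional labels CSV (\code{eye_id}, \code{label} with label
#' \code{stable} or \code{progressing}) attaches the clinical reference
#' standard; eyes absent from it are labelled \code{unknown}.
#'
#' @param path series CSV path.
#' @param labelsPath optional labels CSV path.
#' @param grid a [VFGrid-class] (defaults to [buildGrid()]).
#' @return a [VFCohort-class] with per-eye tests sorted by time.
#' @export
readSeriesCsv <- function(path, labelsPath = NULL, grid = buildGrid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "time_years", "location_id", "sensitivity_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("series CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("series CSV is empty", call. = FALSE)

  if ("eye" %in% names(df)) {
    os <- df$eye == "OS"
    if (any(os)) {
      mm <- .mirror_map()
      df$location_id[os] <- mm[df$location_id[os]]
    }
  }

  bad <- which(df$sensitivity_db < 0 | df$sensitivity_db > 50 |
                 !is.finite(df$sensitivity_db))
  if (length(bad)) {
    stop("sensitivity_db outside [0, 50] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(df$location_id < 1 | df$location_id > 54)) {
    stop("location_id must be in 1..54", call. = FALSE)
  }

  bs <- df$location_id %in% blindSpotIds(grid)
  if (any(bs)) {
    message("dropping ", sum(bs), " blind-spot rows")
    df <- df[!bs, , drop = FALSE]
  }

  key <- paste(df$eye_id, df$time_years, df$location_id)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (eye_id, time_years, location_id) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  labels <- NULL
  if (!is.null(labelsPath)) {
    lab <- utils::read.csv(labelsPath, stringsAsFactors = FALSE)
    if (!all(c("eye_id", "label") %in% names(lab))) {
      stop("labels CSV needs columns eye_id, label", call. = FALSE)
    }
    if (!all(lab$label %in% c("stable", "progressing"))) {
      stop("labels must be 'stable' or 'progressing'", call. = FALSE)
    }
    labels <- stats::setNames(lab$label, lab$eye_id)
  }

  rid <- retainedIds(grid)
  series <- lapply(split(df, df$eye_id), function(d) {
    times <- sort(unique(d$time_years))
    sens <- matrix(NA_real_, nrow = 52L, ncol = length(times),
                   dimnames = list(rid, NULL))
    for (k in seq_along(times)) {
      v <- d[d$time_years == times[k], ]
      missing_ids <- setdiff(rid, v$location_id)
      if (length(missing_ids)) {
        stop("eye '", d$eye_id[1], "' visit at ", times[k],
             " y is missing location(s): ",
             paste(utils::head(missing_ids, 8), collapse = ", "),
             call. = FALSE)
      }
      sens[match(v$location_id, rid), k] <- v$sensitivity_db
    }
    lb <- "unknown"
    if (!is.null(labels) && d$eye_id[1] %in% names(labels)) {
      lb <- labels[[d$eye_id[1]]]
    }
    VFSeries(d$eye_id[1], times - times[1], sens, lb)
  })
  VFCohort(unname(series))
}

#' Write a cohort to a long-format series CSV (and optional labels CSV)
#'
#' Inverse of [readSeriesCsv()]: numeric fields are written with 17
#' significant digits so that a write-read round trip reproduces the cohort
#' exactly.
#'
#' @param cohort a [VFCohort-class].
#' @param path series CSV path.
#' @param labelsPath optional labels CSV path; labelled eyes only.
#' @param grid a [VFGrid-class].
#' @return invisibly, \code{path}.
#' @export
writeSeriesCsv <- function(cohort, path, labelsPath = NULL,
                           grid = buildGrid()) {
  rid <- retainedIds(grid)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("eye_id,time_years,location_id,sensitivity_db", con)
  for (s in cohort@series) {
    for (k in seq_along(s@times)) {
      writeLines(paste(s@eyeId, .num_fmt(s@times[k]), rid,
                       .num_fmt(s@sens[, k]), sep = ","), con)
    }
  }
  if (!is.null(labelsPath)) {
    labs <- progressionLabel(cohort)
    keep <- labs != "unknown"
    con2 <- file(labelsPath, "w")
    on.exit(close(con2), add = TRUE)
    writeLines("eye_id,label", con2)
    writeLines(paste(eyeId(cohort)[keep], labs[keep], sep = ","), con2)
  }
  invisible(path)
}

#' Write a per-eye predictor table
#'
#' One row per eye, \code{eye_id} first then numeric predictor columns in a
#' deterministic order; values carry 17 significant digits and missing
#' predictors serialise as empty fields, so a write-read-write cycle is
#' byte-identical.
#'
#' @param table data.frame with an \code{eye_id} column and numeric
#'   predictor columns.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writePredictorsCsv <- function(table, path) {
  if (!"eye_id" %in% names(table)) {
    stop("predictor table needs an eye_id column", call. = FALSE)
  }
  numcols <- setdiff(names(table), "eye_id")
  isnum <- vapply(table[numcols], is.numeric, logical(1))
  if (!all(isnum)) {
    stop("non-numeric predictor column(s): ",
         paste(numcols[!isnum], collapse = ", "), call. = FALSE)
  }
  numcols <- sort(numcols)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("eye_id", numcols), collapse = ","), con)
  for (r in seq_len(nrow(table))) {
    vals <- vapply(numcols, function(cn) .num_fmt(table[[cn]][r]),
                   character(1))
    writeLines(paste(c(table$eye_id[r], vals), collapse = ","), con)
  }
  invisible(path)
}

#' Read a predictor table written by [writePredictorsCsv()]
#'
#' @param path CSV path.
#' @return data.frame with \code{eye_id} and numeric columns; empty fields
#'   become \code{NA}.
#' @export
readPredictorsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "")
  df$eye_id <- as.character(df$eye_id)
  for (cn in setdiff(names(df), "eye_id")) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Summarise a cohort
#'
#' Echoes the descriptive statistics a reading of the cohort should be
#' checked against: eyes, tests per eye, follow-up, and the distribution of
#' dB sensitivities.
#'
#' @param cohort a [VFCohort-class].
#' @return data.frame of summary statistics (one row).
#' @export
cohortSummary <- function(cohort) {
  nt <- vapply(cohort@series, nTests, numeric(1))
  fu <- vapply(cohort@series, function(s) max(s@times), numeric(1))
  alldb <- unlist(lapply(cohort@series, function(s) as.numeric(s@sens)))
  labs <- progressionLabel(cohort)
  data.frame(
    n_eyes = length(cohort@series),
    n_tests_total = sum(nt),
    mean_tests = mean(nt), min_tests = min(nt), max_tests = max(nt),
    mean_follow_up = mean(fu), min_follow_up = min(fu),
    max_follow_up = max(fu),
    mean_db = mean(alldb), median_db = stats::median(alldb),
    sd_db = stats::sd(alldb),
    n_stable = sum(labs == "stable"),
    n_progressing = sum(labs == "progressing"),
    n_unknown = sum(labs == "unknown")
  )
}
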