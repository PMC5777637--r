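#' Clustered panel dataset of joint activity and damage
#'
#' Long-format panel data: one row per (patient, visit, joint) with the visit
#' time in years since the patient's first visit, a binary activity indicator
#' and a binary damage indicator, plus per-patient covariates.  Each visit
#' must record all 28 hand joints at a common time; damage is irreversible so
#' the damage indicator must be non-decreasing within a joint; every patient
#' must have at least three visits (so at least one interval is usable after
#' the first interval is dropped for the AMA dynamic covariate).
#'
#' @param obs `data.frame` with columns `patient_id`, `visit`, `time_years`,
#'   `joint_id`, `active`, `damaged`.
#' @param patients `data.frame` with columns `patient_id`, `sex` (male = 1),
#'   `age_onset` (years), `entry_duration` (arthritis duration at clinic
#'   entry, years).
#' @param layout Joint layout table; defaults to [joint_layout()].
#' @param validate Run [validate_panel()] (default `TRUE`).
#'
#' @return An object of class `jm_panel`: a list with elements `obs`
#'   (data.table), `patients` (data.table) and `layout`.
#' @export
panel_data <- function(obs, patients, layout = joint_layout(),
                       validate = TRUE) {
  obs <- as.data.table(obs)
  patients <- as.data.table(patients)
  setkey(obs, patient_id, visit, joint_id)
  setkey(patients, patient_id)
  x <- structure(list(obs = obs, patients = patients, layout = layout),
                 class = "jm_panel")
  if (validate) {
    problems <- validate_panel(x)
    if (length(problems)) {
      stop("invalid panel dataset:\n  ",
           paste(utils::head(problems, 25), collapse = "\n  "),
           if (length(problems) > 25) {
             sprintf("\n  ... and %d more problems", length(problems) - 25)
           } else "")
    }
  }
  x
}

#' Validate a panel dataset
#'
#' Checks all structural invariants and returns every violation found (not
#' just the first): required columns, binary indicators, exactly 28 joint rows
#' per visit with a common time, strictly increasing visit times, at least
#' three visits per patient, irreversible damage, and patient covariates
#' present for every patient.
#'
#' @param x A `jm_panel` (or a list with `obs`/`patients` components).
#' @return Character vector of problem descriptions; empty if valid.
#' @export
validate_panel <- function(x) {
  problems <- character()
  obs <- as.data.table(x$obs)
  patients <- as.data.table(x$patients)
  need <- c("patient_id", "visit", "time_years", "joint_id", "active",
            "damaged")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    return(paste("missing observation columns:", paste(miss, collapse = ", ")))
  }
  needp <- c("patient_id", "sex", "age_onset", "entry_duration")
  missp <- setdiff(needp, names(patients))
  if (length(missp)) {
    problems <- c(problems, paste("missing patient columns:",
                                  paste(missp, collapse = ", ")))
  }
  if (anyNA(obs[, ..need])) {
    problems <- c(problems, "missing values in required observation columns")
  }
  for (col in c("active", "damaged")) {
    bad <- which(!(obs[[col]] %in% c(0, 1)))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "column '%s' not binary at row(s) %s", col,
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  # duplicates
  dup <- duplicated(obs, by = c("patient_id", "visit", "joint_id"))
  if (any(dup)) {
    problems <- c(problems, sprintf(
      "duplicate (patient, visit, joint) rows: %d (first at row %d)",
      sum(dup), which(dup)[1]))
  }
  # 28 joints per visit, common time
  pv <- obs[, .(n_joints = .N, n_times = data.table::uniqueN(time_years)),
            by = .(patient_id, visit)]
  badj <- pv[pv$n_joints != 28, ]
  if (nrow(badj)) {
    problems <- c(problems, sprintf(
      "patient %s visit %d has %d joint rows (need 28)",
      badj$patient_id, badj$visit, badj$n_joints))
  }
  badt <- pv[pv$n_times != 1, ]
  if (nrow(badt)) {
    problems <- c(problems, sprintf(
      "patient %s visit %d has inconsistent times across joints",
      badt$patient_id, badt$visit))
  }
  # visit times strictly increasing, >= 3 visits
  per_pat <- obs[, .(time_years = time_years[1]),
                 by = .(patient_id, visit)]
  setkey(per_pat, patient_id, visit)
  inc <- per_pat[, .(ok = all(diff(time_years) > 0), m = .N),
                 by = patient_id]
  badi <- inc[!inc$ok, ]
  if (nrow(badi)) {
    problems <- c(problems, sprintf(
      "patient %s: visit times not strictly increasing (zero-length or negative interval)",
      badi$patient_id))
  }
  badm <- inc[inc$m < 3, ]
  if (nrow(badm)) {
    problems <- c(problems, sprintf(
      "patient %s has only %d visit(s); patients must have more than two clinic visits",
      badm$patient_id, badm$m))
  }
  # irreversible damage
  setkey(obs, patient_id, joint_id, visit)
  rev <- obs[, .(ok = !is.unsorted(damaged)), by = .(patient_id, joint_id)]
  badr <- rev[!rev$ok, ]
  if (nrow(badr)) {
    problems <- c(problems, sprintf(
      "patient %s joint %d: damage indicator decreases (damage is irreversible)",
      badr$patient_id, badr$joint_id))
  }
  # patient covariates present
  missing_pat <- setdiff(unique(obs$patient_id), patients$patient_id)
  if (length(missing_pat)) {
    problems <- c(problems, sprintf(
      "no patient covariates for patient %s", missing_pat))
  }
  setkey(obs, patient_id, visit, joint_id)
  problems
}

#' @export
print.jm_panel <- function(x, ...) {
  np <- nrow(x$patients)
  nv <- nrow(unique(x$obs[, c("patient_id", "visit")]))
  cat(sprintf("<jm_panel> %d patients, %d visits, %d joint observations\n",
              np, nv, nrow(x$obs)))
  invisible(x)
}

#' Observed mover indicator c*
#'
#' `c* = 1` if the patient has any damaged joint at the last clinic visit
#' (such a patient must be a mover), `c* = 0` otherwise.  Because damage is
#' irreversible, `c* = 0` is equivalent to the patient never showing damage.
#'
#' @param panel A [panel_data()] object.
#' @return Named integer vector (one entry per patient).
#' @export
observed_mover_indicator <- function(panel) {
  obs <- as.data.table(panel$obs)
  cs <- obs[, .(cstar = as.integer(any(damaged[visit == max(visit)] == 1))),
            by = patient_id]
  setNames(cs$cstar, as.character(cs$patient_id))
}

#' Read a panel dataset from CSV
#'
#' The CSV is comma separated with a header, one row per (patient, visit,
#' joint), columns `patient_id`, `visit`, `time_years`, `joint_id`, `active`,
#' `damaged`, `sex`, `age_onset`, `entry_duration` (the per-patient covariates
#' repeated on each row).  All validation problems are reported together.
#'
#' @param path File path.
#' @param layout Optional joint layout table (defaults to [joint_layout()]).
#' @return A [panel_data()] object.
#' @export
read_panel_csv <- function(path, layout = joint_layout()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path)
  need <- c("patient_id", "visit", "time_years", "joint_id", "active",
            "damaged", "sex", "age_onset", "entry_duration")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  }
  patients <- unique(dt[, .(patient_id, sex, age_onset, entry_duration)])
  if (anyDuplicated(patients$patient_id)) {
    stop("inconsistent patient covariates for patient(s): ",
         paste(patients$patient_id[duplicated(patients$patient_id)],
               collapse = ", "))
  }
  obs <- dt[, .(patient_id, visit, time_years, joint_id, active, damaged)]
  panel_data(obs, patients, layout = layout)
}

#' Write a panel dataset to CSV
#'
#' Inverse of [read_panel_csv()]; times are written in full precision decimal
#' years.
#'
#' @param panel A [panel_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  dt <- merge(as.data.table(panel$obs), as.data.table(panel$patients),
              by = "patient_id")
  setkey(dt, patient_id, visit, joint_id)
  fwrite(dt[, .(patient_id, visit, time_years, joint_id, active, damaged,
                sex, age_onset, entry_duration)], path)
  invisible(path)
}
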