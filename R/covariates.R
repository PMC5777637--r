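#' Anatomical layout of the 28 hand joints
#'
#' Fourteen joints per hand: metacarpophalangeal (MCP), proximal
#' interphalangeal (PIP) and distal interphalangeal (DIP) joints of the four
#' fingers, plus the thumb MCP and thumb PIP.  Joints 1-14 are the left hand,
#' 15-28 the right; contralateral pairing maps joint `k` to `k + 14` (and
#' back), so paired joints always share a type.
#'
#' @return A `data.frame` with columns `joint_id` (1-28), `hand` ("L"/"R"),
#'   `type` (factor with levels `MCP`, `PIP`, `DIP`, `thumb_MCP`,
#'   `thumb_PIP`; `thumb_PIP` is the reference level used for dummy coding)
#'   and `contralateral` (partner joint id).
#' @export
#' @examples
#' layout <- joint_layout()
#' table(layout$type)
joint_layout <- function() {
  types_one_hand <- c("thumb_MCP", "thumb_PIP",
                      rep(c("MCP", "PIP", "DIP"), 4))
  data.frame(
    joint_id = 1:28,
    hand = rep(c("L", "R"), each = 14),
    type = factor(rep(types_one_hand, 2),
                  levels = c("thumb_PIP", "MCP", "PIP", "DIP", "thumb_MCP")),
    contralateral = c(15:28, 1:14)
  )
}

# joint-type dummy columns (thumb_PIP reference)
layout_dummies <- function(layout) {
  data.frame(
    joint_id = layout$joint_id,
    jt_mcp = as.numeric(layout$type == "MCP"),
    jt_pip = as.numeric(layout$type == "PIP"),
    jt_dip = as.numeric(layout$type == "DIP"),
    jt_thumb_mcp = as.numeric(layout$type == "thumb_MCP")
  )
}

#' Adjusted mean activity (AMA)
#'
#' The AMA at time `t` is the time average of the activity path,
#' `(1/t) * integral of x(s) ds` from the first observation to `t`.  Because
#' activity is observed only at clinic visits, the integral is approximated by
#' the area under the linear interpolant of the observed binary activity
#' values.  Time is measured from the first observation, so the AMA is
#' undefined at the first visit.
#'
#' @param times Strictly increasing numeric vector of observation times.
#' @param activity Binary (0/1) activity values observed at `times`.
#' @param t Evaluation time; must coincide with one of `times` and be strictly
#'   after the first.
#'
#' @return AMA value in `[0, 1]`.
#' @export
#' @examples
#' compute_ama(c(0, 1, 2, 3, 5), c(0, 1, 0, 0, 1), 5)  # 0.4
compute_ama <- function(times, activity, t) {
  if (length(times) != length(activity)) {
    stop("times and activity must have the same length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(activity %in% c(0, 1))) stop("activity must be binary (0/1)")
  k <- which(abs(times - t) <= 1e-9)
  if (!length(k)) stop("t must equal one of the observation times")
  k <- k[1]
  if (k == 1) {
    stop("AMA is undefined at the first observation time; ",
         "it requires previous observations")
  }
  tt <- times[1:k] - times[1]
  xx <- activity[1:k]
  area <- sum(diff(tt) * (head(xx, -1) + xx[-1]) / 2)
  area / tt[k]
}

# vectorized cumulative AMA along one joint's visit history; NA at visit 1
ama_path <- function(times, activity) {
  n <- length(times)
  if (n == 1) return(NA_real_)
  tt <- times - times[1]
  seg <- diff(tt) * (activity[-n] + activity[-1]) / 2
  c(NA_real_, cumsum(seg) / tt[-1])
}

#' Number of damaged joints attained at a visit
#'
#' Counts how many of the patient's 28 joints are recorded as damaged at the
#' given visit.  Because damage is irreversible the count is non-decreasing
#' over visits.
#'
#' @param panel A [panel_data()] object.
#' @param patient_id Patient identifier.
#' @param visit Visit index.
#' @return Integer count in 0..28.
#' @export
attained_damaged_count <- function(panel, patient_id, visit) {
  obs <- as.data.frame(panel$obs)
  rows <- obs[obs$patient_id == patient_id & obs$visit == visit, ]
  if (nrow(rows) == 0) stop("no such visit for patient ", patient_id)
  missing_joints <- setdiff(1:28, rows$joint_id)
  if (length(missing_joints)) {
    stop("missing joint rows at patient ", patient_id, " visit ", visit,
         ": joints ", paste(missing_joints, collapse = ", "))
  }
  sum(rows$damaged)
}

#' Contralateral joint damage indicator
#'
#' Returns 1 if the anatomically matching joint in the opposite hand is
#' damaged at the same visit, 0 otherwise.
#'
#' @inheritParams attained_damaged_count
#' @param joint_id Joint identifier (1-28).
#' @param layout Joint layout table, defaults to [joint_layout()].
#' @return 0 or 1.
#' @export
opposite_damaged <- function(panel, patient_id, joint_id, visit,
                             layout = joint_layout()) {
  partner <- layout$contralateral[match(joint_id, layout$joint_id)]
  if (is.na(partner)) stop("joint ", joint_id, " has no contralateral partner")
  obs <- as.data.frame(panel$obs)
  row <- obs[obs$patient_id == patient_id & obs$visit == visit &
               obs$joint_id == partner, ]
  if (nrow(row) == 0) {
    stop("contralateral joint ", partner, " not observed at patient ",
         patient_id, " visit ", visit)
  }
  as.numeric(row$damaged[1])
}

#' Build the covariate table for every (patient, visit, joint)
#'
#' Assembles the covariate vector used in the transition-intensity (and
#' sojourn/jump) regressions: the adjusted mean activity [compute_ama()], the
#' attained damaged-joint count, the contralateral damage indicator, joint-type
#' dummies (thumb PIP reference), sex, age at arthritis onset and arthritis
#' duration (duration at clinic entry plus time since first visit, years).
#' Covariates at visit `j` use only information available at `t_ij`; they are
#' treated as constant over the interval `(t_ij, t_ij+1]`.
#'
#' @param panel A [panel_data()] object.
#' @param layout Joint layout table, defaults to the panel's layout.
#' @param baseline_ama_proxy If `TRUE`, the AMA at the first visit is proxied
#'   by the activity observed there (so the first interval becomes usable);
#'   default `FALSE` leaves it `NA`.
#'
#' @return A `data.table` keyed by (`patient_id`, `visit`, `joint_id`) with
#'   columns `ama`, `attained_count`, `opposite_damaged`, `jt_mcp`, `jt_pip`,
#'   `jt_dip`, `jt_thumb_mcp`, `sex`, `age_onset`, `duration`.  Rows cover
#'   visits 1..(m_i - 1), i.e. the visits opening each observation interval;
#'   `ama` is `NA` at visit 1 unless proxied.
#' @export
build_covariates <- function(panel, layout = NULL,
                             baseline_ama_proxy = FALSE) {
  stopifnot(inherits(panel, "jm_panel"))
  if (is.null(layout)) layout <- panel$layout
  obs <- as.data.table(panel$obs)
  setkey(obs, patient_id, joint_id, visit)
  obs[, ama := ama_path(time_years, active), by = .(patient_id, joint_id)]
  if (baseline_ama_proxy) {
    obs[visit == 1, ama := as.numeric(active)]
  }
  # attained damaged count per (patient, visit)
  counts <- obs[, .(attained_count = sum(damaged)), by = .(patient_id, visit)]
  obs <- merge(obs, counts, by = c("patient_id", "visit"))
  # contralateral damage at the same visit
  partner <- data.table(joint_id = layout$joint_id,
                        partner = layout$contralateral)
  obs <- merge(obs, partner, by = "joint_id")
  opp <- obs[, .(patient_id, visit, joint_id = partner, opp_dmg = damaged)]
  obs <- merge(obs, opp, by = c("patient_id", "visit", "joint_id"))
  setnames(obs, "opp_dmg", "opposite_damaged")
  obs[, opposite_damaged := as.numeric(opposite_damaged)]
  dum <- as.data.table(layout_dummies(layout))
  obs <- merge(obs, dum, by = "joint_id")
  pat <- as.data.table(panel$patients)
  obs <- merge(obs, pat, by = "patient_id")
  obs[, duration := entry_duration + time_years]
  # keep only visits that open an interval
  mvis <- obs[, .(m = max(visit)), by = patient_id]
  obs <- merge(obs, mvis, by = "patient_id")
  out <- obs[visit < m, .(patient_id, visit, joint_id, time_years,
                          active, damaged, ama, attained_count,
                          opposite_damaged, jt_mcp, jt_pip, jt_dip,
                          jt_thumb_mcp, sex, age_onset, duration)]
  setkey(out, patient_id, visit, joint_id)
  out[]
}
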