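#' Intrinsic-capacity domain scoring
#'
#' The five IC domains are each scored on the unit interval from a standard
#' instrument: locomotion from the Short Physical Performance Battery
#' (SPPB, 0-12 points), vitality from the SF-12 energy item (coded 1 =
#' highest energy .. 6 = lowest) combined with grip strength in kilograms,
#' psychology from the PHQ-9 depression total (0-27, higher = worse),
#' cognition from the MOCA total (0-30), and the sensory domain from four
#' self-ratings of hearing (left/right) and vision (far/near), each 1-5
#' with higher better.
#'
#' @name ic-scoring
NULL

#' IC domain names, in canonical order
#' @return Character vector of the five domain names.
#' @export
ic_domains <- function() {
  c("locomotion", "sensory", "psychology", "cognition", "vitality")
}

# Instrument maxima. The scoring formulas divide by the instrument maximum;
# these are the standard totals (SPPB 0-12, MOCA 0-30) and are exposed as
# configurable constants rather than hard-coded in the formulas.
#' Instrument maxima used by the scoring formulas
#' @return Named list with `sppb` and `moca` maxima.
#' @export
ic_constants <- function() list(sppb_max = 12, moca_max = 30)

#' Score the locomotion domain from an SPPB result
#'
#' The SPPB comprises a balance test, a gait-speed test and a chair-stand
#' test, each scored 0-4 points. The locomotion IC is the total divided by
#' the instrument maximum of 12.
#'
#' @param total SPPB total points (integer, 0-12). Alternatively supply the
#'   three components and leave `total` missing.
#' @param balance,gait,chair Component points (integers, 0-4 each); used
#'   only when `total` is missing.
#' @param sppb_max Instrument maximum (default 12).
#' @return Unit-interval locomotion score.
#' @examples
#' score_locomotion(6)                      # 0.5
#' score_locomotion(balance = 4, gait = 4, chair = 4)  # 1
#' @export
score_locomotion <- function(total = NULL, balance = NULL, gait = NULL,
                             chair = NULL, sppb_max = ic_constants()$sppb_max) {
  if (is.null(total)) {
    for (nm in c("balance", "gait", "chair")) {
      v <- get(nm)
      check_integerish(v, nm)
      check_range(v, 0, 4, nm)
    }
    total <- balance + gait + chair
  }
  check_integerish(total, "total")
  check_range(total, 0, sppb_max, "total")
  total / sppb_max
}

#' Score the vitality domain from energy level and grip strength
#'
#' Composite of the SF-12 energy item (answer code 1-6; 1 = most energy,
#' so `6 - answer` rewards energy) and measured grip strength in raw
#' kilograms: `min(0.13 * (6 - sf12_energy) + 0.09 * grip_kg, 1)`.
#' The coefficients come from a confirmatory factor analysis; grip strength
#' is deliberately not renormalized, so roughly 11 kg alone already
#' saturates the score -- the cap at 1 is doing real work for most adults.
#'
#' @param sf12_energy Answer code for the SF-12 energy item (integer 1-6).
#' @param grip_kg Grip strength in kilograms (non-negative).
#' @return Unit-interval vitality score.
#' @examples
#' score_vitality(1, 40)  # clamps to 1
#' score_vitality(5, 2)   # 0.31
#' @export
score_vitality <- function(sf12_energy, grip_kg) {
  check_integerish(sf12_energy, "sf12_energy")
  check_range(sf12_energy, 1, 6, "sf12_energy")
  if (!is.numeric(grip_kg) || length(grip_kg) != 1L || is.na(grip_kg) ||
      grip_kg < 0) {
    ic_stop("`grip_kg` must be a single non-negative number",
            "icapacity_range_error")
  }
  min(0.13 * (6 - sf12_energy) + 0.09 * grip_kg, 1)
}

#' Score the psychological domain from a PHQ-9 total
#'
#' Piecewise mapping over the widely adopted PHQ-9 severity cut-offs:
#' 1.00 for totals 0-4, 0.75 for 5-9, 0.50 for 10-14, 0.25 for 15-19, and
#' `(27 - PHQ) / 32` above 19, so the score falls linearly to 0 at the
#' instrument maximum of 27.
#'
#' @param phq_total PHQ-9 total (integer, 0-27).
#' @return Unit-interval psychology score.
#' @examples
#' score_psychology(3)   # 1
#' score_psychology(12)  # 0.5
#' score_psychology(22)  # 0.15625
#' @export
score_psychology <- function(phq_total) {
  check_integerish(phq_total, "phq_total")
  check_range(phq_total, 0, 27, "phq_total")
  if (phq_total <= 4) 1
  else if (phq_total <= 9) 0.75
  else if (phq_total <= 14) 0.5
  else if (phq_total <= 19) 0.25
  else (27 - phq_total) / 32
}

#' Score the cognition domain from a MOCA total
#'
#' The MOCA total scaled to the unit interval by the instrument maximum
#' of 30.
#'
#' @param moca_total MOCA total (integer, 0-30).
#' @param moca_max Instrument maximum (default 30).
#' @return Unit-interval cognition score.
#' @export
score_cognition <- function(moca_total, moca_max = ic_constants()$moca_max) {
  check_integerish(moca_total, "moca_total")
  check_range(moca_total, 0, moca_max, "moca_total")
  moca_total / moca_max
}

#' Score the sensory domain from hearing and vision self-ratings
#'
#' Four ratings (left/right hearing, far/near vision), each 1-5 with
#' higher better, summed and divided by the joint maximum of 20.
#'
#' @param h_left,h_right,v_far,v_near Ratings (integers 1-5).
#' @return Unit-interval sensory score.
#' @export
score_sensory <- function(h_left, h_right, v_far, v_near) {
  vals <- c(h_left = h_left, h_right = h_right, v_far = v_far, v_near = v_near)
  for (nm in names(vals)) {
    check_integerish(vals[[nm]], nm)
    check_range(vals[[nm]], 1, 5, nm)
  }
  sum(vals) / 20
}

#' Construct an IC profile
#'
#' @param locomotion,sensory,psychology,cognition,vitality Unit-interval
#'   scores or `NA` for "unavailable".
#' @return An `ic_profile`: named numeric vector of length 5 (NA =
#'   unavailable) with class `ic_profile`.
#' @export
ic_profile <- function(locomotion = NA_real_, sensory = NA_real_,
                       psychology = NA_real_, cognition = NA_real_,
                       vitality = NA_real_) {
  p <- c(locomotion = locomotion, sensory = sensory, psychology = psychology,
         cognition = cognition, vitality = vitality)
  p <- vapply(p, as.numeric, numeric(1))
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) {
    ic_stop(sprintf("profile scores must lie in [0,1]; offending: %s",
                    paste(names(p)[!ok], collapse = ", ")),
            "icapacity_range_error")
  }
  structure(p, class = "ic_profile")
}

#' @export
print.ic_profile <- function(x, ...) {
  cat("Intrinsic-capacity profile (0-1; NA = unavailable)\n")
  for (d in names(x)) {
    cat(sprintf("  %-11s %s\n", d,
                if (is.na(x[[d]])) "unavailable" else format(round(x[[d]], 4))))
  }
  invisible(x)
}

# Pull one scalar field out of a record (named list or 1-row data.frame);
# NULL / NA both count as missing.
record_field <- function(record, name) {
  v <- record[[name]]
  if (is.null(v) || length(v) == 0L || is.na(v)) NULL else v
}

#' Compute a full IC profile from one subject-wave record
#'
#' Scores every domain whose instrument inputs are present in the record
#' and marks the others unavailable (`NA`). Missing inputs never raise;
#' malformed present values do, naming the offending field. The record is
#' a named list or one-row data frame using the canonical variable names of
#' [ic_data_dictionary()]: `sppb_balance`, `sppb_gait`, `sppb_chair` (or
#' `sppb_total`), `hear_left`, `hear_right`, `vision_far`, `vision_near`,
#' `phq9_total`, `moca_total`, `sf12_q10`, `grip_kg`.
#'
#' @param record Named list or one-row data frame.
#' @return An [ic_profile()].
#' @examples
#' compute_profile(list(phq9_total = 12))  # psychology 0.5, rest unavailable
#' @export
compute_profile <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  loco <- {
    tot <- record_field(record, "sppb_total")
    b <- record_field(record, "sppb_balance")
    g <- record_field(record, "sppb_gait")
    ch <- record_field(record, "sppb_chair")
    if (!is.null(tot)) score_locomotion(tot)
    else if (!is.null(b) && !is.null(g) && !is.null(ch))
      score_locomotion(balance = b, gait = g, chair = ch)
    else NA_real_
  }
  sens <- {
    nms <- c("hear_left", "hear_right", "vision_far", "vision_near")
    r <- lapply(nms, record_field, record = record)
    if (any(vapply(r, is.null, logical(1)))) NA_real_
    else {
      for (j in seq_along(nms)) {  # errors must name the record field
        check_integerish(r[[j]], nms[j])
        check_range(r[[j]], 1, 5, nms[j])
      }
      score_sensory(r[[1]], r[[2]], r[[3]], r[[4]])
    }
  }
  psy <- {
    p <- record_field(record, "phq9_total")
    if (is.null(p)) NA_real_ else score_psychology(p)
  }
  cog <- {
    m <- record_field(record, "moca_total")
    if (is.null(m)) NA_real_ else score_cognition(m)
  }
  vit <- {
    e <- record_field(record, "sf12_q10")
    g <- record_field(record, "grip_kg")
    if (is.null(e) || is.null(g)) NA_real_ else score_vitality(e, g)
  }
  ic_profile(locomotion = loco, sensory = sens, psychology = psy,
             cognition = cog, vitality = vit)
}
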