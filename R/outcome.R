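#' Construct an infant clinical record
#'
#' Flat container for the clinical items the outcome engine consumes:
#' cord and infant blood gases, the six-item structured neurologic (ENE /
#' Sarnat) exam, resuscitation and NICU flags, Apgar scores and timing
#' fields.
#'
#' @param infant_id identifier.
#' @param cord_gases data.frame with columns `source` ("arterial" or
#'   "venous"), `pH`, `base_deficit` (mmol/L); may have zero rows.
#' @param infant_gases data.frame with columns `age_h`, `source`, `pH`,
#'   `base_deficit`; may have zero rows.
#' @param ene_abnormal_items worst count of abnormal Sarnat items between
#'   1 and 6 h of age (0-6).
#' @param ene_recorded was an ENE documented at all.
#' @param abnormal_exam_ge_6h abnormal neurologic exam persisting to or
#'   beyond 6 h of age.
#' @param seizures_first_24h confirmed seizures in the first 24 h.
#' @param hypothermia therapeutic hypothermia of any kind (passive,
#'   active or transient).
#' @param apgar5,apgar10 Apgar scores (0-10).
#' @param nicu_admit,discharged_home,death_or_transfer logical flags.
#' @param death_age_h age at death in hours, or `NA`.
#' @param intubation_or_compressions required intubation or chest
#'   compressions during newborn resuscitation.
#' @param seizure_meds seizure medications prescribed.
#' @param hie_imaging_pattern radiographic injury pattern suggestive of
#'   hypoxic-ischemic injury (deep grey matter or watershed).
#' @return a list of class `infant_record`.
#' @export
infant_record <- function(infant_id,
                          cord_gases = data.frame(),
                          infant_gases = data.frame(),
                          ene_abnormal_items = 0L, ene_recorded = FALSE,
                          abnormal_exam_ge_6h = FALSE,
                          seizures_first_24h = FALSE,
                          hypothermia = FALSE,
                          apgar5 = 9L, apgar10 = NA_integer_,
                          nicu_admit = FALSE, discharged_home = TRUE,
                          death_or_transfer = FALSE,
                          death_age_h = NA_real_,
                          intubation_or_compressions = FALSE,
                          seizure_meds = FALSE,
                          hie_imaging_pattern = FALSE) {
  stopifnot(ene_abnormal_items >= 0, ene_abnormal_items <= 6,
            is.na(death_age_h) || death_age_h >= 0)
  structure(as.list(environment()), class = "infant_record")
}

#' Neonatal acidosis predicate
#'
#' Acidosis is present when the lowest-pH umbilical cord gas (arterial or
#' venous) has pH below 7.0 or base deficit of 10 mmol/L or more, or the
#' first infant blood gas drawn before 2 h of age (any source) has base
#' deficit of 10 mmol/L or more.
#'
#' @param rec an [infant_record()].
#' @return a list: `status` (`"acidotic"`, `"not_acidotic"` or
#'   `"no_gas"`) and `evidence` (text).
#' @export
is_acidotic <- function(rec) {
  cg <- rec$cord_gases
  ig <- rec$infant_gases
  early_ig <- if (nrow(ig)) ig[ig$age_h < 2, , drop = FALSE] else ig
  has_gas <- nrow(cg) > 0 || nrow(ig) > 0
  if (!has_gas) return(list(status = "no_gas", evidence = "no blood gas"))
  if (nrow(cg)) {
    worst <- cg[which.min(cg$pH), ]
    if (worst$pH < 7.0)
      return(list(status = "acidotic",
                  evidence = sprintf("cord pH %.2f < 7.0", worst$pH)))
    if (worst$base_deficit >= 10)
      return(list(status = "acidotic",
                  evidence = sprintf("cord BD %.1f >= 10",
                                     worst$base_deficit)))
  }
  if (nrow(early_ig)) {
    first <- early_ig[which.min(early_ig$age_h), ]
    if (first$base_deficit >= 10)
      return(list(status = "acidotic",
                  evidence = sprintf("infant BD %.1f >= 10 at %.1f h",
                                     first$base_deficit, first$age_h)))
  }
  list(status = "not_acidotic", evidence = "gases present, none qualify")
}

# The "healthy" conjunction shared by both healthy study groups.
healthy_conditions <- function(rec) {
  !is.na(rec$apgar5) && rec$apgar5 >= 7 &&
    !rec$nicu_admit && rec$discharged_home && !rec$death_or_transfer &&
    rec$ene_abnormal_items == 0 &&
    !rec$intubation_or_compressions &&
    !rec$seizures_first_24h && !rec$seizure_meds &&
    !rec$hypothermia
}

#' Assign the eight-way perinatal study group
#'
#' Evaluates the mutually exclusive outcome definitions in fixed
#' precedence: death under 6 h; perinatal HIE (acidosis, encephalopathy
#' score above 0, and at least one of therapeutic hypothermia, abnormal
#' exam persisting to 6 h, or confirmed seizures in the first 24 h);
#' distant/atypical HIE (imaging pattern without meeting perinatal HIE);
#' acidosis without HIE; then the healthy/intervention split within the
#' no-gas and gas branches.  Acidotic infants with an abnormal
#' encephalopathy score but none of the three confirmatory criteria match
#' no printed definition and are reported as unclassified rather than
#' silently binned.
#'
#' @param rec an [infant_record()].
#' @return a list: `group` (one of `PERINATAL_HIE`, `ACIDOSIS_NO_HIE`,
#'   `HEALTHY_NO_BG`, `HEALTHY_NO_ACIDOSIS`, `INTERVENTION_NO_BG`,
#'   `INTERVENTION_NO_ACIDOSIS`, `DISTANT_HIE`, `DEATH_UNDER_6H`,
#'   `UNCLASSIFIED`) and `evidence` (the decision trail).
#' @export
classify_study_group <- function(rec) {
  trail <- character(0)
  if (!is.na(rec$death_age_h) && rec$death_age_h < 6)
    return(list(group = "DEATH_UNDER_6H",
                evidence = sprintf("died at %.1f h", rec$death_age_h)))
  acid <- is_acidotic(rec)
  trail <- c(trail, paste0("acidosis: ", acid$status,
                           " (", acid$evidence, ")"))
  confirmatory <- rec$hypothermia || rec$abnormal_exam_ge_6h ||
    rec$seizures_first_24h
  if (acid$status == "acidotic" && rec$ene_abnormal_items > 0 &&
      confirmatory)
    return(list(group = "PERINATAL_HIE",
                evidence = paste(trail, collapse = "; ")))
  if (rec$hie_imaging_pattern)
    return(list(group = "DISTANT_HIE",
                evidence = paste(c(trail, "HIE imaging pattern"),
                                 collapse = "; ")))
  if (acid$status == "acidotic") {
    if (rec$ene_abnormal_items == 0 && !confirmatory)
      return(list(group = "ACIDOSIS_NO_HIE",
                  evidence = paste(trail, collapse = "; ")))
    # abnormal score without confirmation (or confirmation without
    # score): matches no printed definition
    return(list(group = "UNCLASSIFIED",
                evidence = paste(c(trail,
                  "acidotic with partial encephalopathy criteria"),
                  collapse = "; ")))
  }
  healthy <- healthy_conditions(rec)
  if (acid$status == "no_gas") {
    grp <- if (healthy) "HEALTHY_NO_BG" else "INTERVENTION_NO_BG"
  } else {
    grp <- if (healthy) "HEALTHY_NO_ACIDOSIS" else
      "INTERVENTION_NO_ACIDOSIS"
  }
  list(group = grp, evidence = paste(trail, collapse = "; "))
}

#' Grade the severity of perinatal HIE
#'
#' Moderate-to-severe HIE: three or more abnormal items on the worst
#' neurologic exam between 1 and 6 h of age, or seizures; otherwise mild.
#'
#' @param rec an [infant_record()] classified as perinatal HIE.
#' @return `"moderate_severe"` or `"mild"`.
#' @export
hie_severity <- function(rec) {
  grp <- classify_study_group(rec)$group
  if (grp != "PERINATAL_HIE")
    stop("hie_severity() is defined only for perinatal HIE records")
  if (rec$ene_abnormal_items >= 3 || rec$seizures_first_24h)
    "moderate_severe" else "mild"
}

#' Classify a cohort of infant records
#'
#' @param records list of [infant_record()] objects.
#' @return data.frame: `infant_id`, `group`, `severity` (for perinatal
#'   HIE), `evidence`.
#' @export
classify_cohort <- function(records) {
  rows <- lapply(records, function(r) {
    cls <- classify_study_group(r)
    sev <- if (cls$group == "PERINATAL_HIE") hie_severity(r)
      else NA_character_
    data.frame(infant_id = r$infant_id, group = cls$group,
               severity = sev, evidence = cls$evidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
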