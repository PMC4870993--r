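# Small in-code fixtures and a memoised large simulation shared by the
# calibration checks.

make_baseline <- function(patient_id = "P1", age = 70, gender = "female",
                          ethnicity = "caucasian", diagnosis = "poag",
                          lens_status = "phakic", shaffer_grade = "IV",
                          vf_stage = "mild", cup_disc = 0.7, va_logmar = 0.3,
                          baseline_iop = 30, baseline_meds = 2,
                          surgery = "trabectome_alone") {
  tibble::tibble(patient_id = patient_id, age = age, gender = gender,
                 ethnicity = ethnicity, diagnosis = diagnosis,
                 lens_status = lens_status, shaffer_grade = shaffer_grade,
                 vf_stage = vf_stage, cup_disc = cup_disc,
                 va_logmar = va_logmar, baseline_iop = baseline_iop,
                 baseline_meds = baseline_meds, surgery = surgery)
}

make_visits <- function(patient_id, days, iop, meds = 0,
                        secondary = FALSE) {
  tibble::tibble(patient_id = patient_id, day = as.integer(days),
                 iop = iop, meds = as.integer(rep_len(meds, length(days))),
                 secondary_surgery = rep_len(secondary, length(days)))
}

# one patient with a given baseline IOP and a visit stream
one_patient_cohort <- function(baseline_iop, days, iop, secondary = FALSE,
                               id = "P1") {
  new_cohort(make_baseline(patient_id = id, baseline_iop = baseline_iop),
             make_visits(id, days, iop, secondary = secondary))
}

.sim_cache <- new.env(parent = emptyenv())

# default-configuration simulation used by the calibration checks
default_sim <- function(n = 5000, seed = 42) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- generate_cohort(
      cohort_config(n_patients = n, seed = seed))
  }
  .sim_cache[[key]]
}
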