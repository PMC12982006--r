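# hand-built delivery records for exclusion / tally tests
make_record <- function(facility_id = "F001", year = 2020L, ga_days = 270L,
                        birth_order = 1L, n_fetuses = 1L,
                        stillbirth_status = "livebirth", parity = 1L,
                        infertility_treatment = 0L, neonatal_sex = "F",
                        maternal_age = 30, birth_weight = 3000,
                        blood_loss = 400, maternal_survival = 1L,
                        tpl = 0L, hdp = 0L, pprom = 0L, previa = 0L,
                        multiple = 0L, fgr = 0L, abruption = 0L,
                        transfer_in = 0L, cesarean = 0L, cesarean_grade1 = 0L,
                        acs_checkbox = 0L, acs_dose = NA_real_,
                        acs_interval = NA_character_) {
  data.frame(facility_id = facility_id, year = year, ga_days = ga_days,
             birth_order = birth_order, n_fetuses = n_fetuses,
             stillbirth_status = stillbirth_status, parity = parity,
             infertility_treatment = infertility_treatment,
             neonatal_sex = neonatal_sex, maternal_age = maternal_age,
             birth_weight = birth_weight, blood_loss = blood_loss,
             maternal_survival = maternal_survival, tpl = tpl, hdp = hdp,
             pprom = pprom, previa = previa, multiple = multiple, fgr = fgr,
             abruption = abruption, transfer_in = transfer_in,
             cesarean = cesarean, cesarean_grade1 = cesarean_grade1,
             acs_checkbox = acs_checkbox, acs_dose = acs_dose,
             acs_interval = acs_interval, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_facilities = 25L, years = 2020:2021, seed = 101L)
  do.call(registry_config, utils::modifyList(defaults, args))
}
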