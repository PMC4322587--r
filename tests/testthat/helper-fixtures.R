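# Programmatic fixtures: hand-built schema rows and a shared simulated
# colony reused across test files (computed once per run).

FILE_DATE <- as.Date("2014-06-06")  # reference "today" for living ages

# Build a schema-complete animal-list data.frame from per-individual vectors.
make_animals <- function(dlc_id, sex = "F", dob, dod = NA,
                         taxon = "CMED", gestation = 60,
                         birth_type = "CB", birth_inst = "Duke Prim",
                         estimated_dob = NA_character_,
                         dam_id = NA_character_, dam_dob = NA,
                         sire_id = NA_character_, sire_dob = NA,
                         litter_size = NA_integer_,
                         current_resident = "N",
                         age_last_verified = NA_real_) {
  n <- length(dlc_id)
  dob <- as.Date(dob)
  dod <- as.Date(rep_len(if (all(is.na(dod))) as.Date(NA) else dod, n))
  dam_dob <- as.Date(rep_len(if (all(is.na(dam_dob))) as.Date(NA)
                             else dam_dob, n))
  sire_dob <- as.Date(rep_len(if (all(is.na(sire_dob))) as.Date(NA)
                              else sire_dob, n))
  gestation <- rep_len(gestation, n)
  concep <- dob - gestation
  age_death <- round(as.numeric(dod - dob) / 365, 6)
  age_lastver <- rep_len(age_last_verified, n)
  age_living <- ifelse(is.na(age_death) & is.na(age_lastver),
                       round(as.numeric(FILE_DATE - dob) / 365, 6), NA_real_)
  df <- data.frame(
    Taxon = rep_len(taxon, n), DLC_ID = as.character(dlc_id),
    Hybrid = "N", Sex = rep_len(sex, n), Name = paste0("A", dlc_id),
    Current_Resident = rep_len(current_resident, n),
    StudBook = NA_character_, DOB = dob, Birth_Month = lemurlife:::month_of(dob),
    Estimated_DOB = rep_len(estimated_dob, n),
    Birth_Type = rep_len(birth_type, n),
    Birth_Institution = rep_len(birth_inst, n),
    Litter_Size = rep_len(litter_size, n),
    Expected_Gestation_d = gestation,
    Estimated_Concep = concep, Concep_Month = lemurlife:::month_of(concep),
    Dam_ID = rep_len(dam_id, n), Dam_Name = NA_character_,
    Dam_Taxon = NA_character_, Dam_DOB = dam_dob,
    Dam_AgeAtConcep_y = round(as.numeric(concep - dam_dob) / 365, 6),
    Sire_ID = rep_len(sire_id, n), Sire_Name = NA_character_,
    Sire_Taxon = NA_character_, Sire_DOB = sire_dob,
    Sire_AgeAtConcep_y = round(as.numeric(concep - sire_dob) / 365, 6),
    DOD = dod, AgeAtDeath_y = age_death, AgeOfLiving_y = age_living,
    AgeLastVerified_y = age_lastver,
    AgeMax_LiveOrDead_y = pmax(age_death, age_living, age_lastver,
                               na.rm = TRUE),
    N_known_offspring = 0L,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

# Build a minimal weight-file data.frame; derived columns filled directly.
make_weights <- function(dlc_id, dob, age_d, weight_g, sex = "F",
                         taxon = "CMED", gestation = 60,
                         birth_type = "CB", birth_inst = "Duke Prim",
                         dod = NA, min_dam_aac = 0.8,
                         preg_status = "NP") {
  n <- length(age_d)
  dob <- as.Date(rep_len(dob, n))
  dod <- as.Date(rep_len(if (all(is.na(dod))) as.Date(NA) else dod, n))
  wd <- dob + age_d
  df <- data.frame(
    Taxon = rep_len(taxon, n), Hybrid = "N",
    DLC_ID = rep_len(as.character(dlc_id), n), Sex = rep_len(sex, n),
    Name = "x", DOB = dob, Estimated_DOB = NA_character_,
    Weight_g = weight_g, Weight_Date = wd,
    MonthOfWeight = lemurlife:::month_of(wd),
    AgeAtWt_d = as.numeric(age_d),
    AgeAtWt_wk = round(age_d / 7, 6),
    AgeAtWt_mo = round(age_d / 365 * 12, 6),
    AgeAtWt_mo_NoDec = floor(age_d / 365 * 12),
    AgeAtWt_y = round(age_d / 365, 6),
    Days_Since_PrevWt = NA_real_, Change_Since_PrevWt_g = NA_real_,
    Avg_Daily_WtChange_g = NA_real_, DOD = dod,
    DaysBeforeDeath = as.numeric(dod - wd),
    Birth_Type = rep_len(birth_type, n),
    Birth_Institution = rep_len(birth_inst, n),
    Litter_Size = NA_integer_,
    R_Min_Dam_AgeAtConcep_y = rep_len(min_dam_aac, n),
    Age_Category = classify_age(round(age_d / 365, 6),
                                min_dam_aac[1]),
    Current_Resident = "N", Preg_Status = rep_len(preg_status, n),
    Expected_Gestation_d = rep_len(gestation, n),
    ConcepDate_IfPreg = as.Date(NA), InfantDOB_IfPreg = as.Date(NA),
    DaysBeforeInfBirth_IfPreg = NA_real_, Pct_PregRemain_IfPreg = NA_real_,
    InfantLitSz_IfPreg = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

# Shared simulated colony: one seasonal dwarf-lemur-like taxon, ~30 years,
# several hundred captive births. Computed once per test run.
.shared <- new.env()

shared_params <- function() {
  colony_params(taxon = "CMED", n_founders = 12, years_simulated = 30,
                gestation_d = 60, peak_concep_month = 11,
                adult_mass_g = 250, min_dam_age_y = 2)
}

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_colony(shared_params(), seed = 20260901)
  }
  .shared$sim
}

shared_table <- function() {
  if (is.null(.shared$table)) {
    sim <- shared_sim()
    .shared$table <- build_life_history_table(sim$animals, sim$weights)
  }
  .shared$table
}
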