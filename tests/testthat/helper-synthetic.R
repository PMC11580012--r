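# Shared fixtures: a small event vocabulary and compact generator configs
# so replicate studies stay fast.

small_dict_df <- data.frame(
  pt = c("EVT_A", "EVT_NULL", "EVT_B", "Cough", "Headache", "Rash"),
  soc = c("SOC alpha", "SOC alpha", "SOC beta",
          "Respiratory, thoracic and mediastinal disorders",
          "Nervous system disorders",
          "Skin and subcutaneous tissue disorders"),
  stringsAsFactors = FALSE
)

small_rates <- c(EVT_A = 0.005, EVT_NULL = 0.05, EVT_B = 0.02,
                 Cough = 0.10, Headache = 0.08, Rash = 0.05)

tiny_config <- function(seed = 1, n_target = 300, n_background = 5000,
                        planted = c(EVT_A = 20, EVT_NULL = 1), ...) {
  faers_sim_config(seed = seed, n_target_cases = n_target,
                   n_background_cases = n_background,
                   pt_dictionary = small_dict_df,
                   background_pt_rates = small_rates,
                   planted_signals = planted,
                   quarters = c("23Q1", "23Q2"), ...)
}

# assemble a case set straight from in-memory simulated tables
sim_case_set <- function(sim) {
  raw <- sim[c("demo", "drug", "reac", "ther", "indi", "outc", "deleted")]
  raw$quarters <- unique(sim$demo$quarter)
  case_set(raw)
}

# brute-force (case, PT) counting straight off the emitted tables: the
# oracle path shares no code with case_set()/build_event_records()
oracle_counts <- function(sim, pt,
                          target_names = c("mepolizumab", "nucala")) {
  kept <- setdiff(unique(sim$demo$caseid), sim$deleted)
  pat <- paste(target_names, collapse = "|")
  tgt_ids <- unique(sim$drug$caseid[
    sim$drug$role_cod == "PS" &
      grepl(pat, tolower(sim$drug$drugname)) &
      sim$drug$caseid %in% kept])
  rec <- unique(sim$reac[sim$reac$caseid %in% kept, c("caseid", "pt")])
  hit <- rec$pt == pt
  tgt <- rec$caseid %in% tgt_ids
  c(a = sum(hit & tgt), b = sum(!hit & tgt),
    c = sum(hit & !tgt), d = sum(!hit & !tgt))
}
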