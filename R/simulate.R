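#' Configuration for the synthetic claims generator
#'
#' Defines the study conditions a generated cohort emulates: elderly patients
#' with chronic regimens observed through a refill database up to an index
#' hospitalization. Chronic drugs produce refill chains whose inter-fill gaps
#' are the days supply plus a non-negative adherence delay (discretized
#' exponential); some chronic drugs are discontinued well before index; some
#' patients use an as-needed (PRN) drug with long irregular gaps; products
#' include combinations and OTC items; hospital stays occur at a Poisson rate.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param chronic_drugs_per_patient Poisson mean of the number of chronic
#'   drugs per patient.
#' @param days_supply_choices named numeric vector: days-supply values (names)
#'   with sampling weights.
#' @param refill_delay_mean_days mean of the discretized-exponential delay
#'   added to each refill beyond supply exhaustion (0 = perfect adherence).
#' @param prn_probability chance a patient uses a PRN drug.
#' @param prn_gap_range integer length-2 vector: min and max days between
#'   consecutive PRN fills (long and irregular by default).
#' @param discontinue_probability chance a chronic drug stops well before
#'   index.
#' @param combo_fraction fraction of dictionary products with two ingredients.
#' @param otc_fraction fraction of dictionary products flagged OTC.
#' @param hospitalization_rate hospital stays per patient-year.
#' @param observation_days_before_index length of the pre-index observation
#'   window, days.
#' @param post_index_days length of the post-index window in which refills
#'   continue, days.
#' @param n_products dictionary size.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 100,
                              seed = 1,
                              chronic_drugs_per_patient = 5,
                              days_supply_choices = c("30" = 0.60, "90" = 0.25,
                                                      "28" = 0.15),
                              refill_delay_mean_days = 4,
                              prn_probability = 0.4,
                              prn_gap_range = c(60, 250),
                              discontinue_probability = 0.2,
                              combo_fraction = 0.15,
                              otc_fraction = 0.10,
                              hospitalization_rate = 0.5,
                              observation_days_before_index = 365,
                              post_index_days = 60,
                              n_products = 60) {
  probs <- c(prn_probability, discontinue_probability, combo_fraction,
             otc_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  if (n_patients < 1 || n_products < 5)
    stop("n_patients must be >= 1 and n_products >= 5", call. = FALSE)
  if (observation_days_before_index <= 0 || post_index_days < 0)
    stop("observation window must be positive", call. = FALSE)
  if (chronic_drugs_per_patient < 0 || refill_delay_mean_days < 0 ||
      hospitalization_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (length(prn_gap_range) != 2 || any(prn_gap_range < 1) ||
      prn_gap_range[1] > prn_gap_range[2])
    stop("prn_gap_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  ds <- suppressWarnings(as.integer(names(days_supply_choices)))
  if (anyNA(ds) || any(ds <= 0) || any(days_supply_choices < 0) ||
      sum(days_supply_choices) <= 0)
    stop("days_supply_choices must map positive day values to non-negative weights",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 chronic_drugs_per_patient = chronic_drugs_per_patient,
                 days_supply_choices = days_supply_choices,
                 refill_delay_mean_days = refill_delay_mean_days,
                 prn_probability = prn_probability,
                 prn_gap_range = as.integer(prn_gap_range),
                 discontinue_probability = discontinue_probability,
                 combo_fraction = combo_fraction,
                 otc_fraction = otc_fraction,
                 hospitalization_rate = hospitalization_rate,
                 observation_days_before_index =
                   as.integer(observation_days_before_index),
                 post_index_days = as.integer(post_index_days),
                 n_products = as.integer(n_products)),
            class = "simulation_config")
}

route_form_table <- function() {
  list(oral = c("tablet", "capsule", "solution", "suspension"),
       inhalation = c("aerosol", "solution"),
       topical = "cream", transdermal = "patch", ophthalmic = "solution",
       subcutaneous = "solution", sublingual = "tablet", rectal = "other",
       other = "other")
}

generate_dictionary <- function(config) {
  n <- config$n_products
  routes <- sample(c("oral", "inhalation", "topical", "transdermal",
                     "ophthalmic", "subcutaneous", "sublingual", "rectal",
                     "other"), n, replace = TRUE,
                   prob = c(0.66, 0.08, 0.05, 0.04, 0.04, 0.04, 0.04, 0.02,
                            0.03))
  rf <- route_form_table()
  forms <- vapply(routes, function(r) sample(rep(rf[[r]], 2), 1), "")
  pool <- sprintf("ing%03d", seq_len(max(5, ceiling(n * 1.5))))
  is_combo <- stats::runif(n) < config$combo_fraction
  ingredients <- lapply(seq_len(n), function(i)
    sample(pool, if (is_combo[i]) 2 else 1))
  strengths <- paste0(sample(c(5, 10, 20, 25, 40, 50, 100), n, TRUE), " mg")
  dict <- data.frame(
    product_id = sprintf("P%04d", seq_len(n)),
    ingredients = I(ingredients),
    route = routes,
    dosage_form = forms,
    strength = strengths,
    rx_status = ifelse(stats::runif(n) < config$otc_fraction, "otc",
                       "prescription"),
    drug_type = sample(c("standard", "vitamin", "supplement", "herbal",
                         "other_cam"), n, TRUE,
                       prob = c(0.90, 0.04, 0.03, 0.02, 0.01)),
    common_use = ifelse(stats::runif(n) < 0.15, "as_needed", "regular"),
    is_supply = stats::runif(n) < 0.03,
    is_metered_dose_inhaler = FALSE,
    stringsAsFactors = FALSE
  )
  dict$is_metered_dose_inhaler <- dict$route == "inhalation" &
    dict$dosage_form == "aerosol"
  as_dictionary(dict)
}

#' Generate a synthetic refill-claims cohort
#'
#' Deterministic given the config seed. Returns the four claims tables the
#' counting pipeline consumes, plus a `truth` table recording, per patient,
#' the number of chronic drugs generated, how many were discontinued before
#' index, and whether a PRN drug was added — useful for oracle checks.
#'
#' @param config a [simulation_config()].
#' @return List with `dictionary`, `fills`, `hospitalizations`,
#'   `index_events`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)

  dict <- generate_dictionary(config)
  ds_vals <- as.integer(names(config$days_supply_choices))
  ds_wts <- as.numeric(config$days_supply_choices)
  chronic_pool <- dict$product_id[!dict$is_supply & dict$common_use == "regular"]
  prn_pool <- dict$product_id[!dict$is_supply & dict$common_use == "as_needed"]
  obs <- config$observation_days_before_index
  post <- config$post_index_days

  fills <- list()
  hosps <- list()
  index_events <- data.frame(patient_id = character(),
                             index_date = as.Date(character()))
  truth <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("S%05d", i)
    index_date <- as.Date("2008-01-01") + sample.int(365, 1) - 1L
    window_start <- index_date - obs

    k <- min(stats::rpois(1, config$chronic_drugs_per_patient),
             length(chronic_pool))
    drugs <- if (k > 0) sample(chronic_pool, k) else character()
    n_disc <- 0L
    for (p in drugs) {
      ds <- ds_vals[sample.int(length(ds_vals), 1, prob = ds_wts)]
      t <- window_start + sample.int(ds, 1) - 1L
      discontinued <- stats::runif(1) < config$discontinue_probability
      stop_date <- if (discontinued) {
        n_disc <- n_disc + 1L
        # stop long enough before index that the drug has clearly lapsed
        lo <- 2L * ds + 30L
        hi <- max(lo + 1L, as.integer(round(0.7 * obs)))
        index_date - sample(lo:hi, 1)
      } else index_date + post
      while (t < stop_date) {
        fills[[length(fills) + 1L]] <- list(pid, p, t, ds)
        delay <- if (config$refill_delay_mean_days > 0)
          floor(stats::rexp(1, 1 / config$refill_delay_mean_days)) else 0
        t <- t + ds + delay
      }
    }

    has_prn <- FALSE
    if (length(prn_pool) && stats::runif(1) < config$prn_probability) {
      has_prn <- TRUE
      p <- sample(rep(prn_pool, 2), 1)
      ds <- sample(c(9L, 14L, 30L), 1)
      t <- window_start + sample.int(120, 1) - 1L
      while (t < index_date + post) {
        fills[[length(fills) + 1L]] <- list(pid, p, t, ds)
        t <- t + sample(config$prn_gap_range[1]:config$prn_gap_range[2], 1)
      }
    }

    n_h <- stats::rpois(1, config$hospitalization_rate * (obs + post) / 365)
    for (j in seq_len(n_h)) {
      admit <- window_start + sample.int(obs + post, 1) - 1L
      los <- 1L + stats::rpois(1, 3)
      hosps[[length(hosps) + 1L]] <- list(pid, admit, admit + los)
    }

    index_events <- rbind(index_events,
                          data.frame(patient_id = pid, index_date = index_date))
    truth[[i]] <- data.frame(patient_id = pid, n_chronic = k,
                             n_discontinued = n_disc, has_prn = has_prn)
  }

  fdf <- if (length(fills)) {
    data.frame(patient_id = vapply(fills, `[[`, "", 1),
               product_id = vapply(fills, `[[`, "", 2),
               fill_date = as.Date(vapply(fills, function(x)
                 as.numeric(x[[3]]), 0), origin = "1970-01-01"),
               days_supply = vapply(fills, `[[`, 0L, 4),
               quantity = as.numeric(vapply(fills, `[[`, 0L, 4)),
               stringsAsFactors = FALSE)
  } else empty_fills()
  fdf <- fdf[order(fdf$patient_id, fdf$fill_date, fdf$product_id), ]
  rownames(fdf) <- NULL
  hdf <- if (length(hosps)) {
    data.frame(patient_id = vapply(hosps, `[[`, "", 1),
               admit_date = as.Date(vapply(hosps, function(x)
                 as.numeric(x[[2]]), 0), origin = "1970-01-01"),
               discharge_date = as.Date(vapply(hosps, function(x)
                 as.numeric(x[[3]]), 0), origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  } else data.frame(patient_id = character(),
                    admit_date = as.Date(character()),
                    discharge_date = as.Date(character()))
  hdf <- hdf[order(hdf$patient_id, hdf$admit_date), ]
  rownames(hdf) <- NULL

  list(dictionary = dict, fills = fdf, hospitalizations = hdf,
       index_events = index_events, truth = do.call(rbind, truth))
}

#' Write a generated cohort to a directory of CSV files
#'
#' Writes `dictionary.csv`, `fills.csv`, `hospitalizations.csv` and
#' `index.csv`; output is byte-identical across runs for the same config.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dictionary(cohort$dictionary, file.path(dir, "dictionary.csv"))
  write_fills(cohort$fills, file.path(dir, "fills.csv"))
  write_hospitalizations(cohort$hospitalizations,
                         file.path(dir, "hospitalizations.csv"))
  write_index_events(cohort$index_events, file.path(dir, "index.csv"))
  invisible(dir)
}

#' The packaged hypothetical-patient fixture
#'
#' A worked fill history for one patient: three chronic drugs refilled
#' monthly (an estradiol transdermal patch with 28-day supplies, metoprolol
#' succinate and an ezetimibe/simvastatin combination with 30-day supplies),
#' one as-needed sublingual nitroglycerin fill 73 days before index, a
#' hospital admission on 2008-07-01 (the index date) with discharge on
#' 2008-07-03, a lisinopril fill at discharge, and post-discharge refills of
#' the chronic drugs — 14 fills in all.
#'
#' @return List with `history` (a `patient_history`) and `dictionary`.
#' @examples
#' fix <- table3_fixture()
#' nrow(fix$history$fills)  # 14
#' @export
table3_fixture <- function() {
  dict <- as_dictionary(data.frame(
    product_id = c("ESTR", "METO", "EZSI", "NITR", "LISI"),
    ingredients = I(list("estradiol", "metoprolol succinate",
                         c("ezetimibe", "simvastatin"), "nitroglycerin",
                         "lisinopril")),
    route = c("transdermal", "oral", "oral", "sublingual", "oral"),
    dosage_form = c("patch", "tablet", "tablet", "tablet", "tablet"),
    strength = c("0.025 mg/24 h", "50 mg", "10/10 mg", "0.4 mg", "10 mg"),
    rx_status = "prescription",
    drug_type = "standard",
    common_use = c("regular", "regular", "regular", "as_needed", "regular"),
    is_supply = FALSE,
    is_metered_dose_inhaler = FALSE,
    stringsAsFactors = FALSE
  ))
  chronic_dates <- c("2008-04-19", "2008-05-20", "2008-06-18", "2008-07-19")
  fills <- rbind(
    data.frame(patient_id = "hp01", product_id = "ESTR",
               fill_date = as.Date(chronic_dates), days_supply = 28L,
               quantity = 4),
    data.frame(patient_id = "hp01", product_id = "METO",
               fill_date = as.Date(chronic_dates), days_supply = 30L,
               quantity = 30),
    data.frame(patient_id = "hp01", product_id = "EZSI",
               fill_date = as.Date(chronic_dates), days_supply = 30L,
               quantity = 30),
    data.frame(patient_id = "hp01", product_id = "NITR",
               fill_date = as.Date("2008-04-19"), days_supply = 9L,
               quantity = 25),
    data.frame(patient_id = "hp01", product_id = "LISI",
               fill_date = as.Date("2008-07-03"), days_supply = 30L,
               quantity = 30)
  )
  hosp <- data.frame(patient_id = "hp01",
                     admit_date = as.Date("2008-07-01"),
                     discharge_date = as.Date("2008-07-03"),
                     stringsAsFactors = FALSE)
  idx <- data.frame(patient_id = "hp01", index_date = as.Date("2008-07-01"),
                    stringsAsFactors = FALSE)
  list(history = assemble_histories(fills, hosp, idx)[["hp01"]],
       dictionary = dict)
}
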