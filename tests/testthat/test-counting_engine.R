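fix <- table3_fixture()

test_that("scope filtering applies every subcomponent", {
  estradiol <- fix$dictionary[fix$dictionary$product_id == "ESTR", ]
  nitro <- fix$dictionary[fix$dictionary$product_id == "NITR", ]
  metoprolol <- fix$dictionary[fix$dictionary$product_id == "METO", ]
  expect_false(in_scope(estradiol, preset("v2")$scope))   # not oral
  expect_false(in_scope(nitro, preset("v4")$scope))       # as-needed
  expect_true(in_scope(metoprolol, preset("default")$scope))
  expect_true(in_scope(estradiol, preset("v3")$scope))    # transdermal != topical
  otc <- estradiol
  otc$rx_status <- "otc"
  expect_false(in_scope(otc, preset("default")$scope))
  expect_true(in_scope(otc, preset("v1")$scope))
})

test_that("uniqueness keys dissect combinations under the ingredient basis only", {
  combo <- fix$dictionary[fix$dictionary$product_id == "EZSI", ]
  expect_length(drug_keys(combo, uniqueness_spec("ingredient", "ingredient")), 2)
  expect_length(drug_keys(combo, uniqueness_spec("product",
                                                 "ingredient_route_form")), 1)
  expect_setequal(drug_keys(combo, uniqueness_spec("ingredient", "ingredient")),
                  c("ezetimibe", "simvastatin"))

  # classic inhaler illustration: combo inhaler + nebulizer solution + tablet
  inhaler <- list(ingredients = list(c("albuterol", "ipratropium")),
                  route = "inhalation", dosage_form = "aerosol",
                  strength = "100/20 mcg")
  neb <- list(ingredients = list("albuterol"), route = "inhalation",
              dosage_form = "solution", strength = "2.5 mg")
  tab <- list(ingredients = list("albuterol"), route = "oral",
              dosage_form = "tablet", strength = "2 mg")
  ing <- uniqueness_spec("ingredient", "ingredient")
  expect_length(unique(unlist(lapply(list(inhaler, neb, tab), drug_keys, ing))),
                2)  # albuterol, ipratropium
  ing_route <- uniqueness_spec("ingredient", "ingredient_route")
  expect_length(unique(unlist(lapply(list(inhaler, neb, tab), drug_keys,
                                     ing_route))),
                3)  # albuterol-inhalation, ipratropium-inhalation, albuterol-oral
  prod <- uniqueness_spec("product", "ingredient_route_form")
  expect_length(unique(unlist(lapply(list(inhaler, neb, tab), drug_keys, prod))),
                3)
  # ingredient order inside a combination never changes the product key
  inhaler_rev <- inhaler
  inhaler_rev$ingredients <- list(c("Ipratropium", "Albuterol"))
  expect_equal(drug_keys(inhaler, prod), drug_keys(inhaler_rev, prod))
})

test_that("observed index gap is exact calendar-day subtraction, pre-index only", {
  idx <- as.Date("2008-07-01")
  expect_equal(observed_index_gap(as.Date("2008-06-18"), idx), 13L)
  expect_equal(observed_index_gap(as.Date("2008-04-19"), idx), 73L)
  expect_equal(observed_index_gap(idx - 1, idx), 1L)
  expect_error(observed_index_gap(idx, idx), "strictly")
})

test_that("cabinet supply reproduces worked values and the carry recurrence", {
  anchor <- as.Date("2008-07-01")
  one <- data.frame(fill_date = anchor - 27, days_supply = 30)
  expect_equal(cabinet_days_on_hand(one, anchor, 180), 3)
  expect_equal(cabinet_days_on_hand(one[0, ], anchor, 180), 0)
  two <- data.frame(fill_date = c(anchor - 60, anchor - 30),
                    days_supply = c(30, 30))
  expect_equal(cabinet_days_on_hand(two, anchor, 180), 0)
  expect_equal(cabinet_days_on_hand(two, anchor, 180), oracle_cabinet(two, anchor, 180))
  # fills outside the look-back window are ignored
  far <- data.frame(fill_date = anchor - 200, days_supply = 90)
  expect_equal(cabinet_days_on_hand(far, anchor, 180), 0)
  expect_equal(cabinet_days_on_hand(far, anchor, 250),
               oracle_cabinet(far, anchor, 250))
})

test_that("cabinet supply agrees with the day-by-day oracle on random fill sets", {
  set.seed(4021)
  for (i in 1:250) {
    case <- random_fill_set()
    expect_equal(cabinet_days_on_hand(case$fills, case$anchor, case$lookback),
                 oracle_cabinet(case$fills, case$anchor, case$lookback),
                 info = paste("case", i))
  }
})

test_that("inpatient days in the gap follow the half-open stay convention", {
  anchor <- as.Date("2008-03-01")
  idx <- anchor + 20
  none <- data.frame(admit_date = as.Date(character()),
                     discharge_date = as.Date(character()))
  expect_equal(inpatient_days_in_gap(none, anchor, idx), 0L)
  stay <- data.frame(admit_date = anchor + 5, discharge_date = anchor + 8)
  expect_equal(inpatient_days_in_gap(stay, anchor, idx), 3L)
  expect_equal(inpatient_days_in_gap(stay, anchor, idx),
               oracle_inpatient(stay, anchor, idx))
  after <- data.frame(admit_date = idx + 2, discharge_date = idx + 9)
  expect_equal(inpatient_days_in_gap(after, anchor, idx), 0L)
  # overlapping stays are unioned, not double counted
  overlap <- data.frame(admit_date = c(anchor + 5, anchor + 7),
                        discharge_date = c(anchor + 8, anchor + 10))
  expect_equal(inpatient_days_in_gap(overlap, anchor, idx), 5L)
  expect_equal(inpatient_days_in_gap(overlap, anchor, idx),
               oracle_inpatient(overlap, anchor, idx))
  # dialect switch: counting the discharge day too adds one day per stay block
  expect_equal(inpatient_days_in_gap(stay, anchor, idx, "admit_discharge"), 4L)
  expect_equal(inpatient_days_in_gap(stay, anchor, idx, "admit_discharge"),
               oracle_inpatient(stay, anchor, idx, "admit_discharge"))
})

test_that("random stays match the brute-force day enumeration", {
  set.seed(515)
  anchor <- as.Date("2008-01-10")
  for (i in 1:100) {
    idx <- anchor + sample(2:120, 1)
    n <- sample(0:3, 1)
    admits <- anchor + sample(-10:130, max(n, 1), replace = TRUE)
    hosp <- data.frame(admit_date = admits,
                       discharge_date = admits +
                         sample(0:12, max(n, 1), replace = TRUE))
    hosp <- hosp[seq_len(n), , drop = FALSE]
    for (conv in c("admit_only", "admit_discharge")) {
      expect_equal(inpatient_days_in_gap(hosp, anchor, idx, conv),
                   oracle_inpatient(hosp, anchor, idx, conv),
                   info = paste(i, conv))
    }
  }
})

test_that("the hypothetical patient reproduces every preset's published count", {
  for (n in names(expected_fixture_counts)) {
    res <- count_drugs(fix$history, preset(n), fix$dictionary)
    expect_equal(res$count, unname(expected_fixture_counts[n]), info = n)
    expect_equal(res$count, sum(res$evidence$counted), info = n)
  }
})

test_that("evidence explains which rule fired for each candidate drug", {
  res <- count_drugs(fix$history, preset("default"), fix$dictionary)
  ev <- res$evidence
  nitro <- ev[grepl("nitroglycerin", ev$key), ]
  expect_false(nitro$counted)
  expect_equal(nitro$rule_fired, "none")
  expect_equal(nitro$observed_index_gap, 73)
  expect_equal(nitro$allowable_index_gap, 9)
  # lisinopril has only a post-index fill: evidence present, no anchor
  lis <- ev[grepl("lisinopril", ev$key), ]
  expect_false(lis$counted)
  expect_true(is.na(lis$anchor_fill_date))
  # under the fixed-90 variant nitroglycerin is rescued by the base gap
  ev8 <- count_drugs(fix$history, preset("v8"), fix$dictionary)$evidence
  expect_equal(ev8$rule_fired[grepl("nitroglycerin", ev8$key)], "base_gap")
  # under the PRN override it is rescued by the override rule
  ev13 <- count_drugs(fix$history, preset("v13"), fix$dictionary)$evidence
  expect_equal(ev13$rule_fired[grepl("nitroglycerin", ev13$key)],
               "override_gap")
})

test_that("post-index rescue needs a pre-index anchor and a near-enough refill", {
  # no post-index nitroglycerin refill and no pre-index lisinopril anchor
  res <- count_drugs(fix$history, preset("v10"), fix$dictionary)
  expect_equal(res$count, 3L)
  # a drug failing the index gap but refilled soon after index is rescued
  dict <- tiny_dictionary()
  h <- make_history(list(list("A", "2008-05-22", 30),
                         list("A", "2008-07-05", 30)), "2008-07-01")
  expect_equal(count_drugs(h, preset("default"), dict)$count, 0L)  # gap 40
  res2 <- count_drugs(h, preset("v10"), dict)
  expect_equal(res2$count, 1L)
  expect_equal(res2$evidence$rule_fired, "post_index")
  expect_equal(res2$evidence$observed_pre_post_gap, 44)  # 44 < 2 x 30
  # too-late refill: pre-post gap 80 is not < 2 x 30
  h3 <- make_history(list(list("A", "2008-05-22", 30),
                          list("A", "2008-08-10", 30)), "2008-07-01")
  expect_equal(count_drugs(h3, preset("v10"), dict)$count, 0L)
})

test_that("cabinet and hospitalization adjustments extend the allowable gap", {
  dict <- tiny_dictionary()
  # a prior fill fully exhausted before the anchor leaves nothing on hand
  h <- make_history(list(list("A", "2008-04-07", 30),   # 45 d before anchor
                         list("A", "2008-05-22", 30)), "2008-07-01")
  expect_equal(count_drugs(h, preset("default"), dict)$count, 0L)
  res <- count_drugs(h, preset("v11"), dict)
  expect_equal(res$count, 0L)
  expect_equal(res$evidence$cabinet_days, 0)  # 30 - 45 floored at zero
  # a closer prior fill leaves 10 leftover days: observed gap 40 meets
  # allowable 30 + 10 = 40 exactly, and the strict inequality excludes it
  h2 <- make_history(list(list("A", "2008-05-02", 30),  # 20 d before anchor
                          list("A", "2008-05-22", 30)), "2008-07-01")
  res2 <- count_drugs(h2, preset("v11"), dict)
  expect_equal(res2$evidence$cabinet_days, 10)
  expect_equal(res2$count, 0L)
  # an 11-day leftover crosses the threshold
  h3 <- make_history(list(list("A", "2008-05-03", 30),
                          list("A", "2008-05-22", 30)), "2008-07-01")
  expect_equal(count_drugs(h3, preset("v11"), dict)$count, 1L)
  # hospitalization days inside the gap rescue likewise
  hosp <- data.frame(admit_date = as.Date("2008-06-01"),
                     discharge_date = as.Date("2008-06-12"))
  h4 <- make_history(list(list("A", "2008-05-22", 30)), "2008-07-01",
                     hosp = hosp)
  expect_equal(count_drugs(h4, preset("default"), dict)$count, 0L)
  res4 <- count_drugs(h4, preset("v12"), dict)
  expect_equal(res4$count, 1L)
  expect_equal(res4$evidence$inpatient_days_in_gap, 11L)
})

test_that("split fills of one drug on one day pool their days supply", {
  dict <- tiny_dictionary()
  h <- make_history(list(list("A", "2008-06-11", 10),
                         list("A", "2008-06-11", 15)), "2008-07-01")
  res <- count_drugs(h, preset("default"), dict)
  expect_equal(res$evidence$days_supply, 25L)
  expect_equal(res$count, 1L)  # gap 20 < 25 pooled, though 20 >= either part
})

test_that("an ingredient counts when any product containing it qualifies", {
  dict <- tiny_dictionary(list(
    list(product_id = "A", ingredients = "shared", route = "oral",
         dosage_form = "tablet", strength = "10 mg",
         rx_status = "prescription", drug_type = "standard",
         common_use = "regular", is_supply = FALSE,
         is_metered_dose_inhaler = FALSE),
    list(product_id = "B", ingredients = "shared", route = "oral",
         dosage_form = "capsule", strength = "20 mg",
         rx_status = "prescription", drug_type = "standard",
         common_use = "regular", is_supply = FALSE,
         is_metered_dose_inhaler = FALSE)))
  # product A lapsed long ago but product B is current
  h <- make_history(list(list("A", "2008-01-05", 30),
                         list("B", "2008-06-20", 30)), "2008-07-01")
  m <- parse_measure(list(preset = "v5"))
  res <- count_drugs(h, m, dict)
  expect_equal(res$count, 1L)
  expect_equal(res$evidence$key, "shared")
  expect_true(res$evidence$counted)
  # product basis at ingredient-route-form keeps them apart: only B counts
  res_p <- count_drugs(h, preset("default"), dict)
  expect_equal(res_p$count, 1L)
  expect_equal(nrow(res_p$evidence), 2)
})

test_that("longitudinal orientation counts distinct keys inside the window", {
  m <- parse_measure(list(preset = "default", measure_id = "long365",
                          timeframe = list(orientation = "longitudinal",
                                           longitudinal_window = c(-365, 0))))
  res <- count_drugs(fix$history, m, fix$dictionary)
  expect_equal(res$count, 4L)  # all four pre-index drugs, lisinopril excluded
  m30 <- parse_measure(list(preset = "default", measure_id = "long30",
                            timeframe = list(orientation = "longitudinal",
                                             longitudinal_window = c(-30, 0))))
  expect_equal(count_drugs(fix$history, m30, fix$dictionary)$count, 3L)
})

test_that("an empty fill history counts zero under every preset", {
  dict <- tiny_dictionary()
  h <- make_history(list(), "2008-07-01")
  for (n in preset_names()) {
    expect_equal(count_drugs(h, preset(n), dict)$count, 0L, info = n)
  }
})
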