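test_that("validation enforces the check-in contract", {
  ok <- validate_checkin(make_raw_checkin(), default_policy)
  expect_equal(nrow(ok), 1)
  expect_true(all(as.integer(ok[1, symptom_names()]) == 0))
  expect_s3_class(ok$submitted_at, "POSIXct")

  # missing symptom is named, never imputed
  rec <- make_raw_checkin()
  rec$oral_mucositis <- NULL
  err <- expect_error(validate_checkin(rec, default_policy),
                      class = "oncotriage_error_missing_symptom")
  expect_match(conditionMessage(err), "oral_mucositis")

  # out-of-range score is named
  err <- expect_error(
    validate_checkin(make_raw_checkin(pain = 4), default_policy),
    class = "oncotriage_error_score_out_of_range")
  expect_match(conditionMessage(err), "pain")
  expect_error(validate_checkin(make_raw_checkin(fatigue = -1), default_policy),
               class = "oncotriage_error_score_out_of_range")
  expect_error(validate_checkin(make_raw_checkin(nausea_vomiting = 1.5),
                                default_policy),
               class = "oncotriage_error_score_out_of_range")

  # timestamps without an explicit offset are rejected
  expect_error(
    validate_checkin(make_raw_checkin(submitted_at = "2025-07-15T10:00:00"),
                     default_policy),
    class = "oncotriage_error_bad_timestamp")

  # duplicate ids are rejected
  two <- dplyr::bind_rows(make_raw_checkin(), make_raw_checkin())
  expect_error(validate_checkins(two, default_policy),
               class = "oncotriage_error_duplicate_checkin_id")
})

test_that("score-to-tier map follows the policy table", {
  expect_equal(as.character(map_symptom_tier("diarrhea", 0)), "GREEN")
  expect_equal(as.character(map_symptom_tier("diarrhea", 1)), "GREEN")
  expect_equal(as.character(map_symptom_tier("pain", 2)), "AMBER")
  expect_equal(as.character(map_symptom_tier("diarrhea", 3)), "RED")
  # total over all 11 symptoms x 4 scores, non-decreasing per symptom
  for (s in symptom_names()) {
    tiers <- map_symptom_tier(rep(s, 4), 0:3)
    expect_false(is.unsorted(tiers))
  }
  # a custom map is honoured
  tm <- oncotriage:::default_tier_map()
  tm["temperature", "1"] <- "AMBER"
  pol <- triage_policy(symptom_tier_map = tm)
  expect_equal(as.character(map_symptom_tier("temperature", 1, pol)), "AMBER")
})

test_that("triage produces one alert per check-in with max-tier semantics", {
  # all zero -> green, reassurance, no contributing symptoms or domains
  a <- triage_checkins(validate_checkins(make_raw_checkin(), default_policy),
                       default_policy)
  expect_equal(nrow(a), 1)
  expect_equal(as.character(a$tier), "GREEN")
  expect_equal(a$guidance, "reassurance")
  expect_equal(a$contributing_symptoms, "")
  expect_equal(a$domains, "")

  # single severe symptom -> red, its domain only
  a <- triage_checkins(validate_checkins(make_raw_checkin(dyspnea = 3),
                                         default_policy), default_policy)
  expect_equal(as.character(a$tier), "RED")
  expect_equal(a$guidance, "urgent_contact")
  expect_equal(a$contributing_symptoms, "dyspnea")
  expect_equal(a$domains, "respiratory")

  # single amber
  a <- triage_checkins(validate_checkins(make_raw_checkin(pain = 2),
                                         default_policy), default_policy)
  expect_equal(as.character(a$tier), "AMBER")
  expect_equal(a$guidance, "monitor_await_review")
})

test_that("multi-amber upgrade matches exhaustive rule-table enumeration", {
  pol_on <- triage_policy(multi_amber_upgrade = TRUE, multi_amber_threshold = 2)
  pol_off <- triage_policy(multi_amber_upgrade = FALSE)

  # spec'd example: two gastrointestinal ambers upgrade to red, one domain
  a <- triage_checkins(
    validate_checkins(make_raw_checkin(diarrhea = 2, nausea_vomiting = 2), pol_on),
    pol_on)
  expect_equal(as.character(a$tier), "RED")
  expect_equal(a$domains, "gastrointestinal")
  a_off <- triage_checkins(
    validate_checkins(make_raw_checkin(diarrhea = 2, nausea_vomiting = 2), pol_off),
    pol_off)
  expect_equal(as.character(a_off$tier), "AMBER")

  # oracle: enumerate every 2-symptom score combination against the rule table
  combos <- utils::combn(symptom_names(), 2)
  for (i in seq_len(ncol(combos))) {
    for (s1 in 0:3) for (s2 in 0:3) {
      args <- setNames(list(s1, s2), combos[, i])
      rec <- do.call(make_raw_checkin, args)
      got <- as.character(
        triage_checkins(validate_checkins(rec, pol_on), pol_on)$tier)
      t1 <- pol_on$symptom_tier_map[combos[1, i], as.character(s1)]
      t2 <- pol_on$symptom_tier_map[combos[2, i], as.character(s2)]
      base <- c("GREEN", "AMBER", "RED")[max(match(t1, c("GREEN", "AMBER", "RED")),
                                             match(t2, c("GREEN", "AMBER", "RED")))]
      want <- if (sum(c(t1, t2) == "AMBER") >= 2) "RED" else base
      expect_equal(got, want,
                   info = paste(combos[1, i], s1, combos[2, i], s2))
    }
  }
})

test_that("tier is monotone in any single score increase", {
  raw <- random_checkins(60, seed = 101)
  alerts <- triage_checkins(validate_checkins(raw, default_policy), default_policy)
  withr::with_seed(202, {
    for (k in 1:120) {
      i <- sample(nrow(raw), 1)
      s <- sample(symptom_names(), 1)
      if (raw[[s]][i] == 3) next
      bumped <- raw[i, ]
      bumped[[s]] <- bumped[[s]] + 1L
      new_tier <- triage_checkins(validate_checkins(bumped, default_policy),
                                  default_policy)$tier
      expect_gte(as.integer(new_tier), as.integer(alerts$tier[i]))
    }
  })
})

test_that("triage is total: every validated check-in yields exactly one alert", {
  raw <- random_checkins(200, seed = 7)
  checkins <- validate_checkins(raw, default_policy)
  alerts <- triage_checkins(checkins, default_policy)
  expect_equal(nrow(alerts), nrow(checkins))
  expect_setequal(alerts$checkin_id, checkins$checkin_id)
  # guidance bijection with tier
  expect_true(all(alerts$guidance[alerts$tier == "GREEN"] == "reassurance"))
  expect_true(all(alerts$guidance[alerts$tier == "AMBER"] == "monitor_await_review"))
  expect_true(all(alerts$guidance[alerts$tier == "RED"] == "urgent_contact"))
  # green alerts never carry contributing symptoms
  expect_true(all(alerts$contributing_symptoms[alerts$tier == "GREEN"] == ""))
  # domains are the image of contributing symptoms under the domain map
  nz <- alerts[alerts$contributing_symptoms != "", ]
  dm <- default_policy$domain_map
  for (i in seq_len(nrow(nz))) {
    contrib <- strsplit(nz$contributing_symptoms[i], ";")[[1]]
    expect_equal(strsplit(nz$domains[i], ";")[[1]],
                 sort(unique(unname(dm[contrib]))))
  }
})

test_that("coverage classification matches minute-enumeration over a week", {
  sched <- monitoring_schedule()
  # Monday 2025-07-14 00:00 London, one minute at a time for 7 days
  start <- parse_timestamp("2025-07-14T00:00:00+01:00", sched$timezone)
  mins <- start + seq(0, 7 * 24 * 60 - 1) * 60
  got <- classify_coverage(mins, sched)
  local <- format(mins, "%u %H%M", tz = sched$timezone)
  wd <- substr(local, 1, 1)
  hm <- substr(local, 3, 6)
  want <- wd %in% as.character(1:5) & hm >= "0900" & hm < "1700"
  expect_equal(got, want)
  # half-open boundary: exactly 17:00 on a Friday is out of hours
  expect_false(classify_coverage("2025-07-18T17:00:00+01:00", sched))
  expect_true(classify_coverage("2025-07-18T16:59:59+01:00", sched))
  expect_true(classify_coverage("2025-07-15T10:30:00+01:00", sched))
  expect_false(classify_coverage("2025-07-19T10:30:00+01:00", sched))
})

test_that("policy invariants are enforced at construction", {
  tm <- oncotriage:::default_tier_map()
  tm["pain", "3"] <- "GREEN" # decreasing in score
  expect_error(triage_policy(symptom_tier_map = tm),
               class = "oncotriage_error_invalid_config")
  dm <- default_domain_map()
  dm["pain"] <- "not_a_domain"
  expect_error(triage_policy(domain_map = dm),
               class = "oncotriage_error_invalid_config")
  expect_error(triage_policy(episode_window_hours = -1),
               class = "oncotriage_error_invalid_config")
  expect_error(monitoring_schedule(timezone = "Mars/Olympus"),
               class = "oncotriage_error_invalid_config")
})
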