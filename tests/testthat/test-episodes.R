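test_that("a single amber alert initiates a singleton episode", {
  al <- make_alerts("p1", times = 0, domains = "gastrointestinal")
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_alerts, 1L)
  expect_equal(ep$domain_set, "gastrointestinal")
  expect_equal(as.character(ep$max_tier), "AMBER")
})

test_that("the 48h window is measured from the most recent alert, inclusively", {
  # t0 and t0+47h chain; t0+97h is 50h after the chain's last alert
  al <- make_alerts("p1", times = c(0, 47, 97), domains = "gastrointestinal")
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 2)
  expect_equal(sort(ep$n_alerts), c(1L, 2L))
  # inclusive boundary: a gap of exactly 48h joins
  al <- make_alerts("p1", times = c(0, 48), domains = "gastrointestinal")
  expect_equal(nrow(build_episodes(al, default_policy)), 1)
  al <- make_alerts("p1", times = c(0, 48.001), domains = "gastrointestinal")
  expect_equal(nrow(build_episodes(al, default_policy)), 2)
})

test_that("disjoint symptom domains open concurrent episodes", {
  al <- make_alerts("p1", times = c(0, 6), domains = c("gastrointestinal", "respiratory"),
                    tiers = c("AMBER", "RED"))
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 2)
  expect_setequal(ep$domain_set, c("gastrointestinal", "respiratory"))
  # and a later gastrointestinal alert joins the gastrointestinal episode
  al <- make_alerts("p1", times = c(0, 6, 10),
                    domains = c("gastrointestinal", "respiratory", "gastrointestinal"),
                    tiers = c("AMBER", "RED", "AMBER"))
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 2)
  gi <- ep[ep$domain_set == "gastrointestinal", ]
  expect_equal(gi$n_alerts, 2L)
})

test_that("a within-window same-domain chain forms one episode", {
  al <- make_alerts("p1", times = c(0, 40, 80, 120), domains = "pain")
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_alerts, 4L)
  expect_equal(ep$started_at, al$raised_at[1])
  expect_equal(ep$last_alert_at, al$raised_at[4])
})

test_that("continuity uses the cumulative domain set and max tier is tracked", {
  # gastro alert, then mixed gastro+pain, then pain-only: connected via the
  # cumulative set even though alert 1 and 3 share no domain
  al <- make_alerts("p1", times = c(0, 10, 20),
                    domains = c("gastrointestinal", "gastrointestinal;pain", "pain"),
                    tiers = c("AMBER", "AMBER", "RED"))
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$domain_set, "gastrointestinal;pain")
  expect_equal(as.character(ep$max_tier), "RED")
})

test_that("green alerts are ignored and patients never mix", {
  al <- dplyr::bind_rows(
    make_alerts("p1", times = c(0, 10), domains = "pain"),
    make_alerts("p2", times = c(5, 15), domains = "pain"))
  greens <- make_alerts("p1", times = 2, domains = "", tiers = "GREEN")
  ep <- build_episodes(dplyr::bind_rows(al, greens), default_policy)
  expect_equal(nrow(ep), 2)
  expect_setequal(ep$patient_id, c("p1", "p2"))
  expect_equal(sum(ep$n_alerts), 4L)
})

test_that("episode partition, window and permutation invariants hold", {
  bundle <- simulate_cohort(simulation_config(n_patients = 20, duration_days = 40,
                                              seed = 11))
  alerts <- bundle$alerts
  ep <- build_episodes(alerts, default_policy)

  # partition: every amber/red alert in exactly one episode
  member_ids <- unlist(strsplit(ep$alert_ids, ";"))
  expect_equal(length(member_ids), sum(alerts$tier != "GREEN"))
  expect_equal(anyDuplicated(member_ids), 0L)
  expect_setequal(member_ids, alerts$alert_id[alerts$tier != "GREEN"])
  expect_equal(sum(ep$n_alerts), length(member_ids))

  # window: all consecutive gaps within an episode are <= 48h and times
  # non-decreasing
  alert_time <- setNames(alerts$raised_at, alerts$alert_id)
  for (i in seq_len(nrow(ep))) {
    ts <- alert_time[strsplit(ep$alert_ids[i], ";")[[1]]]
    expect_false(is.unsorted(as.numeric(ts)))
    if (length(ts) > 1) {
      expect_true(all(diff(as.numeric(ts)) / 3600 <= 48))
    }
  }

  # permutation invariance: shuffled input gives the identical partition
  withr::with_seed(3, shuffled <- alerts[sample(nrow(alerts)), ])
  ep2 <- build_episodes(shuffled, default_policy)
  expect_equal(ep2, ep)
})

test_that("single-domain streams match brute-force 48h chain clustering", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(1:25, 1)
      times <- sort(runif(n, 0, 500))
      al <- make_alerts("p1", times = times, domains = "pain")
      ep <- build_episodes(al, default_policy)
      expect_equal(sort(ep$n_alerts), sort(oracle_chain_sizes(times)),
                   info = paste("rep", rep))
    }
  })
})

test_that("multi-eligibility joins the most recently active episode", {
  # two open episodes sharing the pain domain become eligible for one alert;
  # it must join the one whose last alert is more recent (episode B)
  al <- make_alerts("p1", times = c(0, 10, 20),
                    domains = c("pain;mucositis", "pain;skin", "pain"))
  ep <- build_episodes(al, default_policy)
  # alert 2 already joined episode A (shares pain), so only one episode exists;
  # force true concurrency with disjoint starts:
  al <- make_alerts("p1", times = c(0, 10, 20),
                    domains = c("mucositis;pain", "skin", "skin;pain"))
  ep <- build_episodes(al, default_policy)
  expect_equal(nrow(ep), 2)
  # alert 3 shares domains with both; episode with alert 2 (t=10) is more
  # recent than episode with alert 1 (t=0)
  sizes <- ep[order(ep$started_at), ]$n_alerts
  expect_equal(sizes, c(1L, 2L))
})

test_that("review outcomes attach with highest-severity action semantics", {
  al <- dplyr::bind_rows(
    make_alerts("p1", times = 0, domains = "pain"),
    make_alerts("p2", times = 0, domains = "pain"),
    make_alerts("p3", times = 0, domains = "pain"))
  ep <- build_episodes(al, default_policy)
  log <- tibble::tibble(
    episode_id = c(ep$episode_id[1], ep$episode_id[2], ep$episode_id[2]),
    responded_at = parse_timestamp(rep("2025-07-14T15:00:00+01:00", 3)),
    action = c("telephone_advice", "telephone_advice", "admission"))
  out <- attach_outcomes(ep, log)
  expect_equal(as.character(out$action),
               c("telephone_advice", "admission", "none"))
  expect_equal(out$actionable, c(TRUE, TRUE, FALSE))
  # actionable <=> action != none
  expect_equal(out$actionable, out$action != "none")
  # unknown episode reference fails
  bad <- tibble::tibble(episode_id = "EP9999",
                        responded_at = log$responded_at[1],
                        action = "telephone_advice")
  expect_error(attach_outcomes(ep, bad),
               class = "oncotriage_error_unknown_episode_reference")
})

test_that("episode statistics summarise workload consolidation", {
  # sizes {1,2,3}: mean 2.0, range 1-3, consolidation 2.0
  al <- dplyr::bind_rows(
    make_alerts("p1", times = 0, domains = "pain"),
    make_alerts("p2", times = c(0, 10), domains = "pain"),
    make_alerts("p3", times = c(0, 10, 20), domains = "pain"))
  st <- episode_stats(build_episodes(al, default_policy))
  expect_equal(st$n_alerts_in, 6L)
  expect_equal(st$n_episodes, 3L)
  expect_equal(st$mean_alerts_per_episode, 2.0)
  expect_equal(st$alerts_per_episode_range, c(1L, 3L))
  expect_equal(st$consolidation_factor, 2.0)
  expect_gte(st$consolidation_factor, 1)

  # five singleton episodes: lower bound 1.0
  al5 <- dplyr::bind_rows(lapply(1:5, function(i)
    make_alerts(paste0("q", i), times = 0, domains = "pain")))
  st5 <- episode_stats(build_episodes(al5, default_policy))
  expect_equal(st5$mean_alerts_per_episode, 1.0)
  expect_equal(st5$consolidation_factor, 1.0)

  # empty input is an explicit error, not NaN
  empty <- build_episodes(make_alerts("p1", times = 0, domains = "",
                                      tiers = "GREEN"), default_policy)
  expect_error(episode_stats(empty), class = "oncotriage_error_empty_input")
})
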