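rec <- function(id, year, sex = NA, brood_size = NA, breeder = !is.na(brood_size),
                ringed = FALSE, ringing_year = NA, brood_id = NA) {
  data.frame(individual_id = id, year = as.integer(year), sex = sex,
             ringed_as_nestling = ringed, ringing_year = as.integer(ringing_year),
             brood_id = brood_id, brood_size = as.integer(brood_size),
             breeder_with_success = breeder, stringsAsFactors = FALSE)
}

test_that("within-year collapse prefers brood-informative records", {
  r <- rbind(rec("A", 2010, brood_size = 4),
             rec("A", 2010, breeder = TRUE),
             rec("B", 2011))
  out <- collapse_to_annual(r)
  expect_equal(nrow(out), 2)
  expect_equal(out$brood_size[out$individual_id == "A"], 4L)
  # single record is returned unchanged, different years are both retained
  one <- rec("C", 2012, brood_size = 3)
  expect_equal(collapse_to_annual(one)$brood_size, 3L)
  two_years <- rbind(rec("D", 2010), rec("D", 2011))
  expect_equal(nrow(collapse_to_annual(two_years)), 2)
})

test_that("conflicting brood sizes resolve to the maximum with a warning", {
  r <- rbind(rec("A", 2010, brood_size = 2), rec("A", 2010, brood_size = 5))
  expect_warning(out <- collapse_to_annual(r), "conflicting brood sizes")
  expect_equal(out$brood_size, 5L)
})

test_that("conflicting sexes raise an error naming the individual", {
  r <- rbind(rec("A", 2010, sex = "F"), rec("A", 2011, sex = "M"))
  expect_error(collapse_to_annual(r), "A")
  # a known sex fills unknown-sex records
  r2 <- rbind(rec("B", 2010, sex = "F"), rec("B", 2011))
  expect_equal(unique(collapse_to_annual(r2)$sex), "F")
})

test_that("study filters drop early years, terminal first captures, and uninformative breeders", {
  r <- rbind(rec("A", 2006, brood_size = 3),             # outside window
             rec("A", 2019, brood_size = 3),
             rec("A", 2021, brood_size = 2),             # kept: not A's first
             rec("B", 2021, brood_size = 4),             # first capture in 2021
             rec("C", 2015, breeder = TRUE),             # breeder, size missing
             rec("C", 2016, brood_size = 5))
  out <- apply_study_filters(r, quiet = TRUE)
  expect_setequal(unique(out$individual_id), c("A", "C"))
  expect_equal(sort(out$year[out$individual_id == "A"]), c(2019L, 2021L))
  expect_equal(out$year[out$individual_id == "C"], 2016L)
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["outside_years"]), 1)
  expect_equal(unname(counts["terminal_first_capture"]), 1)
  expect_equal(unname(counts["missing_brood_size"]), 1)
  # filters on empty input return empty
  expect_equal(nrow(apply_study_filters(r[0, ], quiet = TRUE)), 0)
  # an individual with >= 2 retained capture years is never removed entirely
  expect_true("A" %in% out$individual_id)
})

test_that("encounter encoding reproduces a hand-coded toy case", {
  r <- rbind(rec("A", 2010, brood_size = 2), rec("A", 2012, brood_size = 5))
  st <- build_state_table(r, "size", state_thresholds(3, 424.16))
  h <- encode_histories(r, st, "size", occasion_years = 2008:2013)
  expect_equal(unname(h$events[1, ]), c(0L, 0L, 2L, 0L, 3L, 0L))
  expect_equal(h$first_occ, 3L)
})

test_that("age class at first capture is capture year minus ringing year, capped at 4", {
  r1 <- rbind(rec("A", 2012, ringed = TRUE, ringing_year = 2009),
              rec("B", 2015, ringed = TRUE, ringing_year = 2008),
              rec("C", 2015))
  st <- build_state_table(r1, "size")
  h <- encode_histories(r1, st, "size", occasion_years = 2012:2015)
  expect_equal(h$age_entry[h$ids == "A"], 3L)
  expect_equal(h$age_entry[h$ids == "B"], 4L)
  expect_true(is.na(h$age_entry[h$ids == "C"]))
})

test_that("states without capture records are rejected", {
  r <- rec("A", 2010, brood_size = 2)
  st <- data.frame(individual_id = c("A", "A"), year = c(2010L, 2011L),
                   state = c("L", "H"))
  expect_error(encode_histories(r, st, "size"), "no capture record")
  st_missing <- data.frame(individual_id = "Z", year = 2010L, state = "L")
  expect_error(encode_histories(r, st_missing, "size"), "no capture record")
})

test_that("simulate -> write -> ingest -> encode round-trips the event matrix exactly", {
  for (measure in c("size", "mass")) {
    cfg <- sim_config(n_individuals = 120, n_occasions = 8, seed = 23,
                      measure = measure,
                      entry_weights = c(rep(1 / 7, 7), 0))
    sim <- simulate_histories(cfg)
    dir <- file.path(tempdir(), paste0("roundtrip_", measure))
    paths <- write_sim_data(sim, dir)
    records <- collapse_to_annual(read_capture_records(paths[["captures"]]))
    records <- apply_study_filters(records, first_year = 2008, last_year = 2015,
                                   drop_terminal_first_captures = FALSE,
                                   require_brood_info = measure == "size",
                                   quiet = TRUE)
    broods <- NULL
    if (measure == "mass")
      broods <- brood_table(read_nestlings(paths[["nestlings"]]),
                            smi_params(35.1, 2))
    st <- build_state_table(records, measure, state_thresholds(3, 424.16), broods)
    h <- encode_histories(records, st, measure, occasion_years = 2008:2015)
    expect_equal(h$ids, sim$histories$ids[order(sim$histories$ids)])
    ord <- match(h$ids, sim$histories$ids)
    expect_equal(unname(h$events), unname(sim$histories$events[ord, ]))
    expect_equal(h$sex, sim$histories$sex[ord])
    expect_equal(h$age_entry, sim$histories$age_entry[ord])
    # no history is all zeros and nothing precedes first capture
    expect_true(all(rowSums(h$events != 0L) >= 1))
  }
})

test_that("history writers produce the documented formats", {
  ev <- rbind(c(0L, 2L, 0L, 3L, 0L), c(1L, 0L, 0L, 0L, 2L))
  h <- encounter_histories(ev, sex = c("F", NA), age_entry = c(2, NA),
                           measure = "size", ids = c("owl1", "owl2"))
  inp <- file.path(tempdir(), "h.inp")
  write_inp(h, inp)
  expect_equal(readLines(inp),
               c("/* owl1 */ 02030 1;", "/* owl2 */ 10002 1;"))
  csv <- file.path(tempdir(), "h.csv")
  write_histories_csv(h, csv)
  d <- read.csv(csv, colClasses = c(history = "character", sex = "character"))
  expect_equal(d$history, c("02030", "10002"))
  expect_equal(d$sex, c("F", ""))
})
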