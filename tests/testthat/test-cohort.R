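write_csv_fixture <- function(df, ext = ".csv", sep = ",") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

test_that("event tables parse with validation and duplicate collapsing", {
  df <- data.frame(subject_id = c("s1", "s1", "s2", "s2"),
                   event = c("A", "B", "A", "B"),
                   time = c(3, 10, 5, 53), status = c(1, 1, 1, 0))
  tab <- read_events(write_csv_fixture(df))
  expect_equal(nrow(tab), 4)
  expect_setequal(names(tab), c("subject_id", "event", "time", "status"))
  # duplicate (subject, event) rows: the earliest time wins
  dup <- rbind(df, data.frame(subject_id = "s1", event = "A", time = 1,
                              status = 1))
  tab2 <- read_events(write_csv_fixture(dup))
  expect_equal(tab2$time[tab2$subject_id == "s1" & tab2$event == "A"], 1)
  # tab-separated dialect by extension
  tabtsv <- read_events(write_csv_fixture(df, ext = ".tsv", sep = "\t"))
  expect_equal(nrow(tabtsv), 4)
})

test_that("day-resolution input converts to the week grid with sentinel", {
  df <- data.frame(subject_id = c("s1", "s1", "s1"),
                   event = c("A", "B", "C"),
                   time = c(10, 3, 100), status = c(1, 1, 0))
  tab <- read_events(write_csv_fixture(df), time_unit = "days")
  expect_equal(tab$time[tab$event == "A"], 2)   # ceil(10/7)
  expect_equal(tab$time[tab$event == "B"], 1)
  expect_equal(tab$time[tab$event == "C"], 53)  # censored -> sentinel
  # duplicates in days: earliest day decides before conversion
  dup <- rbind(df, data.frame(subject_id = "s1", event = "A", time = 3,
                              status = 1))
  tab2 <- read_events(write_csv_fixture(dup), time_unit = "days")
  expect_equal(tab2$time[tab2$event == "A"], 1)
})

test_that("malformed event files give descriptive parse errors", {
  df <- data.frame(subject_id = "s1", event = "A", time = 3)
  expect_error(read_events(write_csv_fixture(df)), "status")
  bad_status <- data.frame(subject_id = "s1", event = "A", time = 3,
                           status = 2)
  expect_error(read_events(write_csv_fixture(bad_status)), "status")
  bad_time <- data.frame(subject_id = "s1", event = "A", time = "soon",
                         status = 1)
  expect_error(read_events(write_csv_fixture(bad_time)), "time")
})

test_that("days map to weeks by ceiling with a 52-week cap", {
  expect_equal(to_weeks(1), 1L)
  expect_equal(to_weeks(7), 1L)
  expect_equal(to_weeks(8), 2L)
  expect_equal(to_weeks(364), 52L)
  expect_equal(to_weeks(366), 52L)  # capped
  expect_error(to_weeks(0), "1..366")
})

test_that("patient filtering matches a direct counting oracle", {
  set.seed(61)
  tab <- chain_cohort(200, censor = 0.4)
  filt <- filter_patients(tab, min_events = 2)
  counts <- tapply(tab$status, tab$subject_id, sum)
  expect_setequal(unique(filt$subject_id), names(counts)[counts >= 2])
  # a subject with a single observed event is dropped at min 2
  one <- data.frame(subject_id = "x", event = c("A", "B", "C"),
                    time = c(5, 53, 53), status = c(1, 0, 0))
  expect_equal(nrow(filter_patients(rbind(tab, one), 2)[
    filter_patients(rbind(tab, one), 2)$subject_id == "x", ]), 0)
  # the fully observed subset keeps only subjects with every event observed
  full <- filter_patients(tab, min_events = 2, fully_observed = TRUE)
  tot <- tapply(tab$status, tab$subject_id, length)
  expect_setequal(unique(full$subject_id),
                  names(counts)[counts == tot & counts >= 2])
})

test_that("event selection thresholds the observed rate", {
  set.seed(62)
  n <- 400
  mk <- function(lab, rate) data.frame(
    subject_id = sprintf("S%03d", 1:n), event = lab,
    time = ifelse(runif(n) < rate, sample(1:20, n, TRUE), 53),
    status = NA)
  tab <- rbind(mk("HI", 0.999), mk("MID", 0.76), mk("LO", 0.5))
  tab$status <- as.integer(tab$time != 53)
  sel <- select_top_events(tab, 0.70)
  expect_true(all(c("HI", "MID") %in% sel))
  expect_false("LO" %in% sel)
  rates <- attr(sel, "rates")
  direct <- tapply(tab$status, tab$event, mean)
  expect_equal(rates[names(direct)], direct)
  expect_equal(as.character(sel[1]), "HI")  # sorted by rate
})

test_that("cohort generation respects its spec", {
  spec <- cohort_spec(n_subjects = 500, seed = 63)
  tab <- generate_cohort(spec)
  expect_equal(nrow(tab), 500 * 7)
  expect_true(all(tab$time >= 1 & tab$time <= 53))
  expect_true(all((tab$time == 53) == (tab$status == 0)))
  # deterministic given the spec seed
  expect_identical(tab, generate_cohort(spec))
  # zero censoring: the sentinel never appears
  nospec <- cohort_spec(
    n_subjects = 200, anchor_censoring = 0,
    dependent = list(SKIN = list(offset = 3, spread = 2, censoring = 0)),
    independent = list(EYE = list(median = 20, censoring = 0)),
    seed = 64)
  notab <- generate_cohort(nospec)
  expect_false(any(notab$time == 53))
  expect_true(all(notab$status == 1))
})

test_that("a dependent offset appears as a flat gap around its setting", {
  spec <- cohort_spec(
    n_subjects = 4000, anchor_median = 5, anchor_censoring = 0,
    dependent = list(DEP = list(offset = 2, spread = 0.5, censoring = 0)),
    independent = list(), seed = 65)
  tab <- generate_cohort(spec)
  gap <- diagnosis_gap(tab, "RESP", "DEP")
  filled <- gap[gap$n >= 30, ]
  expect_true(all(abs(filled$median_gap - 2) <= 1))
})

test_that("wide pivoting requires complete records", {
  tab <- chain_cohort(20)
  w <- events_wide(tab)
  expect_equal(dim(w$times), c(20, 3))
  expect_equal(dim(w$status), c(20, 3))
  expect_error(events_wide(tab[-1, ]), "every subject")
})

test_that("the pipeline recovers a strict generative order", {
  set.seed(66)
  tab <- chain_cohort(150, labels = c("A", "B", "C"), censor = 0)
  rep <- run_cohort_analysis(tab, config = opt_config(max_depth = 6),
                             min_subjects = 50)
  expect_equal(rep$ranking$order[1], "A -> B -> C")
  expect_equal(nrow(rep$ranking), 6)
  expect_equal(rep$n_subjects, 150)
  expect_true(all(c("summary", "precedence", "valid", "network", "gaps")
                  %in% names(rep)))
})

test_that("pipeline outputs are pure functions of table and config", {
  set.seed(67)
  tab <- chain_cohort(120, censor = 0.15)
  cfg <- opt_config(max_depth = 5)
  r1 <- run_cohort_analysis(tab, config = cfg)
  r2 <- run_cohort_analysis(tab, config = cfg)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(unclass(r1$precedence), unclass(r2$precedence))
})

test_that("pipeline guards reject degenerate cohorts", {
  tab <- chain_cohort(10)
  expect_error(run_cohort_analysis(tab, min_subjects = 50), "subjects")
  one <- data.frame(subject_id = sprintf("S%03d", 1:60), event = "A",
                    time = 5, status = 1L)
  expect_error(run_cohort_analysis(one, min_subjects = 50),
               "at least two")
})

test_that("reports serialise to a directory of standard formats", {
  set.seed(68)
  tab <- chain_cohort(100, censor = 0.1)
  rep <- run_cohort_analysis(tab, config = opt_config(max_depth = 5))
  dir <- tempfile()
  write_cepa_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "event_summary.csv", "precedence.csv", "sequences.csv",
    "valid_sequences.csv", "network.graphml", "network.dot",
    "run_metadata.json")))))
  meta <- jsonlite::read_json(file.path(dir, "run_metadata.json"))
  expect_equal(meta$n_subjects, 100)
  back <- read_precedence_csv(file.path(dir, "precedence.csv"))
  expect_equal(unclass(back), unclass(rep$precedence), tolerance = 1e-12)
})
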