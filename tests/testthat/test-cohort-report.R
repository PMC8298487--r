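# builds a fully populated cohort table directly (no imaging), with known
# group effects, to exercise the report bookkeeping
makeTable <- function(n = 12, dFF = -2, seed = 31, drop = NULL) {
  set.seed(seed)
  rows <- NULL
  add <- function(s, prot, cond, region, metric, value)
    rows <<- rbind(rows, data.frame(subject = s, protocol = prot,
                                    condition = cond, region = region,
                                    metric = metric, value = value))
  for (s in 1:n) {
    mr <- runif(1, 2, 25)
    ffb <- 85 - 0.4 * mr + rnorm(1, 0, 1)
    for (cond in c("baseline", "cold1", "cold2", "reheated")) {
      shift <- if (cond == "baseline") 0 else dFF + rnorm(1, 0, 0.5)
      for (region in c("sBAT", "sBAT_HI", "sBAT_LO", "SAT"))
        add(s, "cooling-reheating", cond, region, "FF",
            ffb + shift + rnorm(1, 0, 0.2))
      add(s, "control", cond, "sBAT", "FF", ffb + rnorm(1, 0, 0.5))
      add(s, "control", cond, "SAT", "FF", ffb + 4 + rnorm(1, 0, 0.5))
    }
    for (region in c("sBAT", "sBAT_HI", "sBAT_LO", "SAT"))
      add(s, "cooling-reheating", "cold1", region, "MRglu", mr)
    for (cond in c("baseline", "cold1", "reheated")) {
      add(s, "cooling-reheating", cond, "sBAT", "perfusion",
          13 + (cond != "baseline") * 5 + rnorm(1, 0, 2))
      add(s, "cooling-reheating", cond, "sBAT", "VA",
          3 + (cond == "cold1") * 4 + rnorm(1, 0, 0.5))
    }
  }
  if (!is.null(drop))
    rows <- rows[!(rows$subject == drop$subject &
                     rows$condition == drop$condition &
                     rows$protocol == "cooling-reheating"), ]
  cohortTable(rows)
}

test_that("cohort tables reject duplicate keys and missing columns", {
  tab <- makeTable(n = 3)
  expect_s3_class(tab, "cohortTable")
  expect_error(cohortTable(rbind(tab, tab[1, ])), "duplicate")
  expect_error(cohortTable(data.frame(subject = 1)), "columns")
})

test_that("cohort table CSV round-trips", {
  tab <- makeTable(n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(tab, path)
  tab2 <- readCohortTable(path)
  expect_equal(tab2$value, tab$value)
})

test_that("a complete table gives equal n for all contrasts", {
  rep <- buildReport(makeTable(n = 8))
  expect_true(all(rep$changes$n == 8))
  expect_true(all(rep$correlations$n == 8))
})

test_that("the report reproduces a generated group effect", {
  rep <- buildReport(makeTable(n = 12, dFF = -2))
  ch <- rep$changes
  row <- ch[ch$metric == "FF" & ch$region == "sBAT" &
              ch$contrast == "cold1-baseline", ]
  expect_lt(abs(row$delta - (-2)), 0.7)   # Monte-Carlo tolerance
  expect_lt(row$p, 0.05)
  expect_equal(row$flag, "*")
  # FF correlates negatively with MR_glu by construction
  co <- rep$correlations
  expect_lt(co$rho[co$condition == "baseline" & co$region == "sBAT" &
                     co$metric == "FF"], -0.5)
  # perfusion and V_A rows present with the cold increase
  pr <- ch[ch$metric == "perfusion" & ch$contrast == "cold1-baseline", ]
  expect_gt(pr$delta, 0)
  va <- ch[ch$metric == "VA" & ch$contrast == "reheated-cold1", ]
  expect_lt(va$delta, 0)
  # the cooling-vs-control contrast is populated for sBAT FF
  expect_false(is.na(row$delta_control))
  expect_false(is.na(row$p_vs_control))
})

test_that("missing cells reduce n only for contrasts that involve them", {
  rep <- buildReport(makeTable(n = 10, drop = list(subject = 4,
                                                   condition = "cold1")))
  ch <- rep$changes
  ffRows <- ch[ch$metric == "FF" & ch$region == "sBAT", ]
  nFor <- function(contrast) ffRows$n[ffRows$contrast == contrast]
  expect_equal(nFor("cold1-baseline"), 9)
  expect_equal(nFor("cold2-cold1"), 9)
  expect_equal(nFor("cold2-baseline"), 10)
  expect_equal(nFor("reheated-baseline"), 10)
})

test_that("report means are invariant to subject ordering", {
  tab <- makeTable(n = 6)
  shuffled <- cohortTable(tab[sample(nrow(tab)), ])
  r1 <- buildReport(tab); r2 <- buildReport(shuffled)
  expect_equal(r1$summary$mean, r2$summary$mean)
  expect_equal(r1$changes$delta, r2$changes$delta)
  expect_equal(r1$changes$p, r2$changes$p)
})

test_that("p-value flags follow the significance and trend bands", {
  rep <- buildReport(makeTable(n = 8))
  p <- c(rep$changes$p, rep$comparisons$p)
  fl <- c(rep$changes$flag, rep$comparisons$flag)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  expect_true(all(fl[!is.na(p) & p < 0.05] == "*"))
  expect_true(all(fl[!is.na(p) & p >= 0.05 & p < 0.10] == "trend"))
})

test_that("reports can be written to CSV and Markdown", {
  d <- withr::local_tempdir()
  writeReport(buildReport(makeTable(n = 5)), d)
  expect_true(file.exists(file.path(d, "changes.csv")))
  expect_true(file.exists(file.path(d, "report.md")))
  md <- readLines(file.path(d, "report.md"))
  expect_true(any(grepl("## changes", md)))
})
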