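test_that("read_trade_matrix parses valid files and rejects bad rows", {
  p <- write_flow_csv(data.frame(
    reporter = c("AAA", "AAA", "BBB"), partner = c("BBB", "CCC", "AAA"),
    year = 1995L, quantity = c(10, 0, 2.5)))
  rec <- read_trade_matrix(p)
  expect_equal(nrow(rec), 3L)
  expect_identical(rec$source, rep("exporter_reported", 3))
  expect_equal(rec$quantity, c(10, 0, 2.5))

  p2 <- write_flow_csv(data.frame(reporter = "AAA", partner = "BBB",
                                  quantity = 1))
  expect_error(read_trade_matrix(p2), "year")

  p3 <- write_flow_csv(data.frame(reporter = "AAA", partner = "BBB",
                                  year = 1995L, quantity = -5))
  expect_error(read_trade_matrix(p3), "negative")

  p4 <- write_flow_csv(data.frame(reporter = "AAA", partner = "AAA",
                                  year = 1995L, quantity = 1))
  expect_error(read_trade_matrix(p4), "reporter equals partner")

  p5 <- write_flow_csv(data.frame(reporter = "AAA", partner = "BBB",
                                  year = 1995L, quantity = "abc"))
  expect_error(read_trade_matrix(p5), "malformed")
})

test_that("merge precedence: exporter wins, importer fills gaps", {
  ex <- data.frame(reporter = "AAA", partner = "BBB", year = 1995L,
                   quantity = 10, source = "exporter_reported",
                   stringsAsFactors = FALSE)
  # importer-reported: BBB reports importing 12 from AAA, and CCC reports
  # importing 7 from AAA (a gap in the export matrix)
  im <- data.frame(reporter = c("BBB", "CCC"), partner = c("AAA", "AAA"),
                   year = 1995L, quantity = c(12, 7),
                   source = "importer_reported", stringsAsFactors = FALSE)
  m <- merge_reported_flows(ex, im)
  expect_equal(m$quantity[m$sender == "AAA" & m$receiver == "BBB"], 10)
  expect_equal(m$quantity[m$sender == "AAA" & m$receiver == "CCC"], 7)
  expect_equal(nrow(m), 2L)
  # orientation: importer-only rows come out sender -> receiver
  expect_identical(m$source[m$sender == "AAA" & m$receiver == "CCC"],
                   "importer_reported")
  # property: no importer-reported value survives where an exporter one exists
  expect_false(any(m$source == "importer_reported" &
                     paste(m$sender, m$receiver, m$year) %in%
                     paste(ex$reporter, ex$partner, ex$year)))
  # empty inputs allowed
  expect_equal(nrow(merge_reported_flows(ex[0, ], im[0, ])), 0L)
})

test_that("build_trade_tensor zero-fills and counts cells", {
  fl <- data.frame(sender = "AAA", receiver = "BBB", year = 1995L,
                   quantity = 42, stringsAsFactors = FALSE)
  tt <- build_trade_tensor(fl, c("AAA", "BBB", "CCC"), c(1995L, 1996L))
  expect_equal(sum(tt$flows == 0), prod(dim(tt$flows)) - 1L)
  off_diag_cells <- 3 * 2 * 2   # N(N-1) per year x 2 years
  expect_equal(off_diag_cells, 12L)
  expect_equal(tt$flows["AAA", "BBB", "1995"], 42)
  # empty flow list -> all-zero tensor
  tt0 <- build_trade_tensor(fl[0, ], c("AAA", "BBB"), 1995L)
  expect_true(all(tt0$flows == 0))
  # conservation for in-list countries
  expect_equal(sum(tt$flows), sum(fl$quantity))
  # out-of-list flows dropped with a message
  fl2 <- rbind(fl, data.frame(sender = "ZZZ", receiver = "AAA",
                              year = 1995L, quantity = 5))
  expect_message(tt2 <- build_trade_tensor(fl2, c("AAA", "BBB"), 1995L),
                 "dropped 1")
  expect_equal(sum(tt2$flows), 42) # AAA->BBB kept, ZZZ row dropped
})

test_that("conflicting duplicates are rejected, consistent ones collapsed", {
  fl <- data.frame(sender = c("AAA", "AAA"), receiver = "BBB",
                   year = 1995L, quantity = c(1, 2),
                   stringsAsFactors = FALSE)
  expect_error(build_trade_tensor(fl, c("AAA", "BBB"), 1995L),
               "conflicting")
  fl$quantity <- c(2, 2)
  expect_equal(sum(build_trade_tensor(fl, c("AAA", "BBB"), 1995L)$flows), 2)
})

test_that("filter_countries applies both rules, iterates, and reports", {
  countries <- c("AAA", "BBB", "CCC", "DDD", "EEE")
  years <- c(1995L, 1996L)
  arr <- array(0, c(5, 5, 2))
  # AAA, BBB, CCC trade among themselves in both years
  arr[1, 2, ] <- 10; arr[2, 3, ] <- 5; arr[3, 1, ] <- 7
  # DDD trades only in 1995 (zero total in 1996 -> rule 2, first pass)
  arr[4, 1, 1] <- 3
  # EEE trades only with CCC -> zeroed out once CCC goes (iteration)
  arr[5, 3, ] <- 2; arr[3, 5, ] <- 1
  tt <- trade_tensor(arr, countries, years)
  panel <- toy_panel(countries, years)
  # CCC has a missing covariate in 1996 -> rule 1
  panel$gdp_pc[panel$country == "CCC" & panel$year == 1996L] <- NA
  res <- filter_countries(tt, panel)
  expect_setequal(res$tensor$countries, c("AAA", "BBB"))
  rep_c <- res$report
  expect_equal(rep_c$rule[rep_c$country == "CCC"], "missing_covariate")
  expect_equal(rep_c$rule[rep_c$country == "DDD"], "zero_trade")
  expect_equal(rep_c$rule[rep_c$country == "EEE"], "zero_trade")
  # idempotence
  res2 <- filter_countries(res$tensor, res$panel)
  expect_equal(nrow(res2$report), 0L)
  expect_identical(res2$tensor$countries, res$tensor$countries)
})

test_that("toy hand-trace: 5 countries, one missing-covariate, one zero-trade-year -> 3 survive", {
  countries <- c("AAA", "BBB", "CCC", "DDD", "EEE")
  years <- c(1995L, 1996L)
  arr <- array(1, c(5, 5, 2))  # everyone trades with everyone
  for (t in 1:2) diag(arr[, , t]) <- 0
  arr[4, , 2] <- 0; arr[, 4, 2] <- 0   # DDD zero total in 1996
  tt <- trade_tensor(arr, countries, years)
  panel <- toy_panel(countries, years)
  panel$des_pct[panel$country == "BBB" & panel$year == 1995L] <- NA
  res <- filter_countries(tt, panel)
  expect_setequal(res$tensor$countries, c("AAA", "CCC", "EEE"))
})

test_that("filter errors when everything is removed", {
  arr <- array(0, c(2, 2, 2))
  tt <- trade_tensor(arr, c("AAA", "BBB"), c(1995L, 1996L))
  expect_error(filter_countries(tt, toy_panel(c("AAA", "BBB"),
                                              c(1995L, 1996L))),
               "all countries removed")
})

test_that("write/read round-trip is exact on nonzero flows", {
  set.seed(11)
  arr <- array(stats::runif(3 * 3 * 2) * 1000, c(3, 3, 2))
  arr[arr < 300] <- 0
  tt <- trade_tensor(arr, c("AAA", "BBB", "CCC"), c(1995L, 1996L))
  path <- tempfile(fileext = ".csv")
  write_trade_matrix(tt, path)
  back <- build_trade_tensor(read_trade_matrix(path),
                             tt$countries, tt$years)
  expect_identical(back$flows, tt$flows)   # bit-exact

  # omit_zeros flag controls the row count
  n_nonzero <- sum(tt$flows > 0)
  expect_equal(nrow(utils::read.csv(path)), n_nonzero)
  write_trade_matrix(tt, path, omit_zeros = FALSE)
  expect_equal(nrow(utils::read.csv(path)), 3 * 2 * 2)

  # empty tensor -> header-only file
  t0 <- trade_tensor(array(0, c(2, 2, 1)), c("AAA", "BBB"), 1995L)
  write_trade_matrix(t0, path)
  expect_equal(nrow(utils::read.csv(path)), 0L)
  expect_error(write_trade_matrix(tt, "/nonexistent-dir/x/y.csv"),
               "cannot write")
})
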