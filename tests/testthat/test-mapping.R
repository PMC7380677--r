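test_that("euclidean distance matches hand values", {
  expect_identical(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_identical(euclidean_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_identical(euclidean_distance(c(-1, -2, 2), c(1, 2, -2)), 6)
  expect_error(euclidean_distance(c(0, 0), c(1, 1, 1)))
  expect_error(euclidean_distance(c(0, 0, NA), c(1, 1, 1)))
})

test_that("euclidean distance obeys the metric axioms", {
  set.seed(7)
  for (i in 1:200) {
    p <- stats::runif(3, -100, 100)
    q <- stats::runif(3, -100, 100)
    r <- stats::runif(3, -100, 100)
    expect_identical(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_gte(euclidean_distance(p, q), 0)
    expect_identical(euclidean_distance(p, p), 0)
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("violation is strictly greater than the threshold", {
  expect_identical(classify_distance(5, 27), "satisfied")
  expect_identical(classify_distance(27, 27), "satisfied")  # boundary
  expect_identical(classify_distance(27.001, 27), "violated")
  # partition: exactly one of the two labels for any displayable distance
  set.seed(11)
  d <- stats::runif(500, 0, 60)
  cls <- classify_distance(d, 27)
  expect_true(all(cls %in% c("satisfied", "violated")))
  expect_identical(cls == "satisfied", !(cls == "violated"))
})

test_that("raising the threshold never loses satisfied links", {
  set.seed(13)
  d <- stats::runif(300, 0, 80)
  thresholds <- sort(stats::runif(20, 1, 80))
  sat <- vapply(thresholds,
                function(t) sum(classify_distance(d, t) == "satisfied"),
                integer(1))
  expect_true(all(diff(sat) >= 0))
})

test_that("single-link mapping returns distance, status, and topology", {
  spec <- trace_spec(c(A = 10), spacing = 10)
  p <- withr::local_tempfile(fileext = ".pdb")
  make_linear_ca_trace(spec, p)
  m <- read_structure(p, quiet = TRUE)
  r1 <- map_crosslink(m, "A", 1, "A", 3, threshold = 27)
  expect_equal(r1$distance, 20)
  expect_identical(r1$status, "satisfied")
  expect_identical(r1$topology, "intra")
  r2 <- map_crosslink(m, "A", 1, "A", 5, threshold = 27)
  expect_equal(r2$distance, 40)
  expect_identical(r2$status, "violated")
  expect_warning(r3 <- map_crosslink(m, "A", 1, "A", 99), "A/99")
  expect_identical(r3$status, "missing")
  expect_identical(r3$absent_endpoints, "A/99")
  expect_true(is.na(r3$distance))
})

test_that("dataset mapping tallies agree with a per-link loop", {
  fx <- demo_fixture(withr::local_tempdir())
  m <- read_structure(fx$pdb, quiet = TRUE)
  d <- parse_xl_file(fx$xlf)
  rep <- suppressWarnings(map_dataset(m, d))
  # independent loop over map_crosslink outputs
  st <- vapply(seq_len(nrow(d$crosslinks)), function(i)
    suppressWarnings(map_crosslink(
      m, d$crosslinks$chain_1[i], d$crosslinks$res_1[i],
      d$crosslinks$chain_2[i], d$crosslinks$res_2[i]))$status,
    character(1))
  expect_identical(rep$counts$n_total, 4L)
  expect_identical(rep$counts$n_displayable, 3L)
  expect_identical(rep$counts$n_satisfied, sum(st == "satisfied"))
  expect_identical(rep$counts$n_violated, sum(st == "violated"))
  expect_identical(rep$counts$n_missing, sum(st == "missing"))
  expect_identical(rep$counts$n_satisfied, 2L)
  expect_identical(rep$counts$n_violated, 1L)
  expect_identical(rep$counts$n_monolinks, 2L)
  expect_identical(rep$counts$n_monolinks_missing, 1L)
})

test_that("an empty dataset maps to an all-zero report", {
  fx <- demo_fixture(withr::local_tempdir())
  m <- read_structure(fx$pdb, quiet = TRUE)
  p <- tempfile(); writeLines("# nothing", p)
  rep <- suppressWarnings(map_dataset(m, parse_xl_file(p)))
  expect_true(all(unlist(rep$counts) == 0L))
})

test_that("mono-links can be excluded from mapping", {
  fx <- demo_fixture(withr::local_tempdir())
  m <- read_structure(fx$pdb, quiet = TRUE)
  rep <- suppressWarnings(
    map_dataset(m, parse_xl_file(fx$xlf), include_monolinks = FALSE))
  expect_identical(rep$counts$n_monolinks, 0L)
  expect_identical(rep$counts$n_total, 4L)
})

test_that("count conservation holds before and after filtering", {
  check_conservation <- function(n) {
    expect_identical(n$n_satisfied + n$n_violated, n$n_displayable)
    expect_identical(n$n_displayable + n$n_missing, n$n_total)
    expect_identical(n$n_intra + n$n_inter, n$n_total)
  }
  set.seed(19)
  for (i in 1:20) {
    spec <- random_trace_spec()
    p <- tempfile(fileext = ".pdb"); make_linear_ca_trace(spec, p)
    xlf <- tempfile()
    writeLines(make_xl_fixture(random_links(spec, 12), spec), xlf)
    m <- read_structure(p, quiet = TRUE)
    rep <- suppressWarnings(map_dataset(m, parse_xl_file(xlf)))
    check_conservation(rep$counts)
    flags <- as.logical(sample(0:1, 5, replace = TRUE))
    f <- filter_report(rep, flags[1], flags[2], flags[3], flags[4], flags[5])
    check_conservation(f$counts)
    expect_identical(f$counts, summary_counts(f))
  }
})

test_that("filtering matches a brute-force predicate", {
  fx <- demo_fixture(withr::local_tempdir())
  m <- read_structure(fx$pdb, quiet = TRUE)
  rep <- suppressWarnings(map_dataset(m, parse_xl_file(fx$xlf)))
  # identity when everything is shown
  expect_identical(filter_report(rep)$crosslinks, rep$crosslinks)
  # violated only, both topologies
  v <- filter_report(rep, show_satisfied = FALSE)
  keep <- with(rep$crosslinks,
               status == "violated" |
                 (status == "missing"))  # missing kept while violated shown
  expect_identical(v$crosslinks, rep$crosslinks[keep, ])
  expect_identical(v$counts$n_violated, 1L)
  # hiding an absent topology class changes nothing (all-intra dataset)
  expect_identical(filter_report(rep, show_inter = FALSE)$crosslinks,
                   rep$crosslinks)
  # hiding both status classes leaves nothing, including missing links
  none <- filter_report(rep, show_satisfied = FALSE, show_violated = FALSE)
  expect_identical(none$counts$n_total, 0L)
})

test_that("threshold monotonicity holds on mapped datasets", {
  set.seed(23)
  spec <- random_trace_spec()
  p <- tempfile(fileext = ".pdb"); make_linear_ca_trace(spec, p)
  xlf <- tempfile()
  writeLines(make_xl_fixture(random_links(spec, 20), spec), xlf)
  m <- read_structure(p, quiet = TRUE)
  d <- parse_xl_file(xlf)
  prev_sat <- -1L; prev_vio <- .Machine$integer.max
  for (t in c(5, 10, 20, 27, 40, 80)) {
    n <- suppressWarnings(map_dataset(m, d, threshold = t))$counts
    expect_gte(n$n_satisfied, prev_sat)
    expect_lte(n$n_violated, prev_vio)
    prev_sat <- n$n_satisfied; prev_vio <- n$n_violated
  }
})
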