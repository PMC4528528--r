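test_that("event summaries compute the behavioural responses exactly", {
  # no events
  s <- summarize_inspections(tibble::tibble(), shoal_size = 4)
  expect_equal(s$n_inspections, 0)
  expect_false(s$occurred)
  expect_equal(s$time_per_fish_s, 0)
  expect_true(is.na(s$mean_duration_s))
  expect_equal(s$rate_per_hour, 0)
  # one 10 s event by 2 fish in a shoal of 4
  ev <- tibble::tibble(start_s = 100, end_s = 110, group_size = 2)
  s <- summarize_inspections(ev, shoal_size = 4)
  expect_equal(s$n_inspections, 1)
  expect_equal(s$mean_duration_s, 10)
  expect_equal(s$time_per_fish_s, 5)
  expect_true(s$occurred)
  expect_equal(s$rate_per_hour, 3)
  # seeded random events match an event-by-event accumulation oracle
  set.seed(61)
  n <- 100
  st <- runif(n, 0, 1100)
  ev <- tibble::tibble(start_s = st, end_s = st + runif(n, 1, 60),
                       group_size = sample(1:4, n, replace = TRUE))
  ev$end_s <- pmin(ev$end_s, 1200)
  s <- summarize_inspections(ev, shoal_size = 4)
  tot_pf <- 0; durs <- numeric(0)
  for (i in seq_len(n)) {
    durs <- c(durs, ev$end_s[i] - ev$start_s[i])
    tot_pf <- tot_pf + (ev$end_s[i] - ev$start_s[i]) * ev$group_size[i] / 4
  }
  expect_equal(s$mean_duration_s, mean(durs))
  expect_equal(s$time_per_fish_s, tot_pf)
  expect_equal(s$rate_per_hour, n / (1200 / 3600))
  # validation: events past the trial end are rejected
  bad <- tibble::tibble(start_s = 1190, end_s = 1300, group_size = 1)
  expect_error(summarize_inspections(bad, 4), class = "shoalwatch_validation")
})

test_that("union-time accounting merges overlapping bouts", {
  ev <- tibble::tibble(start_s = c(0, 5, 30), end_s = c(10, 12, 40),
                       group_size = c(1, 2, 4))
  s <- summarize_inspections(ev, shoal_size = 4, time_per_fish = "union_time")
  expect_equal(s$time_per_fish_s, 12 + 10) # [0,12] union [30,40]
})

test_that("time per fish is bounded by the maximal-group accounting", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(1:20, 1)
    st <- runif(n, 0, 1000)
    ev <- tibble::tibble(start_s = st, end_s = st + runif(n, 1, 100),
                         group_size = sample(1:4, n, replace = TRUE))
    ev$end_s <- pmin(ev$end_s, 1200)
    s <- summarize_inspections(ev, shoal_size = 4)
    bound <- sum(ev$end_s - ev$start_s) * max(ev$group_size) / 4
    expect_lte(s$time_per_fish_s, bound + 1e-9)
  }
})

test_that("pooled rates reproduce the headline arithmetic", {
  expect_equal(pooled_rate(1092, 48)$rate, 23L)
  expect_equal(pooled_rate(504, 15.7)$rate, 32L)
  expect_equal(pooled_rate(166, 6)$rate, 28L)
  expect_equal(pooled_rate(0, 7)$rate, 0L)
  expect_equal(pooled_rate(504, 15.7)$rate_exact, 504 / 15.7)
  expect_error(pooled_rate(10, 0), class = "shoalwatch_error")
})

test_that("response transforms are correct and monotone", {
  expect_equal(transform_response(0, "log_offset"), 0)
  expect_equal(transform_response(100, "log_offset", offset = 0), 2)
  expect_equal(transform_response(9, "power", lambda = 0.5), 3)
  set.seed(63)
  x <- sort(runif(50, 0, 100))
  for (kind in c("log_offset", "power")) {
    y <- transform_response(x, kind)
    expect_true(all(diff(y) > 0))
  }
  expect_error(transform_response(c(0, 1), "power", lambda = 0),
               class = "shoalwatch_error")
  expect_error(transform_response(-1, "log_offset"), class = "shoalwatch_error")
})

test_that("average speed matches its displacement-over-time formulation", {
  # stationary point
  tr <- trajectory(tibble::tibble(frame = 0:99, x = 5, y = 5), 30, 100 / 30)
  expect_equal(average_speed(tr), 0)
  # 1 cm per frame at 30 fps -> 30 cm/s
  tr <- trajectory(tibble::tibble(frame = 0:49, x = 1 + (0:49) * 1, y = 5), 30, 50 / 30)
  expect_equal(average_speed(tr), 30)
  # seeded random walk: equals total matched path length / total matched time
  set.seed(64)
  steps <- matrix(rnorm(2 * 200, 0, 0.5), ncol = 2)
  pos <- apply(steps, 2, cumsum) + 25
  tr <- trajectory(tibble::tibble(frame = 0:199, x = pos[, 1], y = pos[, 2]), 30, 200 / 30)
  path <- sum(sqrt(rowSums(diff(pos)^2)))
  expect_equal(average_speed(tr), path / (199 / 30), tolerance = 1e-9)
  # gaps contribute nothing
  with_gap <- tr[tr$frame != 100, ]
  tr2 <- trajectory(with_gap, 30, 200 / 30)
  d <- sqrt(rowSums(diff(pos)^2))
  d <- d[-c(100, 101)] # the two intervals touching the missing frame
  expect_equal(average_speed(tr2), mean(d) * 30, tolerance = 1e-9)
  # undefined when nothing can be matched
  lone <- trajectory(tibble::tibble(frame = c(0, 10), x = 1, y = 1), 30, 1)
  expect_warning(v <- average_speed(lone), "undefined|threshold")
  expect_true(is.na(v))
})

test_that("design enumeration reproduces the crossed-design totals", {
  res <- enumerate_design(
    list(sex = c("female", "male"), brain_size = c("large", "small"),
         shoal_size = c(1, 2, 4)),
    groups_per_cell = 12, n_replicates = 3
  )
  expect_equal(nrow(res$design), 12)
  expect_equal(res$totals$n_groups, 144)
  expect_equal(res$totals$n_fish, 336)
  expect_equal(res$totals$n_fish_per_replicate, 112)
  expect_true(res$totals$even_split)
  # totals invariant to factor ordering
  res2 <- enumerate_design(
    list(shoal_size = c(4, 2, 1), sex = c("male", "female"),
         brain_size = c("small", "large")),
    groups_per_cell = 12, n_replicates = 3
  )
  expect_equal(res2$totals, res$totals)
  # single cell
  res3 <- enumerate_design(list(stimulus = "predator"), groups_per_cell = 1)
  expect_equal(res3$totals$n_groups, 1)
  # uneven replicate split is reported, not an error
  expect_warning(
    res4 <- enumerate_design(list(shoal_size = c(1, 2)), groups_per_cell = 5,
                             n_replicates = 2),
    "evenly"
  )
  expect_false(res4$totals$even_split)
})

test_that("the response table assembles factors, summaries and transforms per trial", {
  design <- tidyr::expand_grid(brain_size = c("large", "small"),
                               replicate = factor(1:2), shoal_size = 4)
  trials <- simulate_study(design, duration_s = 60, fps = 5, base_seed = 4)
  tab <- build_response_table(trials, duration_s = 60)
  expect_equal(nrow(tab), nrow(design))
  expect_true(all(c("brain_size", "replicate", "n_inspections", "occurred",
                    "log_n_inspections", "sqrt_time_per_fish") %in% names(tab)))
  expect_equal(tab$log_n_inspections, log10(tab$n_inspections + 1))
  expect_equal(tab$sqrt_time_per_fish, sqrt(tab$time_per_fish_s))
})
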