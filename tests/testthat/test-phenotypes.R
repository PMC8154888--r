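sch <- default_speed_schedule()

test_that("absolute Ucrit interpolates within the fatigue level", {
  # levels 7 and 8 of the default schedule are 65 and 73 cm/s
  expect_equal(ucrit_absolute(8, 0, sch), 65)
  expect_equal(ucrit_absolute(8, 15, sch), 69)
  expect_equal(ucrit_absolute(8, 30, sch), 73)
  # vectorised
  expect_equal(ucrit_absolute(c(8, 8, 3), c(0, 15, 10), sch),
               c(65, 69, 25 + (10 / 30) * 8))
  expect_true(is.na(ucrit_absolute(NA, 5, sch)))
})

test_that("absolute Ucrit validates its inputs", {
  expect_error(ucrit_absolute(8, 31, sch), "time_in_level")
  expect_error(ucrit_absolute(8, -1, sch), "time_in_level")
  expect_error(ucrit_absolute(1, 10, sch), "schedule")
  expect_error(ucrit_absolute(11, 10, sch), "schedule")
})

test_that("absolute Ucrit is monotone in level and time", {
  grid <- expand.grid(level = 2:10, t = seq(0, 30, by = 5))
  u <- ucrit_absolute(grid$level, grid$t, sch)
  for (lv in 2:10) {
    ut <- u[grid$level == lv]
    expect_true(all(diff(ut[order(grid$t[grid$level == lv])]) >= 0))
  }
  for (tt in seq(0, 30, by = 5)) {
    ul <- u[grid$t == tt]
    expect_true(all(diff(ul[order(grid$level[grid$t == tt])]) >= 0))
  }
  # boundary convention: completing a level equals entering the next one
  expect_equal(ucrit_absolute(7, 30, sch), ucrit_absolute(8, 0, sch))
})

test_that("relative Ucrit is absolute Ucrit per standard length", {
  expect_equal(ucrit_relative(70, 7), 10)
  expect_equal(ucrit_relative(0, 3.2), 0)
  expect_equal(ucrit_relative(68.4, 1), 68.4)
  expect_error(ucrit_relative(70, 0), "positive")
  expect_error(ucrit_relative(70, -2), "positive")
  # agrees with direct composition through the schedule
  u <- ucrit_absolute(8, 15, sch)
  expect_equal(ucrit_relative(u, 6.9), u / 6.9)
})

test_that("surface area is the ellipse formula", {
  expect_equal(surface_area(4 / pi, 1), 1)
  expect_equal(surface_area(2, 2), pi)
  expect_equal(surface_area(7.2, 2.7), pi / 4 * 7.2 * 2.7)
  expect_error(surface_area(0, 2), "positive")
  expect_error(surface_area(2, -1), "positive")
})

test_that("daily growth coefficient matches an independent arithmetic oracle", {
  expect_equal(daily_growth_coefficient(8, 1, 100), 1)
  expect_equal(daily_growth_coefficient(55.3, 55.3, 146), 0)
  set.seed(42)
  hw <- runif(50, 50, 800)
  ws <- runif(50, 5, 60)
  dy <- sample(100:200, 50, replace = TRUE)
  oracle <- 100 * (exp(log(hw) / 3) - exp(log(ws) / 3)) / dy
  expect_equal(daily_growth_coefficient(hw, ws, dy), oracle,
               tolerance = 1e-12)
  # shrinkage gives negative values, invalid inputs error
  expect_lt(daily_growth_coefficient(10, 20, 145), 0)
  expect_error(daily_growth_coefficient(-1, 20, 145), "positive")
  expect_error(daily_growth_coefficient(10, 20, 0), "positive")
})

test_that("derive_phenotypes composes the raw fields consistently", {
  raw <- data.frame(fish_id = c("a", "b", "c"),
                    fatigue_level = c(8, 9, NA),
                    time_in_level = c(15, 7.5, NA),
                    sltest = c(7, 8, 6.5), htest = c(2.5, 3, 2.4),
                    hw = c(400, 500, 350), wstart = c(25, 30, 20),
                    days = c(145, 146, 145))
  out <- derive_phenotypes(raw, sch)
  expect_equal(out$ucrit_abs[1:2], c(69, 75))
  expect_true(is.na(out$ucrit_abs[3]))
  expect_equal(out$ucrit_rel, out$ucrit_abs / out$sltest)
  expect_equal(out$sa_test, pi / 4 * raw$sltest * raw$htest)
  expect_equal(out$dgc,
               100 * (raw$hw^(1 / 3) - raw$wstart^(1 / 3)) / raw$days)
  expect_error(derive_phenotypes(raw, schedule = NULL), "schedule")
})

test_that("trait summaries use sample SD and exclude missing values", {
  tab <- data.frame(x = c(1, 2, 3), y = c(5, NA, 7), z = c(4, 4, 4))
  s <- trait_summary(tab, c("x", "y", "z"))
  expect_equal(s$n, c(3L, 2L, 3L))
  expect_equal(s[s$trait == "x", c("mean", "sd", "cv")],
               data.frame(mean = 2, sd = 1, cv = 50),
               ignore_attr = TRUE)
  expect_equal(s[s$trait == "z", "sd"], 0)
  expect_equal(s[s$trait == "z", "cv"], 0)
  expect_equal(s[s$trait == "y", c("min", "max")],
               data.frame(min = 5, max = 7), ignore_attr = TRUE)
  expect_error(trait_summary(tab, "missing_col"), "not found")
  tab$w <- NA_real_
  expect_error(trait_summary(tab, "w"), "non-missing")
})

test_that("phenotype files are read with column remapping", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,day,W,SL", "f1,d01,10.2,7.1", "f2,d01,,6.8"), tmp)
  tab <- read_phenotypes(tmp, mapping = c(fish_id = "id", test_day = "day",
                                          wtest = "W", sltest = "SL"))
  expect_named(tab, c("fish_id", "test_day", "wtest", "sltest"))
  expect_true(is.na(tab$wtest[2]))
  expect_error(read_phenotypes(tmp, mapping = c(fish_id = "nope")),
               "absent")
})

test_that("speed schedules validate ordering and duration", {
  expect_error(speed_schedule(1:3, c(10, 9, 20)), "increasing")
  expect_error(speed_schedule(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(speed_schedule(1:3, c(1, 2, 3), level_duration = 0),
               "positive")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("level,speed_cm_s", "2,25", "1,17", "3,33"), tmp)
  sch2 <- read_speed_schedule(tmp, level_duration = 20)
  expect_equal(sch2$speed, c(17, 25, 33))
  expect_equal(sch2$level_duration, 20)
  # the packaged synthetic schedule round-trips through the reader
  pkg_sch <- read_speed_schedule(system.file("extdata",
                                             "speed_schedule_synthetic.csv",
                                             package = "swimherit"))
  expect_equal(pkg_sch$speed, default_speed_schedule()$speed)
})
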