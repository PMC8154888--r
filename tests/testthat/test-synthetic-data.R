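test_that("the default pedigree realises the study mating design", {
  cfg <- sim_config_ucrit(seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 31 + 58 + 1500)
  off <- !is.na(ped$sire_idx)
  expect_equal(sum(off), 1500)
  fams <- unique(paste(ped$sire[off], ped$dam[off]))
  expect_equal(length(fams), 60L)
  # two dams are used in two matings, with different sires
  dam_sires <- tapply(ped$sire[off], ped$dam[off],
                      function(s) length(unique(s)))
  expect_equal(sum(dam_sires == 2), 2L)
  expect_equal(sum(dam_sires), 60L)
  # sire usage follows the 12x1 + 12x2 + 4x3 + 3x4 plan
  sire_fams <- tapply(ped$dam[off], ped$sire[off],
                      function(d) length(unique(d)))
  expect_equal(sort(unname(table(sire_fams))),
               sort(c(`1` = 12, `2` = 12, `3` = 4, `4` = 3)),
               ignore_attr = TRUE)
})

test_that("offspring counts and config validation behave", {
  cfg1 <- sim_config_ucrit(seed = 1)
  cfg1$offspring_per_family <- rep(1L, 60)
  expect_equal(sum(!is.na(simulate_pedigree(cfg1)$sire_idx)), 60)
  expect_error(sim_config(traits = list(y = list(mean = 0, sigma_a2 = 1,
                                                 sigma_c2 = 0,
                                                 sigma_e2 = 1)),
                          n_sires = 3, mates_per_sire = c(1, 1)),
               "one entry per sire")
  expect_error(sim_config(traits = list(y = list(mean = 0, sigma_a2 = -1,
                                                 sigma_c2 = 0,
                                                 sigma_e2 = 1))),
               "non-negative")
  expect_error(sim_config(traits = list(y = list(mean = 0, sigma_a2 = 1,
                                                 sigma_c2 = 0,
                                                 sigma_e2 = 1)),
                          r_a = matrix(c(1, 2, 2, 1), 2)),
               "correlation")
})

test_that("a sire's offspring across two families are half sibs", {
  cfg <- small_config(seed = 6)
  dat <- simulate_dataset(cfg)
  ped <- dat$pedigree
  A <- relationship_matrix(ped)
  off <- ped$animal[!is.na(ped$sire_idx)]
  # sire S001 has two mates in the small plan
  kids <- off[ped$sire[match(off, ped$animal)] == "S001"]
  dams <- ped$dam[match(kids, ped$animal)]
  k1 <- kids[dams == unique(dams)[1]][1]
  k2 <- kids[dams == unique(dams)[2]][1]
  expect_equal(A[k1, k2], 0.25)
  full <- kids[dams == unique(dams)[1]]
  expect_equal(A[full[1], full[2]], 0.5)
})

test_that("breeding values follow the pedigree covariance structure", {
  ped <- simulate_pedigree(small_config(seed = 1))
  set.seed(2)
  expect_true(all(simulate_breeding_values(ped, matrix(0, 1, 1)) == 0))
  # founder variance matches G0 at large n
  big <- pedigree(sprintf("F%04d", 1:4000), 0, 0)
  set.seed(3)
  bv <- simulate_breeding_values(big, matrix(2.5, 1, 1))
  expect_equal(var(bv[, 1]), 2.5, tolerance = 0.15)
  # full-sib covariance approaches sigma_a2 / 2 across many families
  wide <- sim_config(traits = list(y = list(mean = 0, sigma_a2 = 4,
                                            sigma_c2 = 0, sigma_e2 = 1)),
                     n_sires = 300, n_dams = 300,
                     mates_per_sire = rep(1, 300),
                     offspring_per_family = 2, fish_per_day = 50,
                     seed = 4)
  pedw <- simulate_pedigree(wide)
  set.seed(5)
  bvw <- simulate_breeding_values(pedw, matrix(4, 1, 1))
  off <- which(!is.na(pedw$sire_idx))
  sib1 <- bvw[off[seq(1, 600, by = 2)], 1]
  sib2 <- bvw[off[seq(2, 600, by = 2)], 1]
  expect_equal(cov(sib1, sib2), 2, tolerance = 0.4)
  expect_error(simulate_breeding_values(big, matrix(-1, 1, 1)),
               "positive semi-definite")
})

test_that("phenotypes decompose exactly into their simulated parts", {
  cfg <- small_config(seed = 9)
  dat <- simulate_dataset(cfg)
  ph <- dat$phenotypes
  parts <- attr(ph, "components")
  recomposed <- parts$mu[1] + parts$day[, 1] + parts$a[, 1] +
    parts$c[, 1] + parts$e[, 1]
  expect_equal(ph$y1, unname(recomposed), tolerance = 1e-12)
  # between-family variance close to sigma_a2/2 + sigma_c2 on a large design
  cfg2 <- sim_config(traits = list(y = list(mean = 0, sigma_a2 = 8.9,
                                            sigma_c2 = 0.43,
                                            sigma_e2 = 9.12)),
                     test_day_sd = 0, seed = 10)
  vb <- vapply(11:22, function(sd_i) {
    cfg2$seed <- sd_i
    d <- simulate_dataset(cfg2)
    var(tapply(d$phenotypes$y, d$phenotypes$family, mean))
  }, 0)
  expected <- 0.5 * 8.9 + 0.43 + (0.5 * 8.9 + 9.12) / 25
  expect_equal(mean(vb), expected, tolerance = 0.2)
})

test_that("swim-test encoding inverts the Ucrit calculation", {
  sch <- default_speed_schedule()
  enc <- encode_swim_test(69, sch)
  expect_equal(enc$fatigue_level, 8)   # 65-73 cm/s interval
  expect_equal(enc$time_in_level, 15)
  # a value equal to a level speed encodes as completing that level
  enc65 <- encode_swim_test(65, sch)
  expect_equal(enc65$fatigue_level, 7)
  expect_equal(enc65$time_in_level, 30)
  # below the first tested speed but above level 1 scales from level 1
  enc_low <- encode_swim_test(21, sch)
  expect_equal(enc_low$fatigue_level, 2)
  expect_equal(enc_low$time_in_level, 15)
  expect_error(encode_swim_test(16, sch), "range")
  expect_error(encode_swim_test(90, sch), "range")
  expect_true(is.na(encode_swim_test(NA, sch)$fatigue_level))
})

test_that("encode then compute round-trips Ucrit exactly", {
  sch <- default_speed_schedule()
  set.seed(12)
  u <- c(runif(500, 17.01, 89), sch$speed[-1], 17.01, 89)
  enc <- encode_swim_test(u, sch)
  back <- ucrit_absolute(enc$fatigue_level, enc$time_in_level, sch)
  expect_lt(max(abs(back - u)), 1e-9)
})

test_that("test-day assignment spreads families and fills batches", {
  fam <- rep(1:60, each = 25)
  d <- assign_test_days(fam, fish_per_day = 50)
  expect_equal(length(unique(d)), 30L)
  expect_true(all(table(d) == 50))
  spread <- tapply(d, fam, function(x) length(unique(x)))
  expect_true(all(spread == 3))
  # day composition is 10-fish chunks from 5 families or 5-fish from 10
  comp <- tapply(seq_along(fam), d, function(i) table(fam[i]))
  expect_true(all(vapply(comp, function(tt)
    all(tt == 10) && length(tt) == 5 ||
      all(tt == 5) && length(tt) == 10, TRUE)))
  # non-tiling sizes fall back to sequential filling
  d2 <- assign_test_days(rep(1:7, each = 9), fish_per_day = 20)
  expect_true(all(table(d2)[-4] == 20))
})

test_that("datasets are reproducible by seed and vary across seeds", {
  d1 <- simulate_dataset(small_config(seed = 42))
  d2 <- simulate_dataset(small_config(seed = 42))
  d3 <- simulate_dataset(small_config(seed = 43))
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$breeding_values, d2$breeding_values)
  expect_false(isTRUE(all.equal(d1$phenotypes$y1, d3$phenotypes$y1)))
})

test_that("the study configuration reproduces record-count structure", {
  d <- simulate_dataset(sim_config_study(seed = 8))
  ph <- d$phenotypes
  expect_equal(nrow(ph), 1500L)
  expect_equal(sum(is.na(ph$fatigue_level)), 7L)   # lost swim records
  expect_equal(sum(!is.na(ph$hw)), 1199L)          # pond survival
  expect_true(abs(sum(!is.na(ph$sex)) - 763) < 40) # sexed at harvest
  # DGC recomputes exactly from harvest weight, stocking weight and days
  expect_equal(daily_growth_coefficient(ph$hw, ph$wstart, ph$days),
               ph$dgc, tolerance = 1e-9)
})
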