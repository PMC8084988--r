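test_that("Kendrick coordinates follow the ceiling convention", {
  base <- kendrick_coords(290.079038)
  expect_equal(base$km, 290, tolerance = 1e-9)
  expect_equal(base$nm_cat, 290)
  expect_equal(base$kmd, 0, tolerance = 1e-9)

  mono <- kendrick_coords(289.071762)   # [M-H]- monomer
  expect_equal(mono$kmd, 0.0070, tolerance = 1e-3)

  split <- kendrick_coords(288.565614)  # dimer [M-2H]2- with one 13C
  expect_equal(split$kmd, 0.5130, tolerance = 1e-3)

  expect_error(kendrick_coords(0), "> 0")
  expect_error(kendrick_coords(c(100, -5)), "> 0")
})

test_that("KMD lies in [0, 1) for random m/z", {
  set.seed(11)
  kmd <- kendrick_coords(runif(5e4, 1e-3, 5e3))$kmd
  expect_true(all(kmd >= 0 & kmd < 1))
})

test_that("peak classification matches the nearest ladder species within tolerance", {
  ladder <- ct_ion_ladder(6, c(1, 2), 3)

  exact <- classify_peaks(data.frame(mz = 289.071762), ladder, tol_ppm = 0.01)
  expect_true(exact$assigned)
  expect_equal(exact$n, 1L)
  expect_equal(exact$z, 1L)
  expect_equal(exact$c13_count, 0L)

  off <- classify_peaks(data.frame(mz = 289.075000), ladder, tol_ppm = 3)
  expect_false(off$assigned)

  # exact ladder values are always assigned at any positive tolerance
  hits <- classify_peaks(data.frame(mz = ladder$mz), ladder, tol_ppm = 0.01)
  expect_true(all(hits$assigned))
  expect_equal(hits$n, ladder$n)
  expect_equal(hits$c13_count, ladder$c13_count)

  # empty input is empty output, not an error
  expect_equal(nrow(classify_peaks(data.frame(mz = numeric()), ladder, 3)), 0)
  expect_error(classify_peaks(data.frame(mz = 1), ladder, tol_ppm = 0), "> 0")
})

test_that("ties between equally close ladder entries break to lower n", {
  fake <- data.frame(n = c(2L, 1L), z = c(1L, 1L), c13_count = c(0L, 0L),
                     parity = "mono", formula = "x", mz = c(500, 500))
  hit <- classify_peaks(data.frame(mz = 500), fake, tol_ppm = 3)
  expect_equal(hit$n, 1L)
})

test_that("classification agrees with a brute-force nearest-ppm oracle", {
  ladder <- ct_ion_ladder(6, c(1, 2), 4)
  set.seed(21)
  mz <- c(
    ladder$mz * (1 + rnorm(nrow(ladder), sd = 2e-6)),   # near-ladder peaks
    runif(150, 150, 1800)                               # background
  )
  got <- classify_peaks(data.frame(mz = mz), ladder, tol_ppm = 3)
  want <- brute_force_assign(mz, ladder, tol_ppm = 3)
  got_key <- ifelse(got$assigned, paste(got$n, got$z, got$c13_count),
                    NA_character_)
  expect_equal(got_key, want)
})

test_that("the doubly-charged isotopic split sits at 0.5 KMD, singly-charged lines stay together", {
  ladder <- ct_ion_ladder(6, c(1, 2), 3)
  hits <- classify_peaks(data.frame(mz = ladder$mz), ladder, tol_ppm = 1)
  split <- isotopic_split_check(hits)
  z2 <- split[split$z == 2, ]
  expect_equal(nrow(z2), 6)
  expect_true(all(abs(z2$delta_kmd - 0.5) <= 0.01))
  z1 <- split[split$z == 1, ]
  expect_true(all(z1$delta_kmd < 0.01))

  # even 13C counts return to the main line (z = 2, 13C0 vs 13C2)
  k0 <- kendrick_coords(ion_mz(ct_oligomer_formula(2), 2, 0))$kmd
  k2 <- kendrick_coords(ion_mz(ct_oligomer_formula(2), 2, 2))$kmd
  d <- abs(k0 - k2) %% 1
  expect_lt(min(d, 1 - d), 0.01)

  # no doubly-charged assignments -> empty result
  only_z1 <- hits[hits$z == 1 & !is.na(hits$z), ]
  expect_equal(nrow(isotopic_split_check(only_z1)[
    isotopic_split_check(only_z1)$z == 2, ]), 0)
})

test_that("oligomer richness counts assigned peaks by treatment, day and size", {
  ladder <- ct_ion_ladder(6, c(1, 2), 2)
  none <- classify_peaks(
    data.frame(mz = 150.0, treatment = "unamended", timepoint = 0), ladder, 3)
  expect_equal(nrow(oligomer_richness(none)), 0)

  cfg <- small_scenario()
  ft <- generate_fticr(cfg)
  hits <- classify_peaks(ft$peaks, ladder, 3)
  rich <- oligomer_richness(hits)
  # conservation: table total equals the number of assigned peaks
  expect_equal(sum(rich$count), sum(hits$assigned))
  # planted schedule: small oligomers only at day 10 in biotic soil
  biotic_small <- rich[rich$treatment == "biotic_CT" & rich$n <= 4, ]
  expect_true(all(biotic_small$timepoint == 10))
  expect_true(any(rich$n <= 4 & rich$treatment == "biotic_CT"))
})

test_that("KMD binning conserves counts and tracks the planted ladder range", {
  one <- hexbin_kmd(data.frame(mz = 400), 10, 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 1)

  set.seed(3)
  peaks <- data.frame(mz = runif(500, 200, 900))
  bins <- hexbin_kmd(peaks, 12, 8)
  expect_equal(sum(bins$count), 500)

  ladder <- ct_ion_ladder(6, 2, 1)
  lad_peaks <- data.frame(mz = ladder$mz[ladder$n >= 2])
  bins <- hexbin_kmd(lad_peaks, 20, 10)
  expect_true(all(bins$mz_bin >= min(lad_peaks$mz) &
                    bins$mz_bin <= max(lad_peaks$mz)))
})

test_that("oligomer regions pair ladder m/z extents with the two parity bands", {
  ladder <- ct_ion_ladder(3, c(1, 2), 2)
  regions <- oligomer_regions(ladder, tol_ppm = 3)
  expect_equal(nrow(regions), 6)  # 3 sizes x 2 lines
  expect_true(all(regions$mz_lo < regions$mz_hi))
  for (nn in 1:3) {
    sub <- ladder[ladder$n == nn, ]
    reg <- regions[regions$n == nn, ][1, ]
    expect_true(all(sub$mz >= reg$mz_lo & sub$mz <= reg$mz_hi))
  }
})
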