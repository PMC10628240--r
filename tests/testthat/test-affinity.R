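test_that("the residue class table partitions the 20 amino acids", {
  tab <- residue_class_table()
  expect_identical(sort(tab$residue), sort(abhumanize:::KABAT_AA))
  expect_identical(anyDuplicated(tab$residue), 0L)
  expect_setequal(unique(tab$class), c("charged", "polar", "apolar"))
  expect_error(residue_class_table(list(charged = "D", polar = "S",
                                        apolar = "A")), "partition")
})

test_that("separated chains give all-zero interfacial counts", {
  far <- make_complex(tibble::tibble(res_a = "A", res_b = "A",
                                     distance = 50), n_extra_a = 4,
                      n_extra_b = 4, seed = 81)
  ic <- count_interfacial_contacts(read_structure(far$path), "A", "B")
  expect_identical(ic$count, rep(0L, 6))
  expect_identical(ic$class_pair,
                   c("charged_charged", "charged_polar", "charged_apolar",
                     "polar_polar", "polar_apolar", "apolar_apolar"))
})

test_that("a planted interface of known composition is counted exactly", {
  pairs <- tibble::tibble(
    res_a = c("R", "R", "S", "S", "S", "L", "L", "L", "L"),
    res_b = c("D", "D", "L", "L", "L", "L", "L", "L", "L"),
    distance = c(4.5, 5.0, 3.8, 4.2, 5.5, 3.5, 4.0, 4.4, 5.2))
  cx <- make_complex(pairs, seed = 82)
  ic <- count_interfacial_contacts(read_structure(cx$path), "A", "B")
  want <- stats::setNames(ic$count, ic$class_pair)
  expect_identical(want[["charged_charged"]], 2L)
  expect_identical(want[["polar_apolar"]], 3L)
  expect_identical(want[["apolar_apolar"]], 4L)
  expect_identical(sum(ic$count), 9L)
})

test_that("IC counting matches planted truth, side swap and rigid motion", {
  n_complexes <- 100
  for (i in seq_len(n_complexes)) {
    pairs <- withr::with_seed(9000 + i, {
      n <- sample(1:8, 1)
      tibble::tibble(
        res_a = sample(abhumanize:::KABAT_AA, n, replace = TRUE),
        res_b = sample(abhumanize:::KABAT_AA, n, replace = TRUE),
        distance = round(runif(n, 3.0, 8.0), 2))
    })
    cx <- make_complex(pairs, n_extra_a = 3, n_extra_b = 3, seed = i)
    model <- read_structure(cx$path)
    ic <- count_interfacial_contacts(model, "A", "B")
    expect_identical(ic$count, cx$expected_ic$count)
    # unordered class pairs: side swap preserves every bucket
    ic_sw <- count_interfacial_contacts(model, "B", "A")
    expect_identical(ic_sw$count, ic$count)
    if (i %% 10 == 0) {
      ang <- withr::with_seed(i, stats::runif(3, 0, 2 * pi))
      moved <- transform_model(model,
                               rotation_matrix(ang[1], ang[2], ang[3]),
                               c(15, -8, 30))
      expect_identical(count_interfacial_contacts(moved, "A", "B")$count,
                       ic$count)
    }
    # bucket sum equals the number of in-range cross-side pairs
    n_in <- nrow(interface_residues(model, "A", "B", cutoff = 5.5))
    expect_identical(sum(ic$count), n_in)
  }
})

test_that("predicted dG is the configured linear form", {
  cfg <- pipeline_config()
  zero <- tibble::tibble(class_pair = c(
    "charged_charged", "charged_polar", "charged_apolar", "polar_polar",
    "polar_apolar", "apolar_apolar"), count = rep(0L, 6))
  # all-zero inputs return the intercept exactly
  expect_identical(predict_dg(zero, 0, 0), unname(cfg$dg_coefficients[["intercept"]]))
  # unit increments move dG by exactly the matching coefficient
  for (term in c("charged_charged", "charged_apolar", "polar_polar",
                 "polar_apolar")) {
    bump <- zero
    bump$count[bump$class_pair == term] <- 1L
    expect_equal(predict_dg(bump, 0, 0) - predict_dg(zero, 0, 0),
                 unname(cfg$dg_coefficients[[term]]), tolerance = 1e-12)
  }
  # charged-polar and apolar-apolar do not enter the model
  bump <- zero
  bump$count[bump$class_pair == "charged_polar"] <- 5L
  bump$count[bump$class_pair == "apolar_apolar"] <- 7L
  expect_identical(predict_dg(bump, 0, 0), predict_dg(zero, 0, 0))
  # random inputs equal an independent dot-product oracle
  for (seed in 1:20) {
    ic <- withr::with_seed(seed, sample(0:60, 6, replace = TRUE))
    nis <- withr::with_seed(seed + 50, runif(2, 0, 100))
    tab <- zero
    tab$count <- ic
    got <- predict_dg(tab, nis[1], nis[2])
    co <- cfg$dg_coefficients
    want <- sum(c(ic[1], ic[3], ic[4], ic[5], nis[1], nis[2], 1) *
                  c(co[["charged_charged"]], co[["charged_apolar"]],
                    co[["polar_polar"]], co[["polar_apolar"]],
                    co[["nis_apolar"]], co[["nis_charged"]],
                    co[["intercept"]]))
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(predict_dg(zero, 0, 0, coefficients = c(intercept = 1)),
               "missing")
})

test_that("dG and Kd are exact inverses through RT log", {
  expect_identical(dg_to_kd(0), 1)
  for (dg in seq(-20, 5, by = 2.5)) {
    expect_equal(kd_to_dg(dg_to_kd(dg)), dg, tolerance = 1e-9)
  }
  for (kd in 10^seq(-12, -3)) {
    expect_equal(dg_to_kd(kd_to_dg(kd)), kd, tolerance = 1e-9)
  }
  # monotone: deeper dG means tighter Kd
  expect_lt(dg_to_kd(-14.5), dg_to_kd(-12.1))
})

test_that("the end-to-end profile matches stagewise oracles", {
  pairs <- tibble::tibble(
    res_a = c("R", "K", "S", "L", "L"), res_b = c("D", "E", "L", "L", "F"),
    distance = c(4.0, 5.2, 4.6, 3.6, 5.0))
  cx <- make_complex(pairs, extra_a = c("A", "D", "S"),
                     extra_b = c("L", "K", "T"), seed = 83)
  model <- read_structure(cx$path)
  prof <- interface_profile(model, "A", "B")
  expect_identical(prof$ic_counts$count, cx$expected_ic$count)
  # NIS truth: extras only (A,D,S | L,K,T): 2 apolar, 2 charged, 2 polar
  expect_equal(prof$nis_apolar_pct, 100 * 2 / 6, tolerance = 1e-9)
  expect_equal(prof$nis_charged_pct, 100 * 2 / 6, tolerance = 1e-9)
  want_dg <- predict_dg(cx$expected_ic, prof$nis_apolar_pct,
                        prof$nis_charged_pct)
  expect_equal(prof$delta_g, want_dg, tolerance = 1e-12)
  expect_equal(prof$kd, exp(want_dg / (1.9872e-3 * 298.15)),
               tolerance = 1e-12)
  # glance mirrors the report column layout
  g <- glance(prof)
  expect_identical(names(g)[1:2], c("dG_kcal_mol", "Kd_M_at_25C"))
  expect_identical(unname(unlist(g[1, 3:8])), prof$ic_counts$count)
})
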