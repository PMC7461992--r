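test_that("index recovery on air decays exponentially", {
  expect_identical(decay_index(1e8, 0), 1e8)
  expect_equal(decay_index(1e8, 10), 1e8 * exp(-0.79), tolerance = 1e-12)
  # half-life identity: trec = ln 2 / 0.079 halves the index
  expect_equal(decay_index(1e8, log(2) / 0.079), 5e7, tolerance = 1e-9)
  expect_error(decay_index(1e8, -1), "trec")
  expect_error(decay_index(-1, 5), "K must")
})

test_that("equivalent time inverts the index at a given pressure", {
  cD <- cns_params("DRY_REST")$c
  expect_identical(equivalent_time(0, 2.8, cD), 0)
  for (t in c(0.5, 12, 60, 300)) {
    for (p in c(2.26, 2.8, 3.67)) {
      expect_equal(equivalent_time(cns_ot_index(t, p, cD), p, cD), t,
                   tolerance = 1e-10)
    }
  }
  # log-domain arithmetic oracle: exp(0.5*(17.915 - 12.99*ln 2.5))
  expect_equal(equivalent_time(exp(17.915), 2.5, cD), 20.2086,
               tolerance = 1e-4)
  expect_error(equivalent_time(1e8, 0, cD), "po2")
})

test_that("a single oxygen segment reduces to the closed-form index", {
  dry <- cns_params("DRY_REST")
  pr <- exposure_profile(list(segment(2.8, 45)), dry)
  tr <- accumulate_profile(pr)
  expect_identical(attr(tr, "final_K"), cns_ot_index(45, 2.8, dry$c))
  expect_identical(attr(tr, "final_risk"),
                   cns_ot_risk(cns_ot_index(45, 2.8, dry$c), dry))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$time_min, c(0, 45))
})

test_that("trajectories record every boundary with monotone K per segment", {
  pr <- exposure_profile(list(segment(2.8, 20), segment(0.6, 5),
                              segment(2.8, 20), segment(0.6, 5),
                              segment(2.8, 20)), "DRY_REST")
  tr <- accumulate_profile(pr)
  expect_equal(nrow(tr), nrow(pr$segments) + 1L)
  expect_true(all(tr$K >= 0))
  kinds <- pr$segments$kind
  dK <- diff(tr$K)
  expect_true(all(dK[kinds == "oxygen"] > 0))
  expect_true(all(dK[kinds == "air"] < 0))
  # dense sampling agrees with the boundary-only trajectory at the end
  tr_dense <- accumulate_profile(pr, step = 1)
  expect_equal(attr(tr_dense, "final_K"), attr(tr, "final_K"))
  expect_true(nrow(tr_dense) > nrow(tr))
})

test_that("splitting an oxygen segment at the same PO2 changes nothing", {
  set.seed(11)
  for (rep in 1:10) {
    d <- runif(1, 10, 60)
    cut <- runif(1, 0.1, 0.9) * d
    p <- runif(1, 2.2, 3.7)
    whole <- accumulate_profile(
      exposure_profile(list(segment(2.8, 15), segment(0.5, 6),
                            segment(p, d)), "DRY_REST"))
    split <- accumulate_profile(
      exposure_profile(list(segment(2.8, 15), segment(0.5, 6),
                            segment(p, cut), segment(p, d - cut)),
                       "DRY_REST"))
    expect_equal(attr(split, "final_K"), attr(whole, "final_K"),
                 tolerance = 1e-10)
  }
})

test_that("zero-length air breaks are identities, positive ones help", {
  base <- exposure_profile(list(segment(2.8, 20), segment(2.8, 20)),
                           "DRY_REST")
  zero <- exposure_profile(list(segment(2.8, 20), segment(0.6, 0),
                                segment(2.8, 20)), "DRY_REST")
  brk <- exposure_profile(list(segment(2.8, 20), segment(0.6, 5),
                               segment(2.8, 20)), "DRY_REST")
  K0 <- attr(accumulate_profile(base), "final_K")
  expect_equal(attr(accumulate_profile(zero), "final_K"), K0,
               tolerance = 1e-12)
  expect_lt(attr(accumulate_profile(brk), "final_K"), K0)
  expect_lt(attr(accumulate_profile(brk), "final_risk"),
            attr(accumulate_profile(base), "final_risk"))
})

test_that("accumulation matches the fine-step brute-force integrator", {
  set.seed(42)
  for (rep in 1:8) {
    pr <- random_profile()
    K_pkg <- attr(accumulate_profile(pr), "final_K")
    K_bf <- bf_integrate(pr$segments, pr$params$c)
    expect_lt(abs(K_pkg - K_bf) / K_bf, 1e-3)
  }
})

test_that("profiles reject unusable inputs", {
  expect_error(exposure_profile(list(), "DRY_REST"), "at least one segment")
  expect_error(segment(2.8, -5), "duration")
  ip <- structure(list(segments = segment(2.8, 20),
                       params = interpolate_met(2.7)),
                  class = "exposure_profile")
  expect_error(accumulate_profile(ip), "no sigma")
})

test_that("segment kinds auto-classify by PO2 against the threshold", {
  expect_equal(segment(0.21, 5)$kind, "air")
  expect_equal(segment(2.8, 5)$kind, "oxygen")
  expect_equal(segment(1.2, 5, threshold = 1.4)$kind, "air")
  df <- data.frame(po2 = c(2.5, 0.5, 2.5), duration = c(30, 10, 30))
  pr <- exposure_profile(df, "DRY_REST")
  expect_equal(pr$segments$kind, c("oxygen", "air", "oxygen"))
})

test_that("profile files round-trip exactly through YAML and JSON", {
  pr <- exposure_profile(list(segment(2.5, 30), segment(0.5, 10),
                              segment(2.5, 30)), "DRY_REST")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_profile(pr, path)
    back <- read_profile(path)
    expect_identical(back$segments, pr$segments)
    expect_equal(back$params$name, "DRY_REST")
    expect_identical(attr(accumulate_profile(back), "final_K"),
                     attr(accumulate_profile(pr), "final_K"))
  }
  expect_error(read_profile("no-such-file.yaml"), "no such profile")
})

test_that("trajectory tables round-trip bit-exactly", {
  pr <- exposure_profile(list(segment(2.8, 20), segment(0.6, 5),
                              segment(2.8, 20)), "DRY_REST")
  tr <- accumulate_profile(pr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_identical(back$time_min, tr$time_min)
  expect_identical(back$K, tr$K)
  expect_identical(back$risk, tr$risk)
})

test_that("bundled treatment profiles reproduce the published predictions", {
  hbot <- read_profile(system.file("extdata/profiles",
                                   "hbot_60min_2p5_break10.yaml",
                                   package = "cnsot"))
  expect_equal(100 * attr(accumulate_profile(hbot), "final_risk"), 1.16,
               tolerance = 0.05 / 1.16)
  tt6 <- read_profile(system.file("extdata/profiles", "usn_tt6_first3.yaml",
                                  package = "cnsot"))
  expect_equal(100 * attr(accumulate_profile(tt6), "final_risk"), 12.7,
               tolerance = 0.1 / 12.7)
})
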