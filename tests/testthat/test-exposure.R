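p_tab <- exposure_params("table-consistent")
p_girls <- exposure_params("stated-girls")

test_that("chronic daily intake follows the intake equation", {
  expect_equal(compute_cdi(0, p_tab), 0)
  # 0.175 * 1 * 230 * 5 / (15 * 1150)
  expect_equal(compute_cdi(0.175, p_tab), 0.0116667, tolerance = 1e-5)
  # with ef*ed = at the formula reduces to c * ir / bw
  expect_equal(compute_cdi(2.76, p_girls), 2.76 / 20, tolerance = 1e-12)
  expect_error(compute_cdi(Inf, p_tab), "finite")
  expect_error(compute_cdi(-1, p_tab), ">= 0")
})

test_that("hazard quotients reproduce the published union extremes", {
  expect_equal(round(compute_hq(0.175, "as", p_tab), 2), 38.89)
  expect_equal(round(compute_hq(3.66, "fe", p_tab), 2), 34.86)
  expect_equal(round(compute_hq(2.76, "fe", p_tab), 2), 26.29)
  expect_equal(round(compute_hq(3.38, "fe", p_tab), 2), 32.19)
  expect_equal(round(compute_hq(0.075, "as", p_tab), 2), 16.67)
  expect_equal(compute_hq(0, "fe", p_tab), 0)
  expect_equal(format_hq(compute_hq(2.72, "fe", p_tab)), "25.9")
})

test_that("hazard index is the sum of quotients", {
  expect_equal(compute_hi(c(fe = 32.19, as = 38.89)), 71.08)
  expect_equal(compute_hi(c(fe = 0.5)), 0.5)
  expect_equal(compute_hi(c(fe = 0, as = 0)), 0)
  expect_error(compute_hi(numeric(0)), "at least one")
  expect_error(compute_hi(c(fe = -1)), "non-negative")
})

test_that("hazard quotient is scale-equivariant and hits 1 at c = bw * rfd", {
  set.seed(1)
  cs <- runif(50, 0, 3)
  ks <- runif(50, 0, 5)
  expect_equal(compute_hq(ks * cs, "fe", p_tab), ks * compute_hq(cs, "fe", p_tab),
               tolerance = 1e-12)
  for (nm in c("table-consistent", "stated-girls", "stated-boys")) {
    p <- exposure_params(nm)
    for (a in c("fe", "as")) {
      expect_equal(compute_hq(p$bw * p$rfd[[a]], a, p), 1, tolerance = 1e-12)
    }
  }
})

test_that("risk_table holds the HQ/HI identities per sample", {
  d <- random_dataset(7, n = 40)
  rt <- risk_table(d, p_tab)
  expect_equal(rt$hi, rt$hq_fe + rt$hq_as, tolerance = 1e-12)
  expect_equal(rt$hq_fe, rt$cdi_fe / p_tab$rfd[["fe"]], tolerance = 1e-12)
  expect_true(all(rt$hi >= 0))
})

test_that("union summary reduces correctly for single-sample unions", {
  d <- make_dataset(fe = 2.76, as_conc = 0, union_name = "Bagoan")
  s <- union_risk_summary(d, p_tab)
  expect_equal(s$n_hq_fe_gt1, 1L)
  expect_equal(round(s$hq_fe_min, 2), 26.29)
  expect_equal(round(s$hq_fe_max, 2), 26.29)
  expect_equal(s$n_hq_as_gt1, 0L)

  z <- make_dataset(fe = c(0, 0), as_conc = c(0, 0),
                    union_name = c("Bagoan", "Dariapur"))
  sz <- union_risk_summary(z, p_tab)
  expect_true(all(sz$n_hq_fe_gt1 == 0))
  expect_true(all(sz$hi_min == 0 & sz$hi_max == 0))

  bad <- make_dataset(union_name = "Elsewhere")
  expect_error(union_risk_summary(bad, p_tab), "unknown union")
})

test_that("a sample carrying both published maxima yields the published HI maximum", {
  d <- make_dataset(
    fe = c(3.38, 0.2, 0.1), as_conc = c(0.175, 0.01, 0),
    union_name = "Dariapur", depth = c(120, 300, 500)
  )
  s <- union_risk_summary(d, p_tab)
  expect_equal(round(s$hi_max, 2), 71.08)
})

test_that("union summary equals a brute-force per-sample recomputation", {
  for (seed in 1:5) {
    d <- random_dataset(seed, n = 50)
    s <- union_risk_summary(d, p_tab)
    for (u in unique(d$union_name)) {
      rows <- d[d$union_name == u, ]
      hq_fe <- rows$fe * p_tab$ir * p_tab$ef * p_tab$ed /
        (p_tab$bw * p_tab$at * p_tab$rfd[["fe"]])
      hq_as <- rows$as_conc * p_tab$ir * p_tab$ef * p_tab$ed /
        (p_tab$bw * p_tab$at * p_tab$rfd[["as"]])
      su <- s[s$union_name == u, ]
      expect_equal(su$n, nrow(rows))
      expect_equal(su$n_hq_fe_gt1, sum(hq_fe > 1))
      expect_equal(su$n_hq_as_gt1, sum(hq_as > 1))
      if (any(hq_fe > 1)) {
        expect_equal(su$hq_fe_max, max(hq_fe[hq_fe > 1]), tolerance = 1e-12)
      }
      expect_equal(su$hi_min, min(hq_fe + hq_as), tolerance = 1e-12)
      expect_equal(su$hi_max, max(hq_fe + hq_as), tolerance = 1e-12)
    }
  }
})
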