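# Functional-group counting and the HCL/DS statistics.

test_that("functional-group counts follow the straight-chain closed form", {
  cases <- list(
    list(fa = fatty_acid(18, 1), exp = list(1L, 14L, 2L, 1L)), # oleic
    list(fa = fatty_acid(16, 0), exp = list(1L, 14L, 0L, 1L)), # palmitic
    list(fa = fatty_acid(4, 1), exp = list(1L, 0L, 2L, 1L))    # minimal chain
  )
  for (cs in cases) {
    g <- count_functional_groups(cs$fa)
    expect_identical(unname(unlist(g)),
                     unname(unlist(cs$exp)))
  }
})

test_that("malformed fatty acids are rejected", {
  expect_error(fatty_acid(3, 0), "at least 4 carbons")
  expect_error(fatty_acid(16, -1), "double_bonds")
  expect_error(fatty_acid(16, 8), "double_bonds") # floor((16-2)/2) = 7
  expect_silent(fatty_acid(16, 7))
})

test_that("HCL and DS reproduce the worked single-acid values", {
  expect_equal(fatty_acid_hcl(fatty_acid(16, 0)), 16)
  expect_equal(fatty_acid_hcl(fatty_acid(18, 0)), 18)
  expect_equal(fatty_acid_hcl(fatty_acid(18, 2)), 18)
  expect_equal(fatty_acid_hcl(fatty_acid(14, 0)), 14)
  expect_equal(fatty_acid_ds(fatty_acid(16, 0)), 1)
  expect_equal(fatty_acid_ds(fatty_acid(18, 1)), 0.875)
  expect_equal(round_half_away(fatty_acid_ds(fatty_acid(18, 1)), 2), 0.88)
  expect_equal(round_half_away(fatty_acid_ds(fatty_acid(18, 3)), 2), 0.63)
})

test_that("HCL equals the carbon number and counts conserve carbon (property)", {
  for (c_n in 4:26) {
    for (d in 0:min(6, (c_n - 2) %/% 2)) {
      fa <- fatty_acid(c_n, d)
      g <- count_functional_groups(fa)
      expect_identical(g$n_ch3 + g$n_ch2 + g$n_ch + g$n_cooh, c_n)
      expect_equal(fatty_acid_hcl(fa), c_n)
    }
  }
})

test_that("DS decreases strictly with unsaturation and is 1 iff saturated", {
  for (c_n in c(6, 12, 18, 22)) {
    ds <- vapply(0:((c_n - 2) %/% 2),
                 function(d) fatty_acid_ds(fatty_acid(c_n, d)), 1)
    expect_true(all(diff(ds) < 0))
    expect_equal(ds[1], 1)
    expect_true(all(ds[-1] < 1))
  }
})

test_that("shorthand parser accepts the field's notations", {
  expect_equal(parse_fatty_acid("16:0")$carbons, 16L)
  expect_equal(parse_fatty_acid("C18:2")$double_bonds, 2L)
  fa <- parse_fatty_acid("18:2(n-6)")
  expect_equal(c(fa$carbons, fa$double_bonds), c(18L, 2L))
  expect_error(parse_fatty_acid("18-2"), "cannot parse")
  expect_error(parse_fatty_acid("oleic"), "cannot parse")
})

test_that("composition invariants are enforced", {
  expect_error(fatty_acid_composition(c("16:0" = 0.5, "18:2" = 0.6)),
               "sum to 1")
  expect_error(fatty_acid_composition(c("16:0" = 0.5, "C16:0" = 0.5)),
               "duplicated")
  expect_error(fatty_acid_composition(c("16:0" = 1.2, "18:2" = -0.2)),
               "non-negative")
  expect_error(fatty_acid_composition(numeric(0)), "empty")
})

test_that("composition profiles match hand-computed pooled ratios", {
  single <- fatty_acid_composition(c("16:0" = 1))
  expect_equal(composition_profile(single)$hcl, 16)
  expect_equal(composition_profile(single)$ds, 1)

  half <- fatty_acid_composition(c("16:0" = 0.5, "18:2" = 0.5))
  p <- composition_profile(half, "pooled")
  expect_equal(p$hcl, 17)
  expect_equal(p$ds, (14 + 12) / (14 + 16)) # pooled CH2 over CH+CH2

  oleic <- fatty_acid_composition(c("18:1" = 1))
  expect_equal(composition_profile(oleic)$ds, 0.875)
})

test_that("pooled HCL equals the molar-weighted mean carbon number (property)", {
  panel <- default_fatty_acid_panel()
  withr::with_seed(101, {
    for (i in 1:25) {
      f <- rgamma(nrow(panel), 1)
      f <- f / sum(f)
      names(f) <- panel$fatty_acid
      comp <- fatty_acid_composition(f)
      expect_equal(composition_profile(comp, "pooled")$hcl,
                   sum(f * panel$carbons))
      # pooled and weighted agree on HCL, not necessarily on DS
      expect_equal(composition_profile(comp, "weighted")$hcl,
                   sum(f * panel$carbons))
    }
  })
})

test_that("tissue profiles stay within the per-acid HCL and DS ranges", {
  panel <- default_fatty_acid_panel()
  withr::with_seed(202, {
    for (i in 1:25) {
      f <- rgamma(nrow(panel), 0.5)
      f <- f / sum(f)
      names(f) <- panel$fatty_acid
      for (mode in c("pooled", "weighted")) {
        pr <- composition_profile(fatty_acid_composition(f), mode)
        expect_gte(pr$hcl, min(panel$hcl)); expect_lte(pr$hcl, max(panel$hcl))
        expect_gte(pr$ds, min(panel$ds)); expect_lte(pr$ds, max(panel$ds))
      }
    }
  })
})

test_that("composition CSV round trips including total lipid", {
  comp <- fatty_acid_composition(c("16:0" = 0.4, "18:2" = 0.35, "18:3" = 0.25),
                                 total_lipid = 123.4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition(comp, path)
  back <- read_composition(path)
  expect_equal(back$molar_fraction, comp$molar_fraction)
  expect_equal(back$fatty_acid, comp$fatty_acid)
  expect_equal(attr(back, "total_lipid"), 123.4)
})

test_that("scatter data: single-acid tissue coincides with its vertex", {
  comp <- fatty_acid_composition(c("18:3" = 1))
  pr <- composition_profile(comp)
  sc <- hcl_ds_scatter_data(pr, fatty_acid_properties("18:3"))
  expect_equal(sc$points$hcl, sc$vertices$hcl)
  expect_equal(sc$points$ds, sc$vertices$ds)
})

test_that("major-acid hull has the expected vertices and contains weighted points", {
  panel <- fatty_acid_properties(c("16:0", "18:2", "18:3"))
  expect_equal(panel$hcl, c(16, 18, 18))
  expect_equal(panel$ds, c(1, 0.75, 0.625))

  # brute-force: weighted-mode points are convex combinations of vertices
  in_triangle <- function(p, v) {
    # barycentric sign test with tolerance
    s <- function(a, b, c) (a[1] - c[1]) * (b[2] - c[2]) -
                           (b[1] - c[1]) * (a[2] - c[2])
    d1 <- s(p, v[1, ], v[2, ]); d2 <- s(p, v[2, ], v[3, ])
    d3 <- s(p, v[3, ], v[1, ])
    tol <- 1e-9
    !(any(c(d1, d2, d3) < -tol) && any(c(d1, d2, d3) > tol))
  }
  v <- cbind(panel$hcl, panel$ds)
  withr::with_seed(303, {
    for (i in 1:50) {
      f <- rgamma(3, 1); f <- f / sum(f)
      names(f) <- panel$fatty_acid
      pr <- composition_profile(fatty_acid_composition(f), "weighted")
      expect_true(in_triangle(c(pr$hcl, pr$ds), v))
    }
  })
})
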