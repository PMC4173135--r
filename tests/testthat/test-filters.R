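ok_base <- c(MW = 300, LogP = 2, HBD = 1, HBA = 4, RB = 3, arB = 6)

test_that("Lipinski bounds are inclusive and violations are counted", {
  expect_true(filter_lipinski(c(MW = 500, LogP = 5, HBD = 5,
                                HBA = 10))$passed)
  r1 <- filter_lipinski(c(MW = 501, LogP = 5, HBD = 5, HBA = 10))
  expect_equal(r1$violations, 1L)
  expect_false(r1$passed)
  expect_equal(r1$violated_criteria[[1]], "MW")
  r4 <- filter_lipinski(c(MW = 600, LogP = 6, HBD = 6, HBA = 11))
  expect_equal(r4$violations, 4L)
})

test_that("Tice ranges include their bounds; the RB bound is strict", {
  herb <- filter_tice_herbicide
  expect_false(herb(replace(ok_base, "MW", 149))$passed)
  expect_equal(herb(replace(ok_base, "MW", 149))$violated_criteria[[1]],
               "MW")
  expect_true(herb(c(MW = 300, LogP = 3.5, HBD = 3, HBA = 2,
                     RB = 11))$passed)
  expect_false(herb(replace(ok_base, "RB", 12))$passed)
  expect_true(herb(replace(ok_base, "MW", 150))$passed)
  expect_true(herb(replace(ok_base, "MW", 500))$passed)

  ins <- filter_tice_insecticide
  r <- ins(c(MW = 300, LogP = -0.1, HBD = 1, HBA = 4, RB = 3))
  expect_false(r$passed)
  expect_equal(r$violated_criteria[[1]], "logP")
  expect_true(ins(c(MW = 300, LogP = 0, HBD = 2, HBA = 1, RB = 11))$passed)
  expect_false(ins(replace(ok_base, "HBA", 0))$passed)
  expect_false(ins(replace(ok_base, "HBA", 9))$passed)
})

test_that("Hao bounds are all inclusive and need aromatic-bond counts", {
  expect_true(filter_hao(c(MW = 435, LogP = 6, HBD = 2, HBA = 6, RB = 9,
                           arB = 17))$passed)
  r <- filter_hao(c(MW = 435, LogP = 6, HBD = 2, HBA = 6, RB = 9,
                    arB = 18))
  expect_false(r$passed)
  expect_equal(r$violated_criteria[[1]], "aromatic bonds")
  expect_true(filter_hao(c(MW = 100, LogP = 0, HBD = 0, HBA = 0, RB = 0,
                           arB = 0))$passed)
  expect_error(filter_hao(c(MW = 300, LogP = 2, HBD = 1, HBA = 4,
                            RB = 3)),
               "aromatic-bond")
})

test_that("missing descriptors are reported by name", {
  expect_error(filter_lipinski(c(MW = 300, LogP = 2, HBD = 1)), "HBA")
})

test_that("violation counts always equal the violated-criteria list length", {
  set.seed(12)
  dv <- data.frame(MW = runif(200, 50, 900), LogP = runif(200, -6, 12),
                   HBD = sample(0:8, 200, TRUE),
                   HBA = sample(0:15, 200, TRUE),
                   RB = sample(0:20, 200, TRUE),
                   arB = sample(0:25, 200, TRUE))
  for (f in list(filter_lipinski, filter_tice_herbicide,
                 filter_tice_insecticide, filter_hao)) {
    r <- f(dv)
    expect_equal(r$violations,
                 vapply(r$violated_criteria, length, integer(1)))
    expect_equal(r$passed, r$violations == 0L)
  }
})

test_that("worsening a descriptor never decreases the violation count", {
  set.seed(13)
  for (k in 1:20) {
    dv <- c(MW = runif(1, 100, 600), LogP = runif(1, -2, 8),
            HBD = sample(0:6, 1), HBA = sample(0:12, 1),
            RB = sample(0:15, 1), arB = sample(0:20, 1))
    worse <- dv + c(200, 3, 3, 5, 6, 8)  # push every bounded direction up
    for (f in list(filter_lipinski, filter_hao))
      expect_gte(f(worse)$violations, f(dv)$violations)
  }
})

test_that("apply_filters reports per-rule pass columns and percentages", {
  dv <- data.frame(id = c("a", "b"),
                   MW = c(300, 600), LogP = c(2, 7), HBD = c(1, 6),
                   HBA = c(4, 12), RB = c(3, 14), arB = c(6, 20))
  res <- apply_filters(dv)
  expect_true(res$lipinski_pass[1])
  expect_false(res$lipinski_pass[2])
  pct <- attr(res, "pass_pct")
  expect_equal(unname(pct["lipinski"]), 50)
  expect_equal(unname(pct["hao"]), 50)
})
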