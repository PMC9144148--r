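# Autofluorescence correction, %ID normalization and Monte-Carlo recovery.

test_that("area-scaled autofluorescence cancels exactly", {
  # experimental TRE that is pure autofluorescence at the control's density
  out <- correct_autofluorescence(tre_exp = c(6, 3), area_exp = c(3, 1.5),
                                  tre_ctrl = c(4, 4), area_ctrl = c(2, 2))
  expect_equal(out$corrected_tre, c(0, 0))
  expect_false(any(out$clamped))
})

test_that("zero control fluorescence leaves the signal untouched", {
  out <- correct_autofluorescence(5, 2, 0, 2)
  expect_equal(out$corrected_tre, 5)
})

test_that("negative corrections clamp to zero with a flag", {
  expect_warning(
    out <- correct_autofluorescence(c(1, 10), c(2, 2), c(4, 1), c(2, 2)),
    "clamped")
  expect_equal(out$corrected_tre[1], 0)
  expect_true(out$clamped[1])
  expect_false(out$clamped[2])
})

test_that("invalid TRE/area inputs are rejected", {
  expect_error(correct_autofluorescence(1, 0, 1, 1), "> 0")
  expect_error(correct_autofluorescence(1, 1, 1, 0), "> 0")
  expect_error(correct_autofluorescence(-1, 1, 1, 1), ">= 0")
  expect_error(correct_autofluorescence(c(1, 2), 1, 1, 1), "length")
})

test_that("percent ID is the share of corrected fluorescence", {
  tb <- data.frame(organ = c("a", "b"), corrected_tre = c(3, 0))
  expect_equal(percent_id_from_tre(tb)$percent_id, c(100, 0))
  tb$corrected_tre <- c(2, 2)
  expect_equal(percent_id_from_tre(tb)$percent_id, c(50, 50))
})

test_that("an all-autofluorescence table triggers the undefined-%ID error", {
  areas <- default_organ_areas()
  ctrl <- data.frame(organ = names(areas), tre = 10 * areas, area = areas)
  exp_ <- data.frame(organ = names(areas), tre = 10 * areas, area = areas)
  corrected <- correct_organ_table(exp_, ctrl)
  expect_true(all(corrected$corrected_tre == 0))
  expect_error(percent_id_from_tre(corrected), "undefined")
})

test_that("%ID tables always sum to 100 within 1e-6", {
  set.seed(2)
  for (i in 1:20) {
    tb <- data.frame(organ = letters[1:9],
                     corrected_tre = rexp(9) * 10^runif(1, 0, 8))
    expect_lt(abs(sum(percent_id_from_tre(tb)$percent_id) - 100), 1e-6)
  }
})

test_that("organ-table generator honours its contracts", {
  truth <- c("left kidney" = 100)
  tabs <- simulate_organ_tables(truth, autofl_per_area = 2,
                                areas = c("left kidney" = 1.5),
                                noise_cv = 0, seed = 1)
  corr <- correct_organ_table(tabs$experimental, tabs$control)
  expect_gt(corr$corrected_tre[1], 0)

  nine <- rep(100 / 9, 9)
  names(nine) <- renal_organs()
  tabs <- simulate_organ_tables(nine, 1, noise_cv = 0, seed = 2)
  expect_setequal(tabs$experimental$organ, renal_organs())
  # noiseless recovery is exact
  pid <- percent_id_from_tre(
    correct_organ_table(tabs$experimental, tabs$control))
  expect_equal(pid$percent_id, rep(100 / 9, 9), tolerance = 1e-9)

  expect_error(simulate_organ_tables(c(a = 60, b = 30), 1,
                                     areas = c(a = 1, b = 1)), "sum to 100")
  expect_error(simulate_organ_tables(c(a = 110, b = -10), 1,
                                     areas = c(a = 1, b = 1)),
               "non-negative")
  expect_error(simulate_organ_tables(c(a = 50, b = 50), 1,
                                     areas = c(a = 0, b = 1)), "> 0")
})

test_that("zero true %ID with concentrated dose stays concentrated", {
  truth <- c("left kidney" = 100, "right kidney" = 0, liver = 0)
  tabs <- simulate_organ_tables(truth, autofl_per_area = 3,
                                noise_cv = 0, seed = 3)
  corr <- correct_organ_table(tabs$experimental, tabs$control)
  expect_true(corr$corrected_tre[corr$organ == "left kidney"] > 0)
  expect_equal(corr$corrected_tre[corr$organ != "left kidney"], c(0, 0),
               tolerance = 1e-9)
})

test_that("recovered %ID tracks truth across noisy replicates", {
  truth <- c("left kidney" = 44, "right kidney" = 5, lungs = 6, heart = 2,
             liver = 25, spleen = 3, stomach = 5, intestines = 9,
             appendix = 1)
  errs <- sapply(1:300, function(i) {
    tabs <- simulate_organ_tables(truth, autofl_per_area = 1e5,
                                  noise_cv = 0.05, seed = 1000 + i)
    suppressWarnings(
      pid <- percent_id_from_tre(
        correct_organ_table(tabs$experimental, tabs$control)))
    abs(pid$percent_id - unname(truth[pid$organ]))
  })
  expect_lt(max(apply(errs, 1, stats::median)), 2)
})

test_that("digest %ID is the mass ratio in percent", {
  expect_equal(percent_id_injected(3, 3), 100)
  expect_equal(percent_id_injected(0, 3), 0)
  expect_equal(percent_id_injected(0.9, 3), 30)
  expect_error(percent_id_injected(1, 0), "> 0")
  expect_error(percent_id_injected(-1, 2), ">= 0")
})

test_that("kinetics assembly preserves rows, totals and kidney ratio", {
  tb <- function(l, r) {
    structure(data.frame(organ = c("left kidney", "right kidney"),
                         percent_id = c(l, r)), total_tre = l + r)
  }
  single <- assemble_timecourse(list(`1 min` = tb(80, 20)), form = "free")
  expect_equal(nrow(single), 2)
  expect_equal(single$form, c("free", "free"))

  tps <- c("1 min", "15 min", "1 h", "3 h", "6 h", "24 h")
  tabs <- lapply(seq_along(tps), function(i) tb(90 - 5 * i, 10 + 5 * i))
  names(tabs) <- tps
  tc <- assemble_timecourse(tabs, "encapsulated")
  expect_equal(nrow(tc), 6 * 2)
  expect_equal(attr(tc, "totals")$timepoint, tps)
  kr <- kidney_ratio(tc)
  expect_equal(kr$ratio[1], 85 / 15)
  expect_true(all(diff(kr$ratio) < 0))

  tabs2 <- tabs
  names(tabs2) <- c("1 min", "1 min", tps[3:6])
  expect_error(assemble_timecourse(tabs2, "free"), "duplicate")
})
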