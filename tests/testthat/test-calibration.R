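test_that("standard line is the zero-intercept least-squares fit", {
  # exactly proportional standards
  ln <- fit_standard_line(c(5, 25, 50), c(1000, 5000, 10000), "s")
  expect_equal(ln$slope, 200)
  expect_equal(ln$r2_uncentered, 1)
  expect_true(ln$valid)
  expect_lt(ln$p_value, 0.01)

  # closed form sum(xy)/sum(x^2), frozen from the formula
  ln2 <- fit_standard_line(c(5, 25, 50), c(900, 4600, 9300), "s")
  expect_equal(ln2$slope, 584500 / 3150)
  expect_gt(ln2$r2_uncentered, 0.93)

  # degenerate inputs
  ln3 <- fit_standard_line(c(5, 25, 50), c(0, 0, 0), "s")
  expect_false(ln3$valid)
  expect_identical(ln3$reason, "no_amplification")
  ln4 <- fit_standard_line(c(5, 25, 50), c(0, 0, 7), "s")
  expect_false(ln4$valid)
  expect_identical(ln4$reason, "too_few_nonzero_standards")
  expect_error(fit_standard_line(5, 100), "at least 2")
  expect_error(fit_standard_line(c(0, 25), c(1, 2)), "strictly positive")
})

test_that("fitted slope matches the brute-force SSE minimizer", {
  set.seed(11)
  for (i in 1:25) {
    x <- sort(runif(3, 1, 60))
    y <- rpois(3, runif(1, 50, 900) * x)
    ln <- fit_standard_line(x, y)
    expect_equal(ln$slope, oracle_slope(x, y), tolerance = 1e-6)
  }
})

test_that("reads convert to copies by division through the standard line", {
  ln <- fit_standard_line(c(5, 25, 50), c(1000, 5000, 10000), "s")
  expect_equal(reads_to_copies(1000, ln), 5)
  expect_equal(reads_to_copies(0, ln), 0)
  ln2 <- fit_standard_line(c(5, 25, 50), c(900, 4600, 9300), "s")
  expect_equal(reads_to_copies(75, ln2), 75 * 3150 / 584500)
  expect_equal(reads_to_copies(75, ln2), 0.40419, tolerance = 1e-4)
  bad <- fit_standard_line(c(5, 25, 50), c(0, 0, 0), "s")
  expect_true(is.na(reads_to_copies(100, bad)))
})

test_that("per-litre scaling applies (elution/template)/volume", {
  expect_equal(scale_to_per_litre(5, 1, 100, 2), 250)
  expect_equal(scale_to_per_litre(7.3, 1, 50, 50), 7.3)
  expect_equal(scale_to_per_litre(0, 2, 100, 2), 0)
  expect_error(scale_to_per_litre(1, 0, 100, 2), "positive")
})

test_that("blank subtraction floors at zero and leaves unmatched taxa alone", {
  res <- subtract_blank(c(A = 10, B = 2, C = 4), c(A = 2, B = 5))
  expect_equal(res$values, c(A = 8, B = 0, C = 4))
  expect_equal(res$floored, c(A = FALSE, B = TRUE, C = FALSE))
  # never negative, whatever the pair (property)
  set.seed(3)
  for (i in 1:50) {
    f <- setNames(runif(6, 0, 10), letters[1:6])
    b <- setNames(runif(4, 0, 10), letters[2:5])
    out <- subtract_blank(f, b)$values
    expect_true(all(out >= 0))
    expect_equal(unname(out["a"]), unname(f["a"]))
  }
})

test_that("taxon filters exclude, merge and threshold deterministically", {
  m <- matrix(c(4, 6, 9, 10, 2, 0), 3, 2,
              dimnames = list(c("A", "B", "T3"), c("s1", "s2")))
  out <- apply_taxon_filters(m, list(excluded_taxa = "T3"))
  expect_identical(rownames(out), c("A", "B"))
  out2 <- apply_taxon_filters(m, list(merged_taxa = list(AB = c("A", "B"))))
  expect_equal(out2["AB", "s1"], 10)
  expect_equal(out2["AB", "s2"], 12)
  # read threshold boundary: < 10 zeroed, exactly 10 kept
  out3 <- apply_taxon_filters(m, list(min_reads_per_cell = 10),
                              is_read_table = TRUE)
  expect_equal(out3["T3", "s1"], 0)   # 9 -> 0
  expect_equal(out3["A", "s2"], 10)   # 10 kept
  expect_equal(out3["B", "s2"], 0)    # 2 -> 0
  expect_error(
    apply_taxon_filters(m, list(merged_taxa = list(T3 = c("A", "B")))),
    "collides")
  expect_warning(apply_taxon_filters(m, list(excluded_taxa = "ghost")),
                 "unknown taxa")
})

test_that("calibrate_run recovers noiseless copies and applies the blank rule", {
  toy <- make_toy_run()
  cal <- calibrate_run(toy$counts, toy$manifest)
  # field copies minus blank contamination, floored at zero
  expect_equal(cal$copies["A", "field1"], 500 - 50)
  expect_equal(cal$copies["B", "field1"], 0)
  expect_equal(cal$copies["C", "field1"], 120)
  expect_identical(cal$provenance["A", "field1"], "blank_corrected")
  expect_identical(cal$provenance["C", "field1"], "raw")
  # negative with 75 reads under the 100-read threshold: reported, no warning
  expect_equal(cal$qc$negative_controls$max_taxon_reads, 75)
  expect_length(cal$qc$warnings, 0)
  # standard lines recorded for field and blank, not the negative
  expect_setequal(cal$standard_lines$sample_id, c("field1", "blank1"))
  expect_equal(cal$standard_lines$slope[cal$standard_lines$sample_id == "field1"],
               200, tolerance = 1e-12)
})

test_that("a sample without standard amplification is uncalibratable, not zero", {
  toy <- make_toy_run()
  counts <- toy$counts
  counts[c("std1", "std2", "std3"), "field1"] <- 0L
  cal <- calibrate_run(counts, toy$manifest)
  expect_true(all(is.na(cal$copies[, "field1"])))
  expect_true(all(cal$provenance[, "field1"] == "uncalibratable"))
  expect_match(cal$qc$warnings, "uncalibratable", all = FALSE)
})

test_that("hot PCR negatives are flagged above the warn threshold", {
  toy <- make_toy_run(neg_reads = c(A = 0, B = 150, C = 0))
  cal <- calibrate_run(toy$counts, toy$manifest)
  expect_match(cal$qc$warnings, "exceeds 100 reads", all = FALSE)
})

test_that("scaling a sample's reads leaves its copy estimates unchanged", {
  toy <- make_toy_run(blank_copies_L = c(A = 0))
  base <- calibrate_run(toy$counts, toy$manifest)
  scaled <- toy$counts
  scaled[, "field1"] <- scaled[, "field1"] * 2L
  cal2 <- calibrate_run(scaled, toy$manifest)
  expect_equal(cal2$copies[, "field1"], base$copies[, "field1"],
               tolerance = 1e-13)
})

test_that("within a sample, more reads never means fewer copies", {
  set.seed(21)
  sim <- simulate_experiment(sim_config(n_sites = 6, n_taxa = 10,
                                        blank_contamination_rate = 0, seed = 21))
  cal <- calibrate_run(sim$counts, sim$manifest)
  taxa <- rownames(cal$copies)
  for (sid in colnames(cal$copies)) {
    reads <- sim$counts[taxa, sid]
    ord <- order(reads)
    expect_true(all(diff(cal$copies[taxa[ord], sid]) >= 0))
  }
})
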