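test_that("Kendall tau-b matches the pair-enumeration oracle and cor.test", {
  expect_equal(kendall_tau(1:3, 1:3)$tau_b, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau_b, -1)

  # tied example, checked against the brute-force pair count
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  kt <- kendall_tau(x, y)
  orc <- oracle_tau_b(x, y)
  expect_equal(kt$tau_b, orc$tau_b)
  expect_equal(kt$concordant, orc$conc)
  expect_equal(kt$ties_x, orc$tx)

  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    kt <- kendall_tau(a, b)
    expect_equal(kt$tau_b, oracle_tau_b(a, b)$tau_b, tolerance = 1e-12)
    # independent library cross-check of the estimate
    ct <- suppressWarnings(stats::cor.test(a, b, method = "kendall"))
    expect_equal(kt$tau_b, unname(ct$estimate), tolerance = 1e-12)
    if (n > 8) {
      # tie-adjusted normal approximation agrees with cor.test's z p-value
      expect_equal(kt$p_value, ct$p.value, tolerance = 1e-10)
    }
  }

  expect_true(is.na(kendall_tau(c(1, 1, 1), c(1, 2, 3))$tau_b))
  expect_identical(kendall_tau(c(1, 1, 1), c(1, 2, 3))$reason, "constant_input")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("exact permutation p-values match full enumeration", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    kt <- kendall_tau(a, b)
    expect_identical(kt$p_method, "exact")
    expect_equal(kt$p_value, oracle_exact_p(a, b), tolerance = 1e-12)
  }
  # tau is invariant under strictly monotone transforms of either variable
  x <- c(0.3, 2, 5, 5, 9, 14); y <- c(1, 0, 3, 8, 8, 20)
  expect_equal(kendall_tau(exp(x), y)$tau_b, kendall_tau(x, y)$tau_b)
  expect_equal(kendall_tau(x, y^3 + 1)$tau_b, kendall_tau(x, y)$tau_b)
})

test_that("copies-vs-capture correlation pools and splits by cluster", {
  copies <- matrix(c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20), 2, 5,
                   dimnames = list(c("tA", "tB"), paste0("s", 1:5)))
  capture <- expand.grid(site_id = paste0("s", 1:5), taxon = c("tA", "tB"),
                         stringsAsFactors = FALSE)
  capture$abundance <- as.integer(copies[cbind(capture$taxon, capture$site_id)] / 2)
  capture$biomass_g <- capture$abundance * 3
  res <- correlate_copies_vs_capture(copies, capture, response = "abundance")
  expect_equal(nrow(res), 1)
  expect_equal(res$tau_b, 1)
  expect_equal(res$n_pairs, 10)

  # coupling in one cluster, anti-coupling in the other
  copies2 <- matrix(c(1:4, 4:1), 1, 8,
                    dimnames = list("tA", paste0("s", 1:8)))
  cap2 <- data.frame(site_id = paste0("s", 1:8), taxon = "tA",
                     abundance = rep(1:4, 2), biomass_g = rep(1:4, 2) * 2.5,
                     stringsAsFactors = FALSE)
  clusters <- setNames(rep(1:2, each = 4), paste0("s", 1:8))
  res2 <- correlate_copies_vs_capture(copies2, cap2, clusters, "abundance")
  expect_equal(res2$tau_b[res2$scope == "cluster_1"], 1)
  expect_equal(res2$tau_b[res2$scope == "cluster_2"], -1)
  expect_lt(abs(res2$tau_b[res2$scope == "all_sites"]), 1)

  # double zeros are excluded by default, kept on request
  copies3 <- matrix(c(0, 1, 2, 5), 1, 4,
                    dimnames = list("tA", paste0("s", 1:4)))
  cap3 <- data.frame(site_id = paste0("s", 2:4), taxon = "tA",
                     abundance = c(1L, 3L, 6L), biomass_g = c(1, 3, 6))
  expect_equal(correlate_copies_vs_capture(copies3, cap3)$n_pairs, 3)
  expect_equal(correlate_copies_vs_capture(copies3, cap3,
                                           drop_double_zero = FALSE)$n_pairs, 4)
})

test_that("taxa enter per-taxon models only when both methods detect them", {
  copies <- matrix(0, 3, 5, dimnames = list(c("tA", "tB", "tC"), paste0("s", 1:5)))
  copies["tA", 1:3] <- 10   # 3 eDNA sites
  copies["tB", 1:5] <- 10   # 5 eDNA sites
  copies["tC", 1:4] <- 10
  capture <- data.frame(
    site_id = c("s1", "s2", "s3", "s1", "s2", "s1", "s2", "s3", "s4"),
    taxon = c("tA", "tA", "tA", "tB", "tB", "tC", "tC", "tC", "tC"),
    abundance = 1L, biomass_g = 1, stringsAsFactors = FALSE
  )
  expect_setequal(select_taxa_for_models(copies, capture, min_sites = 3),
                  c("tA", "tC"))  # tB: 2 capture sites only
  expect_setequal(select_taxa_for_models(copies, capture, min_sites = 1),
                  c("tA", "tB", "tC"))
})

test_that("negative-binomial GLM recovers a known coefficient", {
  set.seed(71)
  x <- runif(200, 0, 100)
  y <- rnbinom(200, mu = exp(1 + 0.05 * x), size = 2)
  fit <- fit_glm_nb(y, x, id = "sim")
  expect_true(fit$converged)
  expect_equal(fit$estimate, 0.05, tolerance = 0.15)
  expect_lt(fit$p, 1e-6)
  expect_equal(fit$z, fit$estimate / fit$se)
  expect_gt(fit$theta, 0)

  # degenerate responses flag instead of throwing
  zero_fit <- fit_glm_nb(rep(0, 10), 1:10)
  expect_false(zero_fit$converged)
  expect_error(fit_glm_nb(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_warning(fit_glm_nb(c(1.4, 2.6, 3.9, 5.2), 1:4), "rounding")
})

test_that("group GLMs pool member taxa rows", {
  copies <- matrix(c(3, 8, 20, 41, 3, 8, 20, 41), 2, 4, byrow = TRUE,
                   dimnames = list(c("tA", "tB"), paste0("s", 1:4)))
  capture <- expand.grid(site_id = paste0("s", 1:4), taxon = c("tA", "tB"),
                         stringsAsFactors = FALSE)
  capture$abundance <- rep(c(1L, 2L, 3L, 4L), 2)
  capture$biomass_g <- capture$abundance * 5
  single <- fit_glm_nb(copies["tA", ], capture$abundance[capture$taxon == "tA"],
                       id = "tA")
  grp <- fit_group_glms(copies, capture, list(solo = "tA", both = c("tA", "tB")))
  expect_equal(grp$estimate[grp$id == "solo"], single$estimate, tolerance = 1e-6)
  expect_equal(grp$n_obs[grp$id == "both"], 8)
  # identical duplicated rows: same coefficient as the single-taxon fit
  expect_equal(grp$estimate[grp$id == "both"], single$estimate, tolerance = 1e-4)
  expect_warning(fit_group_glms(copies[, 1:2], capture[capture$site_id %in%
                                                         c("s1", "s2"), ],
                                list(tiny = "tA")), "skipped")
})

test_that("qPCR cross-validation regression behaves on exact and noisy data", {
  q <- c(1, 4, 9, 16, 25)
  r <- suppressWarnings(compare_with_qpcr(q, q))  # exact fit: lm warns
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1)

  r2 <- suppressWarnings(compare_with_qpcr(0.5 * q, q))
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$r2, 1)

  set.seed(19)
  qpcr <- runif(15, 10, 200)
  qmiseq <- 0.58 * qpcr + rnorm(15, sd = 1)
  r3 <- compare_with_qpcr(qmiseq, qpcr)
  expect_equal(r3$slope, 0.58, tolerance = 0.05 / 0.58)
  expect_lt(r3$p_value, 0.05)

  expect_warning(r4 <- compare_with_qpcr(c(0, 2, 3.4, 4.9), c(1, 2, 3, 4),
                                         scale = "log10"), "dropped")
  expect_equal(r4$n, 3)
  expect_error(compare_with_qpcr(c(1, 2), c(1, 2)), "at least 3")
})
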