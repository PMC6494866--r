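test_that("ratio normalization recovers depth ratios and edge cases", {
  m <- withr::with_seed(1, matrix(rpois(40, 20) + 1, nrow = 8,
                                  dimnames = list(paste0("t", 1:8),
                                                  paste0("s", 1:5))))
  tab <- count_table(m)
  # identical samples: equal size factors
  same <- count_table(matrix(rep(m[, 1], 4), ncol = 4,
                             dimnames = list(rownames(m), paste0("s", 1:4))))
  sf_same <- normalize_counts(same)$size_factors
  expect_equal(unname(sf_same), rep(1, 4))
  # doubling a sample doubles its size factor
  dbl <- count_table(cbind(m, s6 = m[, 1] * 2))
  sf <- normalize_counts(dbl)$size_factors
  expect_equal(unname(sf["s6"] / sf["s1"]), 2, tolerance = 1e-10)
  # single sample: factor 1
  one <- count_table(m[, 1, drop = FALSE])
  expect_equal(unname(normalize_counts(one)$size_factors), 1)
  # disjoint sample falls back with a warning
  disj <- count_table(matrix(c(5, 3, 0, 0, 0, 0, 4, 6), nrow = 4,
                             dimnames = list(paste0("t", 1:4),
                                             c("a", "b"))))
  w <- testthat::capture_warnings(normalize_counts(disj))
  expect_true(any(grepl("fallback", w)))
  expect_equal(unname(normalize_counts(tab, method = "tss")$size_factors),
               unname(colSums(m) / exp(mean(log(colSums(m))))))
})

test_that("prevalence and abundance filters exclude strictly below bounds", {
  n <- 100
  m <- matrix(0, nrow = 3, ncol = n,
              dimnames = list(c("rare", "lowab", "ok"), paste0("s", 1:n)))
  m["rare", 1:9] <- 50          # prevalence 9% -> excluded
  m["lowab", 1:50] <- 1         # max proportion ~0.1% -> excluded
  m["ok", ] <- 1000
  m["ok", 1] <- 998             # keeps depths ~1000
  tab <- count_table(m)
  st <- apply_filters(tab)
  expect_equal(st$status[st$taxon == "rare"], "excluded:prevalence")
  expect_equal(st$status[st$taxon == "lowab"], "excluded:abundance")
  expect_equal(st$status[st$taxon == "ok"], "tested")
  # boundary: prevalence exactly 10% and max proportion exactly 0.2% tested
  m2 <- matrix(c(rep(1, 10), rep(0, 90),
                 rep(499, 100)), nrow = 2, byrow = TRUE,
               dimnames = list(c("edge", "fill"), paste0("s", 1:100)))
  st2 <- apply_filters(count_table(m2))
  expect_equal(st2$status[st2$taxon == "edge"], "tested")
})

test_that("the permutation t-test matches exhaustive enumeration", {
  # perfectly separated toy groups: 2 extreme assignments out of C(6,3)
  res <- permutation_t_test(c(0, 0, 0, 5, 5, 5),
                            rep(c("a", "b"), each = 3))
  expect_true(res$exact)
  expect_equal(res$p, 2 / 20)
  # random data, n = 8: agree with a t.test()-based brute force
  x <- withr::with_seed(21, rnorm(8))
  labels <- rep(c("a", "b"), each = 4)
  res8 <- permutation_t_test(x, labels)
  t_obs <- unname(t.test(x[1:4], x[5:8])$statistic)
  expect_equal(res8$t, t_obs, tolerance = 1e-10)
  splits <- combn(8, 4)
  t_all <- apply(splits, 2, function(idx)
    unname(t.test(x[idx], x[-idx])$statistic))
  expect_equal(res8$p, mean(abs(t_all) >= abs(t_obs) - 1e-12))
  # sign symmetry
  res_swap <- permutation_t_test(x, rep(c("b", "a"), each = 4))
  expect_equal(res_swap$t, -res8$t)
  expect_equal(res_swap$p, res8$p)
  # constant input: p = 1 with a warning
  expect_warning(resc <- permutation_t_test(rep(2, 10),
                                            rep(c("a", "b"), 5)),
                 "zero pooled")
  expect_equal(resc$p, 1)
})

test_that("large-sample permutation p-values are add-one estimates", {
  x <- withr::with_seed(22, c(rnorm(20), rnorm(20, 3)))
  res <- permutation_t_test(x, rep(c("a", "b"), each = 20), n_perm = 499,
                            seed = 7)
  expect_false(res$exact)
  expect_equal(res$p, 1 / 500)  # separation: no permutation exceeds
  expect_gt(res$p, 0)           # never exactly zero by construction
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  for (s in 1:5) {
    p <- withr::with_seed(s, runif(200))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("rank-wise differential abundance flags the depleted genera", {
  coh <- generate_cohort(cohort_spec(
    n_reference = 25, n_case = 50, n_taxa = 30,
    differential_taxa = 4:9, fold_change = 0.15,
    dysbiotic_fraction = 1, low_depth_fraction = 0,
    depth_meanlog = log(8000), seed = 33))
  res <- differential_abundance(coh$table, coh$metadata, ranks = "genus",
                                n_perm = 500, seed = 2)
  expect_true(all(res$rank == "genus"))
  expect_true(all(is.na(res$q[res$status != "tested"])))
  truth_hit <- res$taxon %in% sprintf("Genus%03d", 4:9)
  expect_gt(mean(res$q[truth_hit] < 0.05, na.rm = TRUE), 0.8)
  # q computed within the tested set only
  tested <- res[res$status == "tested", ]
  expect_equal(tested$q, bh_fdr(tested$p))
})

test_that("power is monotone in effect size and near-zero under the null", {
  powers <- vapply(c(0.3, 0.6, 1), function(fc) {
    ps <- power_spec(n1 = 15, n2 = 25, n_taxa = 30,
                     differential_taxa = 4:8, fold_change = fc,
                     n_replicates = 40, depth_meanlog = log(5000),
                     seed = 99)
    power_simulation(ps)$average_power
  }, numeric(1))
  expect_true(all(diff(powers) <= 0.05))  # non-increasing toward fold 1
  expect_lt(powers[3], 0.05)              # null: FDR-bounded
  ps <- power_spec(n1 = 10, n2 = 12, n_taxa = 20, differential_taxa = 3:6,
                   fold_change = 0.1, n_replicates = 30,
                   depth_meanlog = log(5000), seed = 100)
  res <- power_simulation(ps)
  expect_gte(res$any_detection_power, max(res$per_taxon_power))
  expect_error(power_spec(fold_change = -1), "> 0")
})
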