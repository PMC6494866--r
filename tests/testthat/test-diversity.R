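test_that("alpha diversity metrics match direct evaluation", {
  expect_equal(shannon(c(25, 25, 25, 25)), 2)
  expect_equal(shannon(c(100)), 0)
  expect_equal(shannon(c(10, 30, 60)),
               -sum(c(.1, .3, .6) * log2(c(.1, .3, .6))))
  expect_equal(shannon(c(10, 30, 60), base = exp(1)),
               -sum(c(.1, .3, .6) * log(c(.1, .3, .6))))
  expect_equal(observed_taxa(c(5, 0, 2)), 2)
  expect_equal(pielou_evenness(c(7, 7, 7)), 1)
  expect_equal(pielou_evenness(c(42)), 1)
  expect_equal(pielou_evenness(c(10, 30, 60)),
               shannon(c(10, 30, 60)) / log2(3))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(observed_taxa(numeric(3)), "all-zero")
})

test_that("Faith's PD spans the minimal root-connected subtree", {
  tree <- toy_tree()
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1), tree), 5)
  expect_equal(faith_pd(c(A = 0, B = 0, C = 3), tree), 2)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 0), tree), 3)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 0), tree,
                        include_root = FALSE), 2)
  expect_error(faith_pd(c(A = 1, D = 1), tree), "absent")
})

test_that("Faith's PD agrees with picante on random trees", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(sprintf("T%02d", 1:12), seed = 6)
  m <- withr::with_seed(7, matrix(rpois(5 * 12, 2), nrow = 5,
                                  dimnames = list(paste0("s", 1:5),
                                                  tree$tip.label)))
  m[1, ] <- pmax(m[1, ], 1)  # avoid an all-zero sample
  ours <- apply(m, 1, function(x) faith_pd(x, tree))
  ref <- picante::pd(m, tree, include.root = TRUE)$PD
  expect_equal(unname(ours), ref, tolerance = 1e-10)
})

test_that("Bray-Curtis handles boundary cases and the printed example", {
  m <- matrix(c(6, 4, 2, 8, 6, 4), nrow = 2,
              dimnames = list(c("t1", "t2"), c("u", "v", "w")))
  tab <- count_table(m)
  d <- bray_curtis(tab)
  expect_equal(d["u", "v"], 0.4)  # (4+4)/20
  expect_equal(d["u", "w"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  disj <- count_table(matrix(c(5, 0, 0, 3), nrow = 2,
                             dimnames = list(c("t1", "t2"), c("a", "b"))))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
})

test_that("unweighted UniFrac is the unique/union branch-length ratio", {
  tree <- toy_tree()
  m <- matrix(c(1, 0, 0,
                1, 1, 0,
                1, 1, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  d <- unweighted_unifrac(count_table(m), tree)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s2", "s3"], 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  md <- matrix(c(1, 0, 0, 0, 1, 0), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("x", "y")))
  expect_equal(unweighted_unifrac(count_table(md), star)["x", "y"], 1)
})

test_that("unweighted UniFrac agrees with picante on random data", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(sprintf("T%02d", 1:10), seed = 8)
  m <- withr::with_seed(9, matrix(rbinom(6 * 10, 1, 0.5), ncol = 6,
                                  dimnames = list(tree$tip.label,
                                                  paste0("s", 1:6))))
  m[1, ] <- 1  # no empty samples
  ours <- unweighted_unifrac(count_table(m), tree)
  ref <- as.matrix(picante::unifrac(t(m), tree))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("rarefaction subsamples exactly, drops shallow samples, is seeded", {
  m <- matrix(c(50, 30, 20,
                10, 5, 5,
                2, 1, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("deep", "mid", "shallow")))
  tab <- count_table(m)
  r <- suppressMessages(rarefy(tab, 20, seed = 3))
  expect_setequal(colnames(r$counts), c("deep", "mid"))
  expect_true(all(sample_depths(r) == 20))
  expect_equal(r$counts[, "mid"], tab$counts[, "mid"])  # exact depth kept
  r2 <- suppressMessages(rarefy(tab, 20, seed = 3))
  expect_identical(r$counts, r2$counts)
  expect_error(suppressMessages(rarefy(tab, 1000)), "no samples")
})

test_that("rarefaction preserves expected proportions", {
  m <- matrix(c(50, 30, 20), nrow = 3,
              dimnames = list(c("A", "B", "C"), "s"))
  tab <- count_table(m)
  draws <- vapply(1:1000, function(i)
    rarefy(tab, 10, seed = i)$counts[, 1], numeric(3))
  # hypergeometric mean 10*p, sd of the 1000-draw mean from hypergeom var
  p <- c(.5, .3, .2)
  v <- 10 * p * (1 - p) * (100 - 10) / (100 - 1)
  expect_true(all(abs(rowMeans(draws) - 10 * p) < 3 * sqrt(v / 1000)))
})

test_that("PCoA reconstructs Euclidean configurations", {
  pts <- withr::with_seed(4, matrix(rnorm(20), ncol = 2))
  rownames(pts) <- paste0("s", 1:10)
  dm <- as.matrix(dist(pts))
  ord <- pcoa(dm)
  expect_equal(as.matrix(dist(ord$coordinates[, 1:2])), dm,
               tolerance = 1e-8)
  expect_equal(sum(ord$percent_variance), 100)
  # three equidistant points: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  ev <- pcoa(eq)$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  # duplicated sample lands on identical coordinates
  dm2 <- as.matrix(dist(pts[c(1, 1, 2, 3, 4), ]))
  ord2 <- pcoa(dm2)
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[2, ],
               tolerance = 1e-8)
  expect_error(pcoa(dm[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA matches exhaustive enumeration and vegan's pseudo-F", {
  pts <- withr::with_seed(12, matrix(rnorm(12), ncol = 2))
  rownames(pts) <- paste0("s", 1:6)
  dm <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 3)
  res <- permanova(dm, labels, n_perm = 999, seed = 1)
  expect_true(res$exact)
  # brute-force oracle over all 20 label assignments
  f_obs <- permanova_f_oracle(dm, labels)
  splits <- combn(6, 3)
  f_all <- apply(splits, 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"
    permanova_f_oracle(dm, lab)
  })
  expect_equal(res$f, f_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(f_all >= f_obs - 1e-12))
  fit <- vegan::adonis2(as.dist(dm) ~ g,
                        data = data.frame(g = labels), permutations = 99)
  expect_equal(res$f, fit$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates distinct clusters at the attainable minimum", {
  pts <- withr::with_seed(13, rbind(matrix(rnorm(20), ncol = 2),
                                    matrix(rnorm(20, mean = 10), ncol = 2)))
  rownames(pts) <- paste0("s", 1:20)
  dm <- as.matrix(dist(pts))
  res <- permanova(dm, rep(c("a", "b"), each = 10), n_perm = 999, seed = 2)
  expect_false(res$exact)
  expect_equal(res$p, 1 / 1000)
  expect_error(permanova(dm, c(rep("a", 19), "b")), ">= 2 samples")
})

test_that("axis group tests correct pairwise t-tests jointly", {
  g1 <- withr::with_seed(14, rnorm(20))
  x <- c(g1, g1 + 5, g1)  # g3 identical to g1: its pair is null exactly
  labels <- rep(c("g1", "g2", "g3"), each = 20)
  res <- axis_group_tests(x, labels)
  expect_equal(nrow(res), 3L)
  expect_lt(res$q[res$group1 == "g1" & res$group2 == "g2"], 1e-4)
  expect_equal(res$q[res$group1 == "g1" & res$group2 == "g3"], 1)
  w <- testthat::capture_warnings(
    axis_group_tests(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")))
  expect_true(all(grepl("skipping", w)))
})

test_that("alpha_diversity assembles the per-sample table", {
  coh <- tiny_cohort(seed = 51)
  tab <- suppressMessages(filter_low_depth(coh$table))
  a <- suppressMessages(alpha_diversity(tab, tree = coh$tree,
                                        rarefy_depth = 500, seed = 1))
  expect_true(all(c("observed_taxa", "shannon", "pielou_evenness",
                    "faith_pd") %in% colnames(a)))
  expect_true(all(a$pielou_evenness >= 0 & a$pielou_evenness <= 1))
  expect_true(all(a$observed_taxa <= nrow(tab$counts)))
  expect_true(all(a$faith_pd >= 0))
})
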