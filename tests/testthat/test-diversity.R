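test_that("CLR centres each sample exactly", {
  expect_equal(unname(clr_normalize(matrix(5, 1, 4,
                 dimnames = list("s", letters[1:4])))),
               matrix(0, 1, 4), ignore_attr = TRUE)
  v <- clr_normalize(matrix(c(1, 3), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(unname(v[1, ]), c(-0.3466, 0.3466), tolerance = 1e-4)
  expect_equal(unname(v[1, ]),
               log(c(2, 4)) - mean(log(c(2, 4))), tolerance = 1e-12)
  m <- counts(SIM$table)[1:5, ]
  expect_lt(max(abs(rowSums(clr_normalize(m)))), 1e-9)
  expect_error(clr_normalize(matrix(c(0, 1), 1,
                 dimnames = list("s", c("a", "b"))), offset = 0),
               "offset")
})

test_that("rarefaction defaults to 99% of the minimum depth", {
  m <- matrix(c(5095, 5100, 6000, 6001), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  ct <- count_table(m)   # totals 10195 and 12001
  r <- rarefy_table(ct, seed = 1)
  expect_true(all(totals(r) == 10093))  # floor(0.99 * 10195)

  # depth equal to a sample's total leaves it unchanged
  r2 <- rarefy_table(ct, depth = 10195, seed = 1)
  expect_equal(counts(r2)["s1", ], m["s1", ])
  # shallower samples are dropped with a warning
  expect_warning(r3 <- rarefy_table(ct, depth = 11000, seed = 1),
                 "dropping")
  expect_equal(sample_ids(r3), "s2")
})

test_that("rarefied counts match the hypergeometric expectation", {
  ct <- count_table(matrix(c(30, 70), 1,
                           dimnames = list("s", c("a", "b"))))
  draws <- vapply(1:400, function(s)
    counts(rarefy_table(ct, depth = 50, seed = s))[1, "a"], numeric(1))
  # E[count of a] = depth * 30/100 = 15
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 15), 3 * se)
  expect_true(all(draws >= 0 & draws <= 30))
  # reproducible for a fixed seed
  expect_identical(counts(rarefy_table(ct, depth = 50, seed = 7)),
                   counts(rarefy_table(ct, depth = 50, seed = 7)))
})

test_that("alpha diversity matches hand arithmetic and vegan", {
  ct <- count_table(matrix(c(40, 0, 0,
                             30, 30, 0,
                             10, 10, 20), 3, byrow = TRUE,
                           dimnames = list(c("one", "two", "three"),
                                           c("a", "b", "c"))))
  a <- alpha_diversity(ct)
  expect_equal(a$richness, c(1, 2, 3))
  expect_equal(a$shannon, c(0, log(2), 1.0397), tolerance = 1e-4)
  expect_equal(a$inv_simpson, c(1, 2, 2.6667), tolerance = 1e-4)
  # independent route: vegan on the same matrix
  expect_equal(a$shannon,
               unname(vegan::diversity(counts(ct), "shannon")),
               tolerance = 1e-12)
  expect_equal(a$inv_simpson,
               unname(vegan::diversity(counts(ct), "invsimpson")),
               tolerance = 1e-12)
})

test_that("rarefaction curves honour the Hill identities at full depth", {
  ct <- count_table(matrix(c(10, 10, 20), 1,
                           dimnames = list("s", c("a", "b", "c"))))
  rc <- re_curves(ct, grid = 40, n_boot = 25, seed = 1)
  a <- alpha_diversity(ct)
  expect_equal(rc$estimate[rc$q == 0], a$richness, tolerance = 1e-12)
  expect_equal(rc$estimate[rc$q == 1], exp(a$shannon),
               tolerance = 1e-12)
  expect_equal(rc$estimate[rc$q == 2], a$inv_simpson,
               tolerance = 1e-12)
  # at full depth the draw is exhaustive, so the CI is degenerate
  expect_equal(rc$lower, rc$estimate, tolerance = 1e-12)
})

test_that("expected interpolated richness matches exhaustive enumeration", {
  # two SVs at 50/50, sub-sample of 2 reads without replacement:
  # E[richness] = 1 * P(same SV twice) + 2 * P(two different SVs)
  ct <- count_table(matrix(c(50, 50), 1,
                           dimnames = list("s", c("a", "b"))))
  p_same <- 2 * (50 / 100) * (49 / 99)
  expected <- 1 * p_same + 2 * (1 - p_same)
  rc <- re_curves(ct, q = 0, grid = 2, n_boot = 4000, seed = 2)
  # Monte-Carlo mean of a {1,2}-valued draw
  p_hat <- rc$estimate - 1
  se <- sqrt(p_hat * (1 - p_hat) / 4000)
  expect_lt(abs(rc$estimate - expected), 3 * se)
})

test_that("the order-0 curve is non-decreasing and bands cover the estimate", {
  ct <- subset_table(SIM$table, samples = 1:2)
  rc <- re_curves(ct, n_boot = 50, seed = 3)
  for (sid in unique(rc$sample_id)) {
    r0 <- rc[rc$sample_id == sid & rc$q == 0, ]
    expect_true(all(diff(r0$estimate[order(r0$m)]) >= 0))
  }
  expect_true(all(rc$estimate >= rc$lower - 1e-9 &
                    rc$estimate <= rc$upper + 1e-9))
  expect_warning(re_curves(ct, grid = c(10, 1e7), n_boot = 5, seed = 1),
                 "skipped")
})

test_that("distances match a naive double loop and basic identities", {
  m <- matrix(c(2, 0, 1,
                0, 2, 1,
                2, 0, 1), 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  ct <- count_table(m)
  db <- as.matrix(distance_matrix(ct, "bray_curtis"))
  de <- as.matrix(distance_matrix(m, "euclidean"))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(db[i, j], sum(abs(m[i, ] - m[j, ])) /
                   sum(m[i, ] + m[j, ]), tolerance = 1e-12)
    expect_equal(de[i, j], sqrt(sum((m[i, ] - m[j, ])^2)),
                 tolerance = 1e-12)
  }
  expect_equal(db["s1", "s3"], 0)          # identical samples
  expect_true(all(db >= 0 & db <= 1))
  expect_equal(db, t(db))
  # disjoint support -> Bray-Curtis 1
  dj <- count_table(matrix(c(2, 0, 0, 2), 2, byrow = TRUE,
                           dimnames = list(c("x", "y"), c("a", "b"))))
  expect_equal(as.matrix(distance_matrix(dj, "bray_curtis"))["x", "y"],
               1)
})

test_that("PCoA reproduces closed-form and spectral identities", {
  # equilateral triangle with side 2: eigenvalues (2, 2, 0)
  D <- matrix(2, 3, 3); diag(D) <- 0
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  p <- pcoa(D)
  expect_equal(p$eigenvalues, c(2, 2, 0), tolerance = 1e-10)
  expect_equal(as.matrix(dist(p$coordinates)), D, tolerance = 1e-10,
               ignore_attr = TRUE)

  # duplicated sample -> identical coordinates; eigenvalue sum = trace
  clr <- clr_normalize(subset_table(SIM$table, samples = 1:6))
  clr <- rbind(clr, dup = clr[1, ])
  d <- distance_matrix(clr, "euclidean")
  p2 <- pcoa(d)
  expect_equal(p2$coordinates[1, ], p2$coordinates["dup", ],
               ignore_attr = TRUE, tolerance = 1e-8)
  G <- -0.5 * (diag(7) - 1 / 7) %*% as.matrix(d)^2 %*% (diag(7) - 1 / 7)
  expect_equal(sum(p2$eigenvalues), sum(diag(G)), tolerance = 1e-10)

  expect_warning(z <- pcoa(matrix(0, 3, 3)), "zero")
  expect_true(all(z$coordinates == 0))
})

test_that("PCoA agrees with an independent implementation", {
  clr <- clr_normalize(subset_table(SIM$table, samples = 1:8))
  d <- distance_matrix(clr, "euclidean")
  ours <- pcoa(d)
  ref <- ape::pcoa(as.dist(d))
  k <- min(ncol(ours$coordinates), ncol(ref$vectors))
  expect_equal(abs(unname(ours$coordinates[, 1:k])),
               abs(unname(ref$vectors[, 1:k])), tolerance = 1e-6)
})

test_that("two-group alpha comparisons use exact rank-sum enumeration", {
  alpha <- data.frame(sample_id = sprintf("s%d", 1:6),
                      richness = c(1, 2, 3, 4, 5, 6),
                      stringsAsFactors = FALSE)
  grp <- rep(c("A", "B"), each = 3)
  res <- compare_alpha(alpha, grp)
  # exhaustive enumeration over C(6,3) = 20 rank splits: the observed
  # split is one of the two most extreme -> two-sided p = 2/20
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # invariant to monotone transformations
  alpha2 <- alpha; alpha2$richness <- alpha$richness^3
  expect_equal(compare_alpha(alpha2, grp)$p_value, res$p_value)

  # identical groups -> p = 1
  alpha3 <- data.frame(sample_id = sprintf("s%d", 1:6),
                       richness = rep(c(1, 2, 3), 2))
  expect_equal(compare_alpha(alpha3, grp)$p_value, 1)

  expect_error(compare_alpha(alpha, c("A", "A", "B", "B", "C", "C")),
               "two groups")
  expect_error(compare_alpha(alpha, c("A", rep("B", 5))),
               "at least 2")
})
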