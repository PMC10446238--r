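# Z-score normalisation, cluster ordering, ANOVA and Spearman
# correlation against independent oracles.

test_that("row z-scores standardise with the sample sd", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 5, 5))
  expect_warning(z <- row_zscores(m), "constant")
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["b", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["c", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_error(row_zscores(m[, 1, drop = FALSE]), "two columns")
  expect_error(row_zscores(rbind(c(1, NA, NA))), "finite")
})

test_that("non-constant z-score rows have mean 0 and sample sd 1", {
  set.seed(11)
  m <- matrix(rnorm(300), ncol = 3)
  z <- row_zscores(m)
  expect_true(max(abs(rowMeans(z))) < 1e-12)
  expect_true(max(abs(apply(z, 1, sd) - 1)) < 1e-12)
  # population mode differs by the expected factor
  zp <- row_zscores(m, sd_type = "population")
  expect_equal(zp, z * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("cluster order is deterministic and groups identical rows", {
  m <- rbind(a = c(0, 0, 0), b = c(10, 10, 10), c = c(0, 0, 0))
  ord <- cluster_order(m)
  expect_equal(cluster_order(m), ord)
  # the two identical rows must be adjacent leaves
  expect_equal(abs(diff(which(ord %in% c(1, 3)))), 1)
  expect_equal(cluster_order(m[1, , drop = FALSE]), 1L)
})

test_that("cluster order agrees with a naive average-linkage agglomeration", {
  set.seed(23)
  for (rep in 1:5) {
    m <- matrix(rnorm(24), nrow = 8)
    ord <- cluster_order(m)
    oracle <- oracle_average_linkage(m)
    h <- hclust(dist(m), method = "average")
    # same merge heights and same cluster composition at every merge
    expect_equal(sort(oracle$heights), sort(h$height), tolerance = 1e-12)
    hclust_members <- lapply(seq_len(nrow(h$merge)), function(i) {
      leaves <- function(k) {
        if (k < 0) return(-k)
        unlist(lapply(h$merge[k, ], leaves))
      }
      sort(unname(leaves(i)))
    })
    expect_setequal(lapply(oracle$members, paste, collapse = ","),
                    lapply(hclust_members, paste, collapse = ","))
    # the returned leaf order is a traversal of that tree: every
    # cluster occupies a contiguous block of the permutation
    pos <- match(seq_len(nrow(m)), ord)
    for (members in oracle$members) {
      p <- sort(pos[members])
      expect_equal(p, seq(min(p), max(p)))
    }
  }
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  res <- compare_group_fc(groups)
  # hand computation: SSB = 26 (df 2), SSW = 6 (df 6) -> F = 13
  expect_equal(res$F, 13)
  expect_equal(res$p, pf(13, 2, 6, lower.tail = FALSE))
  # independent route through lm()
  d <- data.frame(y = unlist(groups),
                  g = rep(names(groups), lengths(groups)))
  tab <- anova(lm(y ~ g, data = d))
  expect_equal(res$F, tab$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, tab$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ANOVA handles degenerate separation and identity cases", {
  expect_equal(compare_group_fc(list(a = c(1, 1, 1), b = c(1, 1, 1))),
               compare_group_fc(list(a = c(1, 1, 1), b = c(1, 1, 1))))
  id <- compare_group_fc(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(id$F, 0); expect_equal(id$p, 1)
  sep <- compare_group_fc(list(a = c(0, 0, 0), b = c(10, 10, 10)))
  expect_equal(sep$p, 0)
  expect_error(compare_group_fc(list(a = 1:3)), "two groups")
  expect_error(compare_group_fc(list(a = 1, b = 1:3)), "at least two values")
})

test_that("ANOVA p is invariant under shifts and group relabeling", {
  set.seed(31)
  groups <- list(a = rnorm(5), b = rnorm(6, 1), c = rnorm(4, 2))
  p0 <- compare_group_fc(groups)$p
  shifted <- lapply(groups, function(g) g + 100)
  expect_equal(compare_group_fc(shifted)$p, p0, tolerance = 1e-12)
  expect_equal(compare_group_fc(rev(groups))$p, p0, tolerance = 1e-12)
})

test_that("spearman matches the exhaustive rank formula on seeded vectors", {
  set.seed(47)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    x <- runif(n); y <- runif(n)  # ties absent almost surely
    res <- spearman_cor(x, y)
    d <- rank(x) - rank(y)
    rho_formula <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(res$rho, rho_formula, tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("spearman is symmetric, monotone-invariant, and errors on constants", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman_cor(x, y), spearman_cor(y, x))
  expect_equal(spearman_cor(exp(x), y), spearman_cor(x, y))
  expect_equal(spearman_cor(x, y^3), spearman_cor(x, y))
  expect_equal(spearman_cor(sort(x), sort(y))$rho, 1)
  expect_equal(spearman_cor(sort(x), rev(sort(y)))$rho, -1)
  expect_error(spearman_cor(rep(1, 5), y[1:5]), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("exact permutation p agrees with enumeration at small n", {
  set.seed(53)
  x <- runif(6); y <- runif(6)
  res <- spearman_cor(x, y, method = "exact")
  # brute-force reference over all 720 permutations
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  rhos <- apply(perms, 1, function(idx) cor(rank(x), rank(y)[idx]))
  expect_equal(res$p, mean(abs(rhos) >= abs(res$rho) - 1e-12),
               tolerance = 1e-12)
  expect_error(spearman_cor(runif(9), runif(9), method = "exact"),
               "n <= 8")
})
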