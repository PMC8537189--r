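test_that("one-way ANOVA matches the hand-computed decomposition", {
  # equal group means with spread -> F = 0
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(one_way_anova(v, g)$f, 0)
  # {1,2,3} vs {4,5,6}: SSB = 13.5, MSW = 1 -> F = 13.5 on (1, 4) df
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(res$f, 13.5)
  expect_equal(c(res$df_between, res$df_within), c(1, 4))
  # two groups: F equals the pooled-variance t statistic squared
  set.seed(5)
  x <- rnorm(12)
  g2 <- rep(c("a", "b"), each = 6)
  tt <- t.test(x ~ g2, var.equal = TRUE)
  expect_equal(one_way_anova(x, g2)$f, unname(tt$statistic)^2)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")),
               class = "leafdepo_validation_error")
})

test_that("ANOVA F is invariant to shift and scale of the outcome", {
  set.seed(9)
  v <- rnorm(15, 10)
  g <- rep(letters[1:3], each = 5)
  f0 <- one_way_anova(v, g)$f
  expect_equal(one_way_anova(v + 100, g)$f, f0)
  expect_equal(one_way_anova(v * 7.3, g)$f, f0)
})

test_that("Tukey HSD finds no pairs in identical groups and obvious ones apart", {
  set.seed(3)
  base <- rnorm(9)
  g <- rep(letters[1:3], each = 3)
  expect_false(any(tukey_hsd(base - ave(base, g), g)$significant))
  v <- c(rnorm(3, 0, 1), rnorm(3, 100, 1), rnorm(3, 200, 1))
  expect_true(all(tukey_hsd(v, g)$significant))
})

test_that("Tukey significance agrees with a direct studentized-range computation", {
  # independent oracle: studentized range statistic per pair compared with
  # qtukey critical value, from the ANOVA pooled variance
  set.seed(17)
  v <- c(rnorm(4, 0), rnorm(4, 2.5), rnorm(4, 3))
  g <- rep(letters[1:3], each = 4)
  got <- tukey_hsd(v, g, alpha = 0.05)
  means <- tapply(v, g, mean)
  msw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (12 - 3)
  crit <- qtukey(0.95, nmeans = 3, df = 9)
  pairs <- combn(names(means), 2)
  oracle <- apply(pairs, 2, function(p) {
    abs(means[p[2]] - means[p[1]]) / sqrt(msw / 4) > crit
  })
  key <- apply(pairs, 2, function(p) paste(p[2], p[1], sep = "-"))
  expect_equal(got$significant[match(key, got$pair)], unname(oracle))
})

test_that("lowering alpha never adds significant pairs", {
  set.seed(23)
  v <- c(rnorm(4, 0), rnorm(4, 1.5), rnorm(4, 3))
  g <- rep(letters[1:3], each = 4)
  sig10 <- tukey_hsd(v, g, alpha = 0.10)$significant
  sig05 <- tukey_hsd(v, g, alpha = 0.05)$significant
  sig01 <- tukey_hsd(v, g, alpha = 0.01)$significant
  expect_true(all(sig05 <= sig10))
  expect_true(all(sig01 <= sig05))
})

test_that("correlation handles exact linear relationships and degenerate input", {
  x <- 1:10
  expect_equal(correlate(x, -x)$r, -1)
  r2 <- correlate(x, 2 * x)
  expect_equal(r2$r, 1)
  expect_equal(r2$slope, 2)
  expect_error(correlate(x, rep(1, 10)), class = "leafdepo_numeric_error")
  expect_error(correlate(1:2, 2:1), class = "leafdepo_validation_error")
})

test_that("correlation recovers the sign of the generator's SFE-capacity link", {
  cfg <- generator_config(seed = 31)
  ss <- simulate_study(cfg)
  q <- quantify_study(ss$bundle)
  totals <- q$densities |>
    dplyr::group_by(species_id) |>
    dplyr::summarise(total = sum(density_mg_m2))
  tr <- dplyr::left_join(totals, q$sfe, by = "species_id")
  expect_gt(correlate(tr$gamma_total, tr$total)$r, 0)
  expect_lt(correlate(tr$mean_deg_water, tr$total)$r, 0)
})

test_that("k-means clusters separate points and orders labels by magnitude", {
  f <- tibble::tibble(species_id = c("a", "b", "c"),
                      x = c(0, 10, 20), total = c(0, 10, 20))
  cl <- kmeans_capacity_clusters(f, k = 3, seed = 1, n_restarts = 10)
  expect_equal(cl$assignments$cluster[order(f$total)], 1:3)
  # duplicated rows land in the same cluster
  f2 <- tibble::tibble(species_id = sprintf("s%d", 1:6),
                       x = c(0, 0, 10, 10, 20, 20),
                       total = c(0, 0, 10, 10, 20, 20))
  cl2 <- kmeans_capacity_clusters(f2, k = 3, seed = 1, n_restarts = 10)
  lab <- cl2$assignments$cluster
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_equal(lab[5], lab[6])
  expect_error(kmeans_capacity_clusters(f[1:2, ], k = 3),
               class = "leafdepo_validation_error")
})

test_that("k-means relabelling is deterministic for a fixed seed", {
  set.seed(77)
  f <- tibble::tibble(species_id = sprintf("s%02d", 1:12),
                      x = rnorm(12), y = rnorm(12), total = rnorm(12, 10))
  a <- kmeans_capacity_clusters(f, seed = 4, n_restarts = 20)
  b <- kmeans_capacity_clusters(f, seed = 4, n_restarts = 20)
  expect_identical(a$assignments, b$assignments)
})
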