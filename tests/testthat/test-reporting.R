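makeRecords <- function() {
  data.frame(animal_id = rep(c("m1", "m2", "m3", "m4", "m5", "m6"), each = 3),
             bronchiole_id = rep(1:3, 6),
             thickness_mean_um = c(2, 4, 6,   5, 5, 5,   4, 6, 8,
                                   9, 10, 11, 12, 12, 12, 10, 11, 12))
}

makeGroups <- function() {
  data.frame(animal_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
             group = rep(c("air", "ozone"), each = 3))
}

test_that("aggregation averages objects within animal before testing", {
  tb <- aggregateByAnimal(makeRecords(), makeGroups())
  expect_equal(tb$value[tb$animal_id == "m1"], 4)  # mean of 2, 4, 6
  expect_equal(tb$value[tb$animal_id == "m5"], 12)
  # invariant to row order
  rec <- makeRecords()
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(aggregateByAnimal(shuffled, makeGroups()), tb)
  # missing labels are an error; object level keeps every record
  expect_error(aggregateByAnimal(rec, makeGroups()[-1, ]), "missing group")
  expect_equal(nrow(aggregateByAnimal(rec, makeGroups(), level = "object")),
               nrow(rec))
})

test_that("group summaries report mean and SEM per group", {
  tb <- data.frame(group = "g", animal_id = c("a", "b", "c"),
                   metric = "m", value = c(1, 2, 3))
  gs <- groupSummary(tb, "m")
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(gs$sem, 0.577, tolerance = 1e-3)
})

test_that("one-way ANOVA and Bonferroni pairs match hand-computed oracles", {
  v <- c(6.2, 5.8, 6.6, 6.4,  7.3, 7.9, 7.1, 7.7,  9.1, 8.5, 8.8, 9.4)
  tb <- data.frame(group = rep(c("air", "acute", "chronic"), each = 4),
                   animal_id = paste0("m", 1:12), metric = "t", value = v)
  res <- compareGroups(tb, "t", "anova_bonferroni")
  # oracle: F from explicit sums of squares
  gm <- tapply(v, tb$group, mean)
  ssb <- sum(4 * (gm - mean(v))^2)
  ssw <- sum((v - gm[tb$group])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(unname(res$overall["statistic"]), f_oracle, tolerance = 1e-10)
  expect_equal(unname(res$overall["p"]), pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
  # oracle: pooled-SD t per pair, Bonferroni = min(1, 3 * p_raw)
  msw <- ssw / 9
  for (k in seq_len(nrow(res$pairwise))) {
    g1 <- res$pairwise$group1[k]; g2 <- res$pairwise$group2[k]
    tstat <- (gm[g1] - gm[g2]) / sqrt(msw * (1 / 4 + 1 / 4))
    p_raw <- 2 * pt(abs(tstat), df = 9, lower.tail = FALSE)
    expect_equal(res$pairwise$p_adj[k], min(1, 3 * p_raw), tolerance = 1e-10)
  }
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
})

test_that("Bonferroni adjustment multiplies by the comparison count and caps at 1", {
  # a pair with raw p near 0.02 under 3 comparisons adjusts to near 0.06: ns
  set.seed(5)
  v <- c(10.0, 10.4, 9.8, 10.2, 10.9, 11.2, 10.6, 11.0, 10.4, 10.8, 10.5, 10.9)
  tb <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                   animal_id = paste0("m", 1:12), metric = "x", value = v)
  res <- compareGroups(tb, "x")
  gm <- tapply(v, tb$group, mean)
  ssw <- sum((v - gm[tb$group])^2)
  for (k in seq_len(nrow(res$pairwise))) {
    tstat <- (gm[res$pairwise$group1[k]] - gm[res$pairwise$group2[k]]) /
      sqrt(ssw / 9 / 2)
    p_raw <- 2 * pt(abs(tstat), 9, lower.tail = FALSE)
    expect_equal(res$pairwise$p_adj[k], min(1, 3 * p_raw), tolerance = 1e-9)
  }
})

test_that("identical constant groups are reported non-significant with a warning", {
  tb <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                   animal_id = paste0("m", 1:9), metric = "x", value = 5)
  expect_warning(res <- compareGroups(tb, "x"), "F undefined")
  expect_true(all(res$pairwise$stars == "ns"))
  expect_equal(unname(res$overall["p"]), 1)
})

test_that("the Kruskal-Wallis route matches the rank-statistic formula", {
  v <- c(1.1, 2.3, 3.1, 4.7,  5.2, 6.8, 7.4, 8.1,  9.9, 11.3, 12.8, 14.1)
  tb <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                   animal_id = paste0("m", 1:12), metric = "x", value = v)
  res <- compareGroups(tb, "x", "kruskal_wallis")
  # oracle: H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1), no ties
  rk <- rank(v); N <- 12
  H <- 12 / (N * (N + 1)) * sum(tapply(rk, tb$group, sum)^2 / 4) - 3 * (N + 1)
  expect_equal(unname(res$overall["statistic"]), H, tolerance = 1e-10)
  expect_equal(res$test, "kruskal_wallis")
})

test_that("relabeling groups permutes but does not change pairwise results", {
  v <- c(6.2, 5.8, 6.6, 6.4, 7.3, 7.9, 7.1, 7.7, 9.1, 8.5, 8.8, 9.4)
  tb <- data.frame(group = rep(c("air", "acute", "chronic"), each = 4),
                   animal_id = paste0("m", 1:12), metric = "t", value = v)
  swap <- c(air = "zz_air", acute = "acute", chronic = "chronic")
  tb2 <- transform(tb, group = unname(swap[group]))
  r1 <- compareGroups(tb, "t")
  r2 <- compareGroups(tb2, "t")
  key1 <- with(r1$pairwise, paste(pmin(group1, group2), pmax(group1, group2)))
  key1 <- sub("air", "zz_air", key1, fixed = TRUE)
  key2 <- with(r2$pairwise, paste(sub("zz_zz_", "zz_", pmin(group1, group2)),
                                  pmax(group1, group2)))
  expect_setequal(round(r1$pairwise$p_adj, 12), round(r2$pairwise$p_adj, 12))
})

test_that("significance stars follow the four reporting thresholds", {
  expect_equal(significanceStars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significanceStars(0.05), "ns")    # strictly below 0.05
  expect_equal(significanceStars(1e-4), "***")   # strictly below 1e-4 for ****
})

test_that("a built-in group effect is recovered with the correct direction", {
  # cohort of single-bronchiole phantoms: ozone thins the epithelium
  walls <- list(air = c(20, 21, 19.5, 20.5), ozone = c(14, 15, 13.5, 14.5))
  rows <- list()
  for (g in names(walls)) for (i in seq_along(walls[[g]])) {
    sp <- phantomSpec(c(420, 420), 1, "HE",
      bronchioles = list(phantomBronchiole(c(160, 160), 65, walls[[g]][i])),
      seed = 100L + i)
    panel <- measureBronchioles(
      detectLumina(segmentTissue(generatePhantom(sp)$image)))
    rows[[paste(g, i)]] <- data.frame(animal_id = paste0(g, i),
                                      thickness_mean_um = panel$thickness_mean_um)
  }
  rec <- do.call(rbind, rows)
  groups <- data.frame(animal_id = rec$animal_id,
                       group = sub("[0-9]+$", "", rec$animal_id))
  tb <- aggregateByAnimal(rec, groups)
  res <- compareGroups(tb, "thickness_mean_um")
  expect_lt(res$pairwise$p_adj[1], 0.05)
  ms <- res$groups
  expect_gt(ms$mean[ms$group == "air"], ms$mean[ms$group == "ozone"])
  expect_equal(ms$mean[ms$group == "air"], mean(walls$air), tolerance = 0.01)
})
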