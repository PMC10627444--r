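test_that("decile breaks follow the linear-interpolation convention", {
  expect_equal(decile_breaks(1:10),
               c(1.9, 2.8, 3.7, 4.6, 5.5, 6.4, 7.3, 8.2, 9.1))
  expect_equal(decile_breaks(rep(7, 5)), rep(7, 9))
  b <- decile_breaks(c(0, 100))
  expect_true(all(b > 0 & b < 100))
  expect_equal(b + rev(b), rep(100, 9))   # symmetric about 50
  expect_error(decile_breaks(c(NA, NA)), "no finite values")
  # matches the hand-rolled oracle on random draws
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(sample(2:40, 1))
    expect_equal(decile_breaks(v), oracle_breaks(v))
  }
})

test_that("rank_value applies the lower-bin tie rule", {
  br <- decile_breaks(1:10)
  expect_equal(rank_value(0, br), 1L)
  expect_equal(rank_value(99, br), 10L)
  expect_equal(rank_value(1.9, br), 1L)      # tie falls in the lower bin
  expect_equal(rank_value(1.9 + 1e-9, br), 2L)
  # degenerate breaks: all equal c
  bc <- rep(5, 9)
  expect_equal(rank_value(5, bc), 1L)
  expect_equal(rank_value(5 + 1e-12, bc), 10L)
  expect_true(is.na(rank_value(NA, br)))
})

test_that("metric scoring: signs, extremes, permutations of 1..10", {
  tab <- random_metric_table(10, seed = 1)
  dirs <- metric_directions()
  sc <- score_metrics(tab, dirs)
  for (m in metric_columns()$all) {
    r <- sc[[paste0("metric_rank_", m)]]
    expect_setequal(r, 1:10)   # distinct values -> a permutation of 1..10
    s <- sc[[paste0("metric_score_", m)]]
    expect_equal(s, dirs$sign[[m]] * r)
    # unit at the extreme of the column
    i_max <- which.max(tab[[m]])
    expect_equal(r[i_max], 10L)
    expect_equal(s[i_max], if (dirs$sign[[m]] < 0) -10 else 10)
    expect_equal(r[which.min(tab[[m]])], 1L)
  }
  expect_error(score_metrics(tab[1, , drop = FALSE]), "cohort")
})

test_that("category sums apply the stated weights", {
  # adaptive: 1.5*(-4) + 5 + 2*6 + 7 = 18
  sc <- data.frame(unit_id = "U1",
                   metric_score_pct_hardened = -4,
                   metric_score_shoreline_complexity = 5,
                   metric_score_migration_ratio = 6,
                   metric_score_connectedness = 7)
  expect_equal(category_sum(sc, category = "adaptive"), 18)
  # condition unweighted: 3 - 2 - 1 + 4 - 5 = -1
  sc2 <- data.frame(unit_id = "U1",
                    metric_score_area_to_edge_ratio = 3,
                    metric_score_unveg_edge_ratio = -2,
                    metric_score_pct_impervious = -1,
                    metric_score_pct_natural = 4,
                    metric_score_pct_agricultural = -5)
  expect_equal(category_sum(sc2, category = "condition"), -1)
  # vulnerability: -8 + 2 - 9 - 7 = -22
  sc3 <- data.frame(unit_id = "U1",
                    metric_score_soil_erodibility = -8,
                    metric_score_tidal_range_m = 2,
                    metric_score_pct_below_mhhw = -9,
                    metric_score_pct_below_mtl = -7)
  expect_equal(category_sum(sc3, category = "vulnerability"), -22)
})

test_that("vulnerability orientation: worst unit scores -10, best -1", {
  tab <- random_metric_table(25, seed = 3)
  st <- score_table(tab)
  worst <- which.min(st$sum_vulnerability)   # least favourable sum
  best <- which.max(st$sum_vulnerability)
  expect_equal(st$score_vulnerability[worst], -10L)
  expect_equal(st$score_vulnerability[best], -1L)
  expect_true(all(st$score_vulnerability %in% -(1:10)))
  expect_true(all(st$score_condition %in% 1:10))
  expect_true(all(st$score_adaptive %in% 1:10))
})

test_that("two-unit cohort gets category scores {1, 10}", {
  tab <- random_metric_table(2, seed = 4)
  st <- score_table(tab)
  expect_setequal(st$score_adaptive, c(1L, 10L))
  expect_setequal(st$score_condition, c(1L, 10L))
  expect_setequal(abs(st$score_vulnerability), c(1L, 10L))
})

test_that("total score: bounds and arithmetic", {
  tab <- random_metric_table(40, seed = 5)
  st <- score_table(tab)
  expect_equal(st$total_sum,
               st$score_condition + st$score_vulnerability + st$score_adaptive)
  expect_true(all(st$total_sum >= -8 & st$total_sum <= 19))
  expect_true(all(st$total_score %in% 1:10))
  mc <- metric_columns()
  w <- metric_directions()$weight
  for (cat in c("condition", "vulnerability", "adaptive")) {
    wsum <- sum(10 * w[mc[[cat]]])
    expect_true(all(abs(st[[paste0("sum_", cat)]]) <= wsum))
  }
})

test_that("full pipeline matches the brute-force oracle on random cohorts", {
  for (seed in 1:25) {
    n <- sample(2:50, 1)
    tab <- random_metric_table(n, seed = 1000 + seed)
    st <- score_table(tab)
    or <- oracle_score(tab)
    for (m in metric_columns()$all) {
      expect_equal(st[[paste0("metric_score_", m)]],
                   unname(or$metric_scores[, m]), label = m)
    }
    expect_equal(st$sum_condition, or$sums$condition)
    expect_equal(st$sum_vulnerability, or$sums$vulnerability)
    expect_equal(st$sum_adaptive, or$sums$adaptive)
    expect_equal(as.numeric(st$score_condition), or$cat_score$condition)
    expect_equal(as.numeric(st$score_vulnerability), or$cat_score$vulnerability)
    expect_equal(as.numeric(st$score_adaptive), or$cat_score$adaptive)
    expect_equal(as.numeric(st$total_score), or$total_score)
    expect_equal(st$management_key, or$key)
  }
})

test_that("ranks are invariant under strictly increasing transforms", {
  for (i in 1:20) {
    tab <- random_metric_table(sample(5:40, 1), seed = 2000 + i)
    st <- score_table(tab)
    m <- sample(metric_columns()$all, 1)
    f <- sample(list(function(x) exp(x), function(x) x^3 + 2 * x,
                     function(x) 5 * x + 1, function(x) atan(x)), 1)[[1]]
    tab2 <- tab
    tab2[[m]] <- f(tab2[[m]])
    st2 <- score_table(tab2)
    expect_equal(st2[[paste0("metric_rank_", m)]],
                 st[[paste0("metric_rank_", m)]], label = paste(i, m))
  }
})

test_that("scores are invariant under unit-order permutation", {
  tab <- random_metric_table(20, seed = 11)
  st <- score_table(tab)
  perm <- sample(20)
  st2 <- score_table(tab[perm, , drop = FALSE])
  reord <- st2[match(st$unit_id, st2$unit_id), ]
  expect_equal(reord$total_score, st$total_score)
  expect_equal(reord$score_vulnerability, st$score_vulnerability)
  expect_equal(reord$management_key, st$management_key)
})

test_that("dominance: a uniformly better unit never sums lower", {
  dirs <- metric_directions()
  set.seed(12)
  for (i in 1:10) {
    tab <- random_metric_table(15, seed = 3000 + i)
    # make unit 1 weakly better than unit 2 on every signed metric
    for (m in metric_columns()$all) {
      vals <- tab[[m]][c(1, 2)]
      better <- if (dirs$sign[[m]] > 0) max(vals) else min(vals)
      worse <- if (dirs$sign[[m]] > 0) min(vals) else max(vals)
      tab[[m]][1] <- better
      tab[[m]][2] <- worse
    }
    st <- score_table(tab)
    expect_gte(st$sum_condition[1], st$sum_condition[2])
    expect_gte(st$sum_vulnerability[1], st$sum_vulnerability[2])
    expect_gte(st$sum_adaptive[1], st$sum_adaptive[2])
    expect_gte(st$total_sum[1], st$total_sum[2])
  }
})

test_that("missing metrics propagate without defaulting to a mid rank", {
  tab <- random_metric_table(10, seed = 13)
  tab$pct_hardened[3] <- NA
  st <- score_table(tab)
  expect_true(is.na(st$metric_score_pct_hardened[3]))
  expect_true(is.na(st$sum_adaptive[3]))
  expect_true(is.na(st$score_adaptive[3]))
  expect_true(is.na(st$total_score[3]))
  expect_true(is.na(st$management_key[3]))
  # others unaffected in count
  expect_false(any(is.na(st$score_adaptive[-3])))
})
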