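test_that("group_summary computes per-cell mean and SE", {
  df <- data.frame(
    animal_id = c("a", "b", "c"),
    age_group = "young", temperature = "20C",
    state = c("basal", "basal", "intrinsic"),
    mean_hr_bpm = c(10, 14, 20),
    stringsAsFactors = FALSE
  )
  out <- suppressWarnings(group_summary(df, "mean_hr_bpm"))
  bas <- out[out$state == "basal", ]
  expect_equal(bas$mean, 12)
  expect_equal(bas$se, 2)
  expect_equal(bas$n, 2)
  # single-record cell: warning, no SE
  expect_warning(group_summary(df, "mean_hr_bpm"),
                 class = "single_record_warning")
  expect_true(is.na(out$se[out$state == "intrinsic"]))
  expect_error(group_summary(df, "nope"), class = "configuration_error")
})

test_that("paired_delta pairs animals and applies the sign convention", {
  df <- data.frame(
    animal_id = rep(c("A", "B", "C"), each = 2),
    age_group = "young", temperature = "20C",
    state = rep(c("basal", "intrinsic"), 3),
    mean_hr_bpm = c(600, 500, 620, 540, 580, NA),
    stringsAsFactors = FALSE
  )
  out <- paired_delta(df, "mean_hr_bpm", "20C")
  expect_equal(out$n_pairs, 2) # C lacks intrinsic
  expect_equal(out$mean, 90)
  expect_equal(out$se, 10)
  expect_equal(sort(out$deltas[[1]]), c(80, 100))

  # basal below intrinsic (the thermoneutral case) gives a negative delta
  df2 <- df
  df2$mean_hr_bpm <- c(371, 443, 360, 450, 380, 440)
  out2 <- paired_delta(df2, "mean_hr_bpm", "20C")
  expect_lt(out2$mean, 0)

  expect_error(paired_delta(df[df$state == "basal", ], "mean_hr_bpm", "20C"),
               class = "empty_delta_error")
})

test_that("delta equals difference of cell means for complete pairs", {
  set.seed(81)
  df <- data.frame(
    animal_id = rep(sprintf("m%d", 1:6), each = 2),
    age_group = "old", temperature = "30C",
    state = rep(c("basal", "intrinsic"), 6),
    sdnn_ms = runif(12, 1, 12),
    stringsAsFactors = FALSE
  )
  out <- paired_delta(df, "sdnn_ms", "30C")
  gs <- group_summary(df, "sdnn_ms")
  expect_equal(out$mean,
               gs$mean[gs$state == "basal"] - gs$mean[gs$state == "intrinsic"],
               tolerance = 1e-12)
})

test_that("NN-SDNN power law recovers exact log-linear relations", {
  nn <- seq(100, 200, by = 10)
  fit <- nn_sdnn_powerlaw(nn, 0.001 * nn^2)
  expect_equal(fit$slope, 2, tolerance = 1e-9)

  two <- nn_sdnn_powerlaw(c(100, 200, 100), c(2, 8, 2))
  expect_equal(two$slope, log(4) / log(2), tolerance = 1e-9)

  expect_warning(
    dropped <- nn_sdnn_powerlaw(c(nn, 150), c(0.001 * nn^2, 0)),
    class = "dropped_points_warning"
  )
  expect_equal(dropped$slope, 2, tolerance = 1e-9)
  expect_error(suppressWarnings(nn_sdnn_powerlaw(c(1, 2), c(1, 1))),
               class = "insufficient_data_error")
})

test_that("singular mixed model falls back to a plain t-test", {
  y1 <- c(600, 610, 590, 605, 598)
  y2 <- c(540, 560, 555, 548, 552)
  df <- two_cell_metrics(y1, y2)
  res <- suppressWarnings(lmm_contrasts(df, "mean_hr_bpm"))
  expect_equal(res$method, "fixed")
  tt <- t.test(y1, y2, var.equal = TRUE)
  expect_equal(res$contrasts$p[1], tt$p.value, tolerance = 1e-6)
  expect_equal(res$contrasts$estimate[1], mean(y1) - mean(y2),
               tolerance = 1e-9)
})

test_that("identical responses give null effects with p = 1", {
  df <- two_cell_metrics(rep(5, 4), rep(5, 4))
  res <- lmm_contrasts(df, "mean_hr_bpm")
  expect_true(all(res$contrasts$estimate == 0))
  expect_true(all(res$contrasts$p == 1))
})

test_that("mixed model uses repeated measures and Bonferroni dominates raw p", {
  set.seed(83)
  n <- 8
  animal_effect <- rnorm(2 * n, sd = 20)
  df <- expand.grid(
    animal = seq_len(2 * n), state = c("basal", "intrinsic"),
    stringsAsFactors = FALSE
  )
  df <- data.frame(
    animal_id = sprintf("m%d", df$animal),
    age_group = ifelse(df$animal <= n, "young", "old"),
    temperature = "30C",
    state = df$state,
    mean_hr_bpm = ifelse(df$animal <= n, 371, 307) +
      ifelse(df$state == "intrinsic", 100, 0) +
      animal_effect[df$animal] + rnorm(nrow(df), sd = 5),
    stringsAsFactors = FALSE
  )
  res <- lmm_contrasts(df, "mean_hr_bpm")
  expect_equal(res$method, "lmm")
  expect_true(all(res$contrasts$p_bonf >= res$contrasts$p))
  expect_true(all(res$contrasts$p_bonf <= 1))
  age_row <- grep("young vs old", res$contrasts$comparison)
  expect_true(any(res$contrasts$significant[age_row]))
})
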