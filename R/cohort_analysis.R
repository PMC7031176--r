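#' Per-cell group summaries (mean and standard error)
#'
#' Summarises one metric over the cells of the age x temperature x state
#' design, reporting mean, standard error (sample SD / sqrt(n)) and n per
#' cell, as in the published group tables.
#'
#' @param metrics Per-recording metric table ([hrv_table()] output, or any
#'   data frame with `age_group`, `temperature`, `state` and the metric
#'   column).
#' @param metric Name of the metric column.
#' @return Data frame with one row per non-empty cell: `age_group`,
#'   `temperature`, `state`, `mean`, `se`, `n`. Cells with a single record
#'   get `se = NA` with a warning.
#' @export
group_summary <- function(metrics, metric) {
  if (!metric %in% names(metrics)) {
    mhrv_error("configuration_error",
               sprintf("metric %s not found in table", sQuote(metric)))
  }
  df <- metrics[!is.na(metrics[[metric]]), ]
  if (nrow(df) == 0) {
    mhrv_error("empty_input_error", "no usable records for this metric")
  }
  key <- interaction(df$age_group, df$temperature, df$state, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    rows <- df[key == lv, ]
    y <- rows[[metric]]
    data.frame(
      age_group = rows$age_group[1],
      temperature = rows$temperature[1],
      state = rows$state[1],
      mean = mean(y),
      se = if (length(y) > 1) stats::sd(y) / sqrt(length(y)) else NA_real_,
      n = length(y),
      stringsAsFactors = FALSE
    )
  }))
  if (any(out$n == 1)) {
    mhrv_warn("single_record_warning",
              "cell(s) with a single record: no standard error available")
  }
  rownames(out) <- NULL
  out
}

#' Paired basal-minus-intrinsic deltas
#'
#' For one metric at one temperature, computes the per-animal difference
#' basal - intrinsic (the net autonomic contribution removed by double
#' autonomic blockade) and summarises it per age group. Animals lacking
#' either state at that temperature are excluded. Note the sign convention:
#' when blockade *raises* the metric (e.g. heart rate at thermoneutrality),
#' the delta is negative.
#'
#' @param metrics Per-recording metric table (see [group_summary()]).
#' @param metric Metric column name.
#' @param temperature `"20C"` or `"30C"`.
#' @return Data frame per age group: `metric`, `temperature`, `age_group`,
#'   `mean`, `se`, `n_pairs`, plus a list-column `deltas` of the per-animal
#'   values.
#' @export
paired_delta <- function(metrics, metric, temperature) {
  df <- metrics[metrics$temperature == temperature &
                  !is.na(metrics[[metric]]), ]
  out <- NULL
  for (ag in unique(df$age_group)) {
    sub <- df[df$age_group == ag, ]
    bas <- sub[sub$state == "basal", ]
    intr <- sub[sub$state == "intrinsic", ]
    animals <- intersect(bas$animal_id, intr$animal_id)
    if (length(animals) == 0) next
    d <- unname(vapply(animals, function(a) {
      bas[[metric]][bas$animal_id == a][1] -
        intr[[metric]][intr$animal_id == a][1]
    }, numeric(1)))
    row <- data.frame(
      metric = metric,
      temperature = temperature,
      age_group = ag,
      mean = mean(d),
      se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
      n_pairs = length(d),
      stringsAsFactors = FALSE
    )
    row$deltas <- list(d)
    out <- rbind(out, row)
  }
  if (is.null(out)) {
    mhrv_error("empty_delta_error",
               sprintf("no complete basal/intrinsic pairs at %s", temperature))
  }
  rownames(out) <- NULL
  out
}

#' Mean NN versus SDNN power law
#'
#' Fits the power law SDNN ~ mean NN^slope by ordinary least squares on the
#' ln-ln scale. Across conditions, SDNN falls as the mean NN interval
#' shortens, so the slope is positive.
#'
#' @param mean_nn Numeric vector of per-recording mean NN (ms), or a data
#'   frame holding columns `mean_nn_ms` and `sdnn_ms`.
#' @param sdnn Numeric vector of per-recording SDNN (ms); ignored when
#'   `mean_nn` is a data frame.
#' @return List with `slope`, `intercept`, `points` (data frame of
#'   `ln_nn`, `ln_sdnn`), and `residuals`. Points with `sdnn <= 0` are
#'   dropped with a warning.
#' @export
nn_sdnn_powerlaw <- function(mean_nn, sdnn = NULL) {
  if (is.data.frame(mean_nn)) {
    sdnn <- mean_nn$sdnn_ms
    mean_nn <- mean_nn$mean_nn_ms
  }
  keep <- is.finite(mean_nn) & is.finite(sdnn) & sdnn > 0 & mean_nn > 0
  if (any(!keep)) {
    mhrv_warn("dropped_points_warning",
              sprintf("%d point(s) with non-positive SDNN/NN dropped",
                      sum(!keep)))
  }
  if (sum(keep) < 3) {
    mhrv_error("insufficient_data_error",
               "need at least 3 points with positive SDNN for the power law")
  }
  lx <- log(mean_nn[keep])
  ly <- log(sdnn[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    points = data.frame(ln_nn = lx, ln_sdnn = ly),
    residuals = unname(fit$residuals)
  )
}

# the reported contrast family: within-design pairwise comparisons along
# each factor (state within age x temperature, temperature within age x
# state, age within temperature x state)
.contrast_family <- function(cells) {
  out <- list()
  add <- function(a, b, label) {
    if (a %in% cells && b %in% cells) {
      out[[length(out) + 1]] <<- list(a = a, b = b, label = label)
    }
  }
  ages <- c("young", "old")
  temps <- c("20C", "30C")
  states <- c("basal", "intrinsic")
  cell <- function(a, t, s) paste(a, t, s, sep = ".")
  for (a in ages) for (t in temps) {
    add(cell(a, t, "basal"), cell(a, t, "intrinsic"),
        sprintf("%s/%s: basal vs intrinsic", a, t))
  }
  for (a in ages) for (s in states) {
    add(cell(a, "20C", s), cell(a, "30C", s),
        sprintf("%s/%s: 20C vs 30C", a, s))
  }
  for (t in temps) for (s in states) {
    add(cell("young", t, s), cell("old", t, s),
        sprintf("%s/%s: young vs old", t, s))
  }
  out
}

#' Mixed-model cell contrasts with Bonferroni correction
#'
#' Fits the cell-means form of `metric ~ age * temperature * state` with a
#' random intercept per animal (REML, via `lme4`), then tests the reported
#' family of pairwise cell contrasts: basal vs intrinsic within each
#' age x temperature, 20C vs 30C within each age x state, and young vs old
#' within each temperature x state (up to 12 comparisons; only contrasts
#' between populated cells are computed, and the Bonferroni multiplier is
#' the number actually computed). When the random-effect variance is
#' singular -- e.g. one record per animal -- the model falls back to a
#' fixed-effects fit with a warning, in which case contrast p-values reduce
#' to pooled-variance t-tests. For the mixed fit, degrees of freedom are
#' taken conservatively as (number of animals - 2).
#'
#' @param metrics Per-recording metric table with `animal_id`, `age_group`,
#'   `temperature`, `state` and the metric column.
#' @param metric Metric column name.
#' @return List with `fit` (the model object), `method` (`"lmm"` or
#'   `"fixed"`), and `contrasts`: data frame with `comparison`, `estimate`,
#'   `se`, `t`, `df`, `p`, `p_bonf`, `significant` (p_bonf < 0.05).
#' @export
lmm_contrasts <- function(metrics, metric) {
  df <- metrics[!is.na(metrics[[metric]]), ]
  if (length(unique(df$animal_id[df$age_group == "young"])) < 2 ||
      length(unique(df$animal_id[df$age_group == "old"])) < 2) {
    if (length(unique(df$age_group)) > 1) {
      mhrv_error("insufficient_data_error",
                 "need at least 2 animals per age group")
    }
  }
  y <- df[[metric]]
  df$cell <- factor(paste(df$age_group, df$temperature, df$state, sep = "."))
  cells <- levels(df$cell)
  fam <- .contrast_family(cells)

  if (stats::var(y) == 0) {
    cons <- do.call(rbind, lapply(fam, function(cc) {
      data.frame(comparison = cc$label, estimate = 0, se = 0, t = 0,
                 df = NA_real_, p = 1, p_bonf = 1, significant = FALSE,
                 stringsAsFactors = FALSE)
    }))
    return(list(fit = NULL, method = "degenerate", contrasts = cons))
  }

  method <- "lmm"
  fit <- tryCatch({
    m <- suppressMessages(lme4::lmer(
      y ~ 0 + cell + (1 | animal_id), data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    ))
    if (lme4::isSingular(m, tol = 1e-5)) NULL else m
  }, error = function(e) NULL)
  if (is.null(fit)) {
    mhrv_warn("singular_fit_warning",
              "random-effect variance singular; using fixed-effects model")
    method <- "fixed"
    fit <- stats::lm(y ~ 0 + cell, data = df)
  }

  beta <- if (method == "lmm") lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  names(beta) <- sub("^cell", "", names(beta))
  colnames(V) <- rownames(V) <- names(beta)
  dof <- if (method == "lmm") {
    max(length(unique(df$animal_id)) - 2, 1)
  } else {
    fit$df.residual
  }
  m_comp <- length(fam)
  cons <- do.call(rbind, lapply(fam, function(cc) {
    est <- beta[[cc$a]] - beta[[cc$b]]
    se <- sqrt(V[cc$a, cc$a] + V[cc$b, cc$b] - 2 * V[cc$a, cc$b])
    tt <- est / se
    p <- 2 * stats::pt(-abs(tt), dof)
    data.frame(comparison = cc$label, estimate = est, se = se, t = tt,
               df = dof, p = p, p_bonf = min(1, p * m_comp),
               significant = min(1, p * m_comp) < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(cons) <- NULL
  list(fit = fit, method = method, contrasts = cons)
}
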