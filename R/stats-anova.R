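#' Two-factor repeated-measures ANOVA (waveform x direction)
#'
#' Balanced within-subject decomposition for the 2 (pulse waveform) x 3
#' (current direction) design, computed from sums of squares with each
#' effect tested against its own subject-interaction error term. Sphericity
#' is assessed with Mauchly's test for the direction and interaction effects
#' (the two-level waveform factor is exempt); when Mauchly's p < .05 the
#' Greenhouse-Geisser correction is applied to that effect's degrees of
#' freedom. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long tibble with columns `subject_id`, `waveform`,
#'   `direction` and the response; complete cases only (every subject in all
#'   six cells), n >= 5 subjects.
#' @param value Name of the response column (default `"value"`).
#' @return A `tep_rm_anova`: tibble with one row per effect (`waveform`,
#'   `direction`, `interaction`): `df1`, `df2`, `ss`, `ss_error`, `F`, `p`,
#'   `pes`, `mauchly_w`, `mauchly_p`, `gg_eps`, `df1_gg`, `df2_gg`, `p_gg`,
#'   `sphericity_assumed`, `p_reported` (GG-corrected where triggered).
#' @export
rm_anova_2x3 <- function(data, value = "value") {
  Y <- cell_matrix(data, value)
  n <- nrow(Y)
  if (n < 5) abort("rmANOVA needs >= 5 complete subjects")
  grand <- mean(Y)
  # cell order: (w1 d1, w1 d2, w1 d3, w2 d1, w2 d2, w2 d3)
  Mw <- cbind(rowMeans(Y[, 1:3]), rowMeans(Y[, 4:6]))      # subject x waveform
  Md <- cbind(rowMeans(Y[, c(1, 4)]), rowMeans(Y[, c(2, 5)]),
              rowMeans(Y[, c(3, 6)]))                       # subject x direction
  w_m <- colMeans(Mw); d_m <- colMeans(Md)
  cell_m <- matrix(colMeans(Y), 2, 3, byrow = TRUE)
  subj_m <- rowMeans(Y)

  ss_subj <- 6 * sum((subj_m - grand)^2)
  ss_w <- 3 * n * sum((w_m - grand)^2)
  ss_d <- 2 * n * sum((d_m - grand)^2)
  inter <- sweep(sweep(cell_m, 1, w_m), 2, d_m) + grand
  ss_wd <- n * sum(inter^2)
  ss_ws <- 3 * sum(sweep(sweep(Mw, 1, subj_m), 2, w_m - grand)^2)
  ss_ds <- 2 * sum(sweep(sweep(Md, 1, subj_m), 2, d_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_wds <- ss_tot - ss_subj - ss_w - ss_d - ss_wd - ss_ws - ss_ds

  eff <- tibble(
    effect = c("waveform", "direction", "interaction"),
    df1 = c(1, 2, 2), df2 = c(n - 1, 2 * (n - 1), 2 * (n - 1)),
    ss = c(ss_w, ss_d, ss_wd), ss_error = c(ss_ws, ss_ds, ss_wds)
  ) %>%
    mutate(F = (.data$ss / .data$df1) / (.data$ss_error / .data$df2),
           p = pf(.data$F, .data$df1, .data$df2, lower.tail = FALSE),
           pes = .data$ss / (.data$ss + .data$ss_error))

  # sphericity: direction effect from the waveform-averaged direction scores,
  # interaction from the waveform difference of the direction scores
  sph_d <- sphericity_stats(Md)
  sph_i <- sphericity_stats(Y[, 1:3] - Y[, 4:6])
  eff$mauchly_w <- c(NA, sph_d$w, sph_i$w)
  eff$mauchly_p <- c(NA, sph_d$p, sph_i$p)
  eff$gg_eps <- c(NA, sph_d$eps, sph_i$eps)
  eff <- eff %>%
    mutate(sphericity_assumed = is.na(.data$mauchly_p) | .data$mauchly_p >= 0.05,
           df1_gg = .data$df1 * .data$gg_eps, df2_gg = .data$df2 * .data$gg_eps,
           p_gg = pf(.data$F, .data$df1_gg, .data$df2_gg, lower.tail = FALSE),
           p_reported = ifelse(.data$sphericity_assumed, .data$p, .data$p_gg))
  structure(eff, class = c("tep_rm_anova", class(eff)), n = n)
}

# Mauchly W, its chi-square p, and the Greenhouse-Geisser epsilon for the
# covariance of a subject x levels score matrix (levels >= 3).
sphericity_stats <- function(M) {
  J <- ncol(M)
  n <- nrow(M)
  C <- contr_orthonormal(J)
  S <- cov(M %*% C)          # p x p, p = J - 1
  p <- J - 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev^2) == 0) return(list(w = NA_real_, p = NA_real_, eps = 1))
  eps <- sum(ev)^2 / (p * sum(ev^2))
  w <- prod(ev) / (sum(ev) / p)^p
  if (!is.finite(w) || w <= 0) {
    return(list(w = NA_real_, p = NA_real_, eps = max(eps, 1 / p)))
  }
  f <- n - 1
  chi <- -(f - (2 * p^2 + p + 2) / (6 * p)) * log(w)
  df <- p * (p + 1) / 2 - 1
  list(w = w, p = pchisq(chi, df, lower.tail = FALSE), eps = eps)
}

contr_orthonormal <- function(J) {
  C <- stats::contr.helmert(J)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# subject x 6-cell matrix in (waveform, direction) order; errors on
# incomplete designs, naming the subjects
cell_matrix <- function(data, value = "value") {
  need <- c("subject_id", "waveform", "direction", value)
  if (!all(need %in% names(data))) {
    abort(paste0("data needs columns: ", paste(need, collapse = ", ")))
  }
  subs <- unique(data$subject_id)
  Y <- matrix(NA_real_, length(subs), 6,
              dimnames = list(subs, tep_conditions()))
  for (i in seq_len(nrow(data))) {
    cond <- condition_label(data$waveform[i], data$direction[i])
    Y[as.character(data$subject_id[i]), cond] <- data[[value]][i]
  }
  bad <- subs[!complete.cases(Y)]
  if (length(bad)) {
    abort(paste0("incomplete design for subject(s): ", paste(bad, collapse = ", ")))
  }
  Y
}

#' @export
tidy.tep_rm_anova <- function(x, ...) as_tibble(x)

#' @export
glance.tep_rm_anova <- function(x, ...) {
  tibble(n = attr(x, "n"), any_gg = any(!x$sphericity_assumed, na.rm = TRUE))
}

#' Tukey-corrected pairwise post-hoc contrasts
#'
#' All pairwise paired contrasts among the cells of a within-subject effect
#' (the six conditions, the three directions, or the two waveforms, cell
#' scores averaged over the other factor where applicable). Each contrast is
#' a paired t statistic; the adjusted p comes from the studentized-range
#' distribution with as many means as cells; Cohen's d for paired data is
#' the mean difference over the SD of the differences.
#'
#' @inheritParams rm_anova_2x3
#' @param effect `"condition"`, `"direction"`, or `"waveform"`.
#' @return Tibble: `contrast`, `estimate`, `t`, `df`, `p_raw`, `p_tukey`,
#'   `cohens_d`.
#' @export
tukey_posthoc <- function(data, effect = c("condition", "direction", "waveform"),
                          value = "value") {
  effect <- match.arg(effect)
  Y <- cell_matrix(data, value)
  M <- switch(effect,
    condition = Y,
    direction = cbind(PA = rowMeans(Y[, c(1, 4)]), AP = rowMeans(Y[, c(2, 5)]),
                      LM = rowMeans(Y[, c(3, 6)])),
    waveform = cbind(monophasic = rowMeans(Y[, 1:3]),
                     biphasic = rowMeans(Y[, 4:6])))
  k <- ncol(M)
  n <- nrow(M)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- M[, a] - M[, b]
    sdd <- sd(d)
    tt <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(n))
    p_raw <- if (sdd == 0) 1 else 2 * pt(-abs(tt), n - 1)
    p_tuk <- if (sdd == 0) 1 else
      ptukey(sqrt(2) * abs(tt), nmeans = k, df = n - 1, lower.tail = FALSE)
    tibble(contrast = paste(colnames(M)[a], "-", colnames(M)[b]),
           estimate = mean(d), t = tt, df = n - 1,
           p_raw = p_raw, p_tukey = max(p_tuk, p_raw),
           cohens_d = if (sdd == 0) 0 else mean(d) / sdd)
  })
}

#' ANCOVA of direction with a TMS-intensity covariate
#'
#' For one pulse waveform: tests the current-direction effect on a response
#' adjusted for the stimulation-intensity covariate of the corresponding
#' block, via a linear mixed model `value ~ direction + intensity +
#' (1 | subject)` with Satterthwaite degrees of freedom.
#'
#' @param data Long tibble with `subject_id`, `direction`, the response and
#'   the covariate.
#' @param value Response column name.
#' @param covariate Covariate column name (default `"intensity"`).
#' @return Tibble: `term`, `F`, `df1`, `df2`, `p`.
#' @export
ancova_direction <- function(data, value = "value", covariate = "intensity") {
  if (!covariate %in% names(data)) abort(paste0("no covariate column: ", covariate))
  if (sd(data[[covariate]]) == 0) abort("constant covariate")
  d <- data.frame(y = data[[value]], direction = factor(data$direction),
                  x = data[[covariate]], subject = factor(data$subject_id))
  m <- lmerTest::lmer(y ~ direction + x + (1 | subject), data = d, REML = TRUE)
  a <- anova(m)
  tibble(term = c("direction", covariate),
         F = a$`F value`, df1 = a$NumDF, df2 = a$DenDF,
         p = a$`Pr(>F)`)
}
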