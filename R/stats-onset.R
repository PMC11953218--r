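#' Benjamini-Hochberg adjustment over a declared family
#'
#' Step-up false-discovery-rate adjustment. `family_size` may exceed the
#' number of p-values supplied: unsupplied family members are treated as p =
#' 1, which under the step-up rule simply fixes the denominator family size
#' at `family_size`. Adjusted values are monotone in the raw values and
#' capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param family_size Declared family size, `>= length(p)` (default
#'   `length(p)`).
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p, family_size = length(p)) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must be in (0, 1]")
  if (family_size < length(p)) abort("family_size smaller than the number of p-values")
  k <- length(p)
  o <- order(p)
  ranked <- p[o] * family_size / seq_len(k)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Gamma/identity mixed model for microstate onsets
#'
#' Models microstate onset times (strictly positive, ms) with a generalized
#' linear mixed model: gamma family, identity link, fixed effects for
#' microstate class, stimulation condition and their interaction, and a
#' per-subject random intercept. Fixed effects are tested with Wald
#' chi-square statistics (type III, sum-to-zero contrasts). Post-hoc
#' contrasts are the within-condition class pairs only — 15 pairs in each of
#' 6 conditions, a declared 90-contrast family — Benjamini-Hochberg adjusted
#' over that family. Pairs whose significant contrasts change sign between
#' conditions are reported as onset-order swaps. Onsets absent for a
#' subject/condition/class are dropped listwise (counted in the result). If
#' the identity-link fit fails to converge, a log-link refit is attempted
#' and flagged.
#'
#' @param features Long tibble with `subject_id`, `condition`, `class`,
#'   `onset` (ms; `NA` when the class never occurred), e.g. from
#'   [microstate_features()].
#' @param family_size Contrast family size for BH (default 90, i.e. 15 class
#'   pairs x 6 conditions).
#' @param alpha Significance level for the swap report (default .05).
#' @param nagq0 Use the faster `nAGQ = 0` fit (default TRUE).
#' @return An `onset_model`: list with `fixed_tests` (term, chisq, df, p),
#'   `contrasts` (condition, pair, estimate, se, z, p, p_adj), `swaps`,
#'   `n_dropped`, `link`, `converged`, and the fitted `model`.
#' @export
onset_mixed_model <- function(features, family_size = 90, alpha = 0.05,
                              nagq0 = TRUE) {
  d <- features %>%
    filter(is.finite(.data$onset)) %>%
    mutate(class = factor(.data$class), condition = factor(.data$condition),
           subject = factor(.data$subject_id))
  n_dropped <- nrow(features) - nrow(d)
  if (any(d$onset <= 0)) abort("onsets must be strictly positive for the gamma family")
  single_cond <- nlevels(d$condition) < 2
  form <- if (single_cond) onset ~ class + (1 | subject) else
    onset ~ class * condition + (1 | subject)
  ctr <- if (single_cond) list(class = "contr.sum") else
    list(class = "contr.sum", condition = "contr.sum")
  fit_with <- function(link) {
    suppressWarnings(suppressMessages(tryCatch(
      lme4::glmer(form, data = d, family = stats::Gamma(link = link),
                  contrasts = ctr, nAGQ = if (nagq0) 0L else 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)))
  }
  link <- "identity"
  m <- fit_with("identity")
  # a singular random-effect fit (zero subject variance) is legitimate here;
  # only genuine convergence failures are flagged
  msgs <- if (is.null(m)) character(0) else
    m@optinfo$conv$lme4$messages %||% character(0)
  converged <- !is.null(m) && all(grepl("singular", msgs))
  if (is.null(m)) {
    link <- "log"
    m <- fit_with("log")
    converged <- FALSE
    if (is.null(m)) abort("gamma mixed model failed with identity and log links")
  }

  # Wald covariance rescaled to the Pearson dispersion estimate (the
  # standard moment estimator for gamma models, as in summary.glm); the
  # ML/deviance-based estimate makes the chi-square tests conservative
  mu_hat <- stats::fitted(m)
  disp <- sum((d$onset - mu_hat)^2 / mu_hat^2) /
    (nrow(d) - length(lme4::fixef(m)) - 1)
  V <- as.matrix(vcov(m)) * disp / stats::sigma(m)^2

  fixed_tests <- wald_type3(m, V)
  contrasts <- within_condition_contrasts(m, d, V, family_size = family_size)
  swaps <- detect_swaps(contrasts, alpha = alpha)
  structure(list(fixed_tests = fixed_tests, contrasts = contrasts,
                 swaps = swaps, n_dropped = n_dropped, link = link,
                 converged = converged, model = m),
            class = "onset_model")
}

# Wald type-III chi-square per fixed-effect term (sum-to-zero contrasts, so
# term blocks of the coefficient vector are the type-III hypotheses)
wald_type3 <- function(m, V) {
  b <- lme4::fixef(m)
  asg <- attr(stats::model.matrix(m), "assign")
  labs <- attr(stats::terms(m), "term.labels")
  purrr::map_dfr(seq_along(labs), function(i) {
    idx <- which(asg == i)
    bi <- b[idx]
    Vi <- V[idx, idx, drop = FALSE]
    ch <- as.numeric(t(bi) %*% solve(Vi, bi))
    tibble(term = labs[i], chisq = ch, df = length(idx),
           p = pchisq(ch, length(idx), lower.tail = FALSE))
  })
}

within_condition_contrasts <- function(m, d, V, family_size = 90) {
  classes <- levels(d$class)
  conds <- levels(d$condition)
  # design rows for each (class, condition) cell mean on the link scale
  grid <- expand.grid(class = classes, condition = conds,
                      stringsAsFactors = FALSE)
  grid$class <- factor(grid$class, levels = classes)
  grid$condition <- factor(grid$condition, levels = conds)
  form_fixed <- if (length(conds) > 1) ~ class * condition else ~ class
  ctr <- if (length(conds) > 1) list(class = "contr.sum", condition = "contr.sum")
         else list(class = "contr.sum")
  X <- stats::model.matrix(form_fixed, grid, contrasts.arg = ctr)
  b <- lme4::fixef(m)
  rows <- list()
  for (cd in conds) {
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (i >= j) next
      ra <- X[grid$class == classes[i] & grid$condition == cd, , drop = FALSE]
      rb <- X[grid$class == classes[j] & grid$condition == cd, , drop = FALSE]
      L <- ra - rb
      est <- as.numeric(L %*% b)
      se <- sqrt(as.numeric(L %*% V %*% t(L)))
      z <- est / se
      rows[[length(rows) + 1]] <- tibble(
        condition = cd, class_a = classes[i], class_b = classes[j],
        pair = paste(classes[i], "vs", classes[j]),
        estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
    }
  }
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p, family_size = max(family_size, nrow(out)))
  out
}

detect_swaps <- function(contrasts, alpha = 0.05) {
  contrasts %>%
    filter(.data$p_adj < alpha) %>%
    group_by(.data$pair) %>%
    summarise(n_sig = n(),
              signs = length(unique(sign(.data$estimate))),
              conditions = paste(.data$condition, collapse = ", "),
              .groups = "drop") %>%
    filter(.data$n_sig >= 2, .data$signs > 1)
}

#' @export
print.onset_model <- function(x, ...) {
  cat(sprintf("<onset_model> gamma(%s link)%s; %d contrasts, %d swap pair(s); %d onsets dropped\n",
              x$link, if (x$converged) "" else " [convergence flagged]",
              nrow(x$contrasts), nrow(x$swaps), x$n_dropped))
  invisible(x)
}

#' @export
tidy.onset_model <- function(x, ...) x$contrasts

#' @export
glance.onset_model <- function(x, ...) {
  tibble(link = x$link, converged = x$converged, n_dropped = x$n_dropped,
         n_swaps = nrow(x$swaps),
         interaction_p = {
       ip <- x$fixed_tests$p[x$fixed_tests$term == "class:condition"]
       if (length(ip)) ip else NA_real_
     })
}
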