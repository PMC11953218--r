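test_that("rmANOVA F, eta_p^2 and epsilon match independent oracles", {
  set.seed(31)
  for (rep in 1:5) {
    d <- random_design_table(n = 8 + rep)
    d$value <- d$value + 0.6 * as.numeric(factor(d$direction))
    a <- rm_anova_2x3(d)
    o <- aov_oracle(d)
    expect_equal(a$F[a$effect == "waveform"], o$F_w, tolerance = 1e-8)
    expect_equal(a$F[a$effect == "direction"], o$F_d, tolerance = 1e-8)
    expect_equal(a$F[a$effect == "interaction"], o$F_wd, tolerance = 1e-8)
    # eta_p^2 recomputed from F and df (internal consistency)
    pes <- a$F * a$df1 / (a$F * a$df1 + a$df2)
    expect_equal(a$pes, pes, tolerance = 1e-10)
  }
})

test_that("Mauchly test and Greenhouse-Geisser epsilon match base R's mlm path", {
  set.seed(32)
  n <- 12
  M <- matrix(rnorm(n * 3), n, 3) %*% matrix(c(1, .3, 0, 1.5, 0, .2, 0, 0, 3), 3)
  # package path: via the direction effect of a 2x3 table whose waveform
  # halves are identical, so direction scores equal M
  d <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                   waveform = c("monophasic", "biphasic"),
                   direction = c("PA", "AP", "LM"), stringsAsFactors = FALSE)
  d$value <- M[cbind(match(d$subject_id, sprintf("s%02d", 1:n)),
                     match(d$direction, c("PA", "AP", "LM")))]
  a <- rm_anova_2x3(tibble::as_tibble(d))

  mlm <- stats::lm(M ~ 1)
  mt <- stats::mauchly.test(mlm, X = ~1,
                            idata = data.frame(direction = factor(1:3)))
  expect_equal(a$mauchly_w[a$effect == "direction"], unname(mt$statistic),
               tolerance = 1e-8)
  expect_equal(a$mauchly_p[a$effect == "direction"], mt$p.value, tolerance = 1e-8)

  # epsilon oracle from eigenvalues of the double-centered covariance
  S <- cov(M)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  ev <- eigen(Sc, only.values = TRUE)$values[1:2]
  expect_equal(a$gg_eps[a$effect == "direction"], sum(ev)^2 / (2 * sum(ev^2)),
               tolerance = 1e-8)
  expect_true(all(a$gg_eps[-1] > 0.5 & a$gg_eps[-1] <= 1))
})

test_that("rmANOVA is invariant to adding a constant and rejects incompleteness", {
  set.seed(33)
  d <- random_design_table(10)
  a1 <- rm_anova_2x3(d)
  d2 <- d; d2$value <- d2$value + 100
  a2 <- rm_anova_2x3(d2)
  expect_equal(a1$F, a2$F, tolerance = 1e-9)

  expect_error(rm_anova_2x3(d[-1, ]), "incomplete design.*s01")
})

test_that("Tukey post-hocs behave at ties, dominate raw p, and report paired d", {
  d <- random_design_table(9)
  # force two identical direction cells
  d$value[d$direction == "AP"] <- d$value[d$direction == "PA"]
  th <- tukey_posthoc(d, "direction")
  row <- th[th$contrast == "PA - AP", ]
  expect_equal(row$t, 0)
  expect_equal(row$p_tukey, 1)

  set.seed(34)
  for (i in 1:25) {
    th <- tukey_posthoc(random_design_table(7), "condition")
    expect_true(all(th$p_tukey >= th$p_raw - 1e-12))
    expect_true(all(th$p_tukey <= 1))
  }

  # d = 2 separation detected reliably at n = 28
  set.seed(35)
  hits <- vapply(1:15, function(i) {
    d <- random_design_table(28)
    d$value[d$direction == "AP"] <- d$value[d$direction == "AP"] + 2
    th <- tukey_posthoc(d, "direction")
    th$p_tukey[th$contrast == "PA - AP"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 14 / 15)
})

test_that("trimmed rmANOVA reduces to the classical F at trim 0", {
  set.seed(36)
  for (i in 1:4) {
    n <- 9 + i
    Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("PA", "AP", "LM")))
    r0 <- robust_trimmed_rm_anova(Y, trim = 0)
    d <- data.frame(value = as.vector(Y),
                    direction = rep(colnames(Y), each = n),
                    subject_id = sprintf("s%02d", rep(1:n, 3)))
    s <- summary(stats::aov(value ~ direction + Error(factor(subject_id) / direction),
                            data = d))
    Fc <- s[["Error: factor(subject_id):direction"]][[1]]["direction", "F value"]
    expect_equal(r0$F, Fc, tolerance = 1e-8)
    # contrasts reduce to paired t tests
    tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
    row <- r0$contrasts[r0$contrasts$contrast == "PA - AP", ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-8)
  }
})

test_that("the trimmed test resists an extreme subject that breaks the classical F", {
  set.seed(37)
  n <- 12
  Y <- cbind(PA = rnorm(n, 0, 0.3), AP = rnorm(n, 1, 0.3), LM = rnorm(n, 2, 0.3))
  Yx <- rbind(Y, c(60, -50, 70))   # one wild subject
  classical <- robust_trimmed_rm_anova(Yx, trim = 0)
  robust <- robust_trimmed_rm_anova(Yx, trim = 0.2)
  clean <- robust_trimmed_rm_anova(Y, trim = 0.2)
  expect_lt(clean$p, 0.001)
  expect_lt(robust$p, 0.01)      # decision survives the outlier
  expect_gt(classical$p, 0.05)   # classical decision flips

  expect_error(robust_trimmed_rm_anova(Y[1:4, ], trim = 0.25), "too few")
  expect_error(robust_trimmed_rm_anova(Y, trim = 0.4), "trim must be")
})

test_that("ANCOVA separates direction effects from intensity confounds", {
  set.seed(38)
  n <- 16
  mkdata <- function(y, x) {
    tibble::tibble(subject_id = rep(sprintf("s%02d", 1:n), 3),
                   direction = rep(c("PA", "AP", "LM"), each = n),
                   value = y, intensity = x)
  }
  # response purely linear in the covariate
  x <- rnorm(3 * n, 50, 5)
  a <- ancova_direction(mkdata(2 * x + rnorm(3 * n, 0, 0.5), x))
  expect_gt(a$p[a$term == "direction"], 0.2)
  expect_lt(a$p[a$term == "intensity"], 1e-6)

  # direction effect fully mediated by intensity differences
  xm <- rnorm(3 * n, 50, 1) + rep(c(0, 4, 8), each = n)
  ym <- xm + rnorm(3 * n, 0, 0.7)
  conf <- mkdata(ym, xm)
  adj <- ancova_direction(conf)
  unadj <- ancova_direction(transform(conf, intensity = intensity * 0 + rnorm(3 * n)))
  expect_lt(unadj$p[unadj$term == "direction"], 0.001)  # spurious without adjustment
  expect_gt(adj$p[adj$term == "direction"], 0.05)       # removed by the covariate

  expect_error(ancova_direction(mkdata(ym, rep(1, 3 * n))), "constant covariate")
})

test_that("BH adjustment matches hand computation and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  brute_bh <- function(p, m) {
    k <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(k)
    adj <- vapply(seq_len(k), function(i) min(1, min(q[i:k])), 1.0)
    out <- numeric(k); out[o] <- adj; out
  }
  set.seed(39)
  for (i in 1:300) {
    k <- sample(1:30, 1)
    p <- runif(k)
    m <- k + sample(0:60, 1)
    expect_identical(bh_adjust(p, m), brute_bh(p, m))
    expect_equal(bh_adjust(p, m), p.adjust(p, "BH", n = m))
  }
  expect_error(bh_adjust(c(0, 0.5)), "in \\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.5), family_size = 1), "family_size")
})

test_that("the onset model degrades gracefully to a single condition", {
  set.seed(40)
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:12),
                          condition = "monophasic_PA", class = 1:4)
  d$onset <- rgamma(nrow(d), shape = 30, rate = 30 / (20 * d$class))
  om <- onset_mixed_model(d, family_size = 6)
  expect_false("class:condition" %in% om$fixed_tests$term)
  expect_true("class" %in% om$fixed_tests$term)
  expect_lt(om$fixed_tests$p[om$fixed_tests$term == "class"], 1e-4)
  expect_equal(nrow(om$contrasts), 6)

  d$onset[1] <- -1
  expect_error(onset_mixed_model(d), "strictly positive")
})
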