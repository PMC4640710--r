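test_that("with zero random-effect variance the mixed fit is plain logistic", {
  # large cohort so the variance estimate reaches its true boundary value,
  # where the integrated likelihood reduces to the pooled logistic one
  cfg <- one_driver_config(n_subjects = 3000L, baseline_logit = -1.5,
                           seed = 403L)
  prox <- build_proximity(generate_cohort(cfg))
  m <- suppressWarnings(fit_mixed_logit(prox, "violent_ideation",
                                        adjust = FALSE, levels = 2))
  g <- stats::glm(outcome ~ violent_ideation, stats::binomial(),
                  data = as.data.frame(prox))
  expect_lt(abs(coef(m)[["violent_ideation"]] -
                  coef(g)[["violent_ideation"]]), 1e-3)
  expect_lt(abs(coef(m)[["(Intercept)"]] - coef(g)[["(Intercept)"]]), 1e-3)
  expect_lt(m$var_subject, 0.05)
})

test_that("odds ratios and Wald intervals are internally consistent", {
  cfg <- small_config(n_subjects = 200L, seed = 223L)
  prox <- build_proximity(generate_cohort(cfg))
  m <- suppressWarnings(fit_mixed_logit(prox, "instability"))
  expect_equal(m$terms$or, exp(m$terms$beta), tolerance = 1e-10)
  expect_true(all(m$terms$ci_lo <= m$terms$or & m$terms$or <= m$terms$ci_hi))
  expect_true(m$var_subject >= 0 && m$var_trust >= 0)
  expect_equal(unname(coef(m)), m$terms$beta)
  ci <- confint(m)
  expect_equal(unname(ci[, 1]), m$terms$beta - qnorm(0.975) * m$terms$se)
})

test_that("estimates and likelihood stabilise as quadrature nodes increase", {
  cfg <- one_driver_config(n_subjects = 400L, sigma_subject = 0.7, seed = 227L)
  prox <- build_proximity(generate_cohort(cfg))
  fits <- lapply(c(1, 7, 15), function(q)
    suppressWarnings(fit_mixed_logit(prox, "violent_ideation",
                                     adjust = FALSE, levels = 2, nAGQ = q)))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  beta <- vapply(fits, function(f) coef(f)[["violent_ideation"]], numeric(1))
  # converged quadrature: 7 and 15 nodes agree far more closely than 1 and 15
  expect_lt(abs(ll[2] - ll[3]), 1e-3)
  # agreement between 7 and 15 nodes is limited by optimizer precision
  expect_lt(abs(beta[2] - beta[3]), 5e-4)
  expect_lt(abs(ll[2] - ll[3]), abs(ll[1] - ll[3]))
})

test_that("a 3-level fit on Trust-free data collapses to the 2-level fit", {
  cfg <- one_driver_config(n_subjects = 500L, sigma_subject = 0.7, seed = 229L)
  prox <- build_proximity(generate_cohort(cfg))
  m3 <- suppressWarnings(fit_mixed_logit(prox, "violent_ideation",
                                         adjust = FALSE, levels = 3))
  m2 <- suppressWarnings(fit_mixed_logit(prox, "violent_ideation",
                                         adjust = FALSE, levels = 2, nAGQ = 1))
  expect_lt(m3$var_trust, 0.02)
  expect_lt(abs(coef(m3)[["violent_ideation"]] - coef(m2)[["violent_ideation"]]),
            1e-2)
  expect_equal(m3$var_subject, m2$var_subject, tolerance = 0.05)
  expect_equal(m3$loglik, m2$loglik, tolerance = 1e-4)
})

test_that("a known concurrent effect is recovered by the proximity fit", {
  cfg <- small_config(n_subjects = 800L, sigma_trust = 0, seed = 233L)
  prox <- build_proximity(generate_cohort(cfg))
  terms <- c(proximal_risk_items(), proximal_protective_item())
  m <- suppressWarnings(fit_mixed_logit(prox, terms, adjust = FALSE,
                                        levels = 2, include_window = TRUE))
  truth <- cfg$gamma_proximal
  tt <- m$terms[m$terms$term %in% names(truth), ]
  covered <- tt$beta - 1.96 * tt$se <= truth[tt$term] &
    truth[tt$term] <= tt$beta + 1.96 * tt$se
  expect_gte(sum(covered), 3L)  # at least 3 of the 4 effects at one seed
})

test_that("item tables are fitted per item and record failures in place", {
  panel <- generate_cohort(small_config(n_subjects = 250L, seed = 239L))
  static <- fit_item_table(panel, "static", levels = 2)
  expect_equal(nrow(static), 11L)  # 10 historical items + the total score
  expect_true(all(c("or", "ci_lo", "ci_hi", "p", "converged") %in%
                    names(static)))

  # a constant column cannot be fitted; the remaining items still are
  panel$data$violence_history <- 0L
  tab <- fit_item_table(panel, "static", levels = 2,
                        items = c("violence_history", "traumatic_experiences"))
  expect_true(is.na(tab$or[tab$item == "violence_history"]))
  expect_false(is.na(tab$or[tab$item == "traumatic_experiences"]))

  expect_equal(nrow(fit_item_table(panel, "proximity", items = character())),
               0L)
})

test_that("proximal items associate more strongly under proximity than lagged", {
  panel <- generate_cohort(small_config(n_subjects = 400L, seed = 241L))
  items <- proximal_risk_items()
  prox <- fit_item_table(panel, "proximity", levels = 2, items = items)
  lag <- fit_item_table(panel, "lagged", levels = 2, items = items)
  expect_true(all(prox$or > lag$or))
})

test_that("spearman summaries match a direct recomputation", {
  panel <- generate_cohort(small_config(n_subjects = 250L, seed = 251L))
  s <- spearman_item_summary(panel, "C", "m6")
  expect_equal(s$n_pairs, choose(5, 2))
  d <- panel$data[panel$data$wave == "m6", ]
  rho_direct <- cor(d$lack_of_insight, d$violent_ideation, method = "spearman")
  got <- s$pairs$rho[s$pairs$item1 == "lack_of_insight" &
                       s$pairs$item2 == "violent_ideation"]
  expect_equal(got, rho_direct, tolerance = 1e-12)
  expect_equal(s$M, mean(s$pairs$rho))
  expect_equal(s$Md, median(s$pairs$rho))
  expect_equal(s$alpha, 0.05 / s$n_pairs)
})

test_that("spearman summaries are invariant to monotone score transforms", {
  panel <- generate_cohort(small_config(n_subjects = 200L, seed = 257L))
  s1 <- spearman_item_summary(panel, "SAPROF", "m6")
  squared <- panel
  for (item in distal_protective_items())
    squared$data[[item]] <- squared$data[[item]]^2  # 0,1,2 -> 0,1,4
  s2 <- spearman_item_summary(squared, "SAPROF", "m6")
  expect_equal(s1$M, s2$M)
  expect_equal(s1$n_significant, s2$n_significant)
})

test_that("identical items correlate perfectly; constant items are excluded", {
  panel <- generate_cohort(small_config(n_subjects = 150L, seed = 263L))
  panel$data$lack_of_insight <- panel$data$violent_ideation
  s <- spearman_item_summary(panel, "C", "m6")
  pair <- s$pairs[s$pairs$item1 == "lack_of_insight" &
                    s$pairs$item2 == "violent_ideation", ]
  expect_equal(pair$rho, 1)
  expect_lt(pair$p, s$alpha)

  panel$data$instability <- 0L
  s2 <- spearman_item_summary(panel, "C", "m6")
  expect_equal(s2$excluded_items, "instability")
  expect_equal(s2$n_pairs, choose(4, 2))
})

test_that("independent items rarely clear the Bonferroni threshold", {
  cfg <- null_config(n_subjects = 400L, seed = 269L)
  panel <- generate_cohort(cfg)  # delta_distal = 0: SAPROF items independent
  s <- spearman_item_summary(panel, "SAPROF", "m6")
  expect_equal(s$n_pairs, choose(17, 2))
  expect_lte(s$n_significant, 2L)
})
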