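test_that("cell means on the 3x2 worked table", {
  cm <- cell_means(spec_trial(), "y")
  expect_equal(cm$overall_mean, 9)
  expect_equal(unname(cm$tester_means), c(10, 8))
  expect_equal(unname(cm$line_means), c(9, 9, 9))
  expect_equal(unname(cm$cross_means["L2", ]), c(12, 6))
})

test_that("cell means: rep averaging, constant table, empty-cross error", {
  tt <- trial_table(data.frame(
    line = rep(c("L1", "L2"), each = 4),
    tester = rep(c("T1", "T1", "T2", "T2"), 2),
    env = "E1", rep = rep(1:2, 4),
    y = c(4, 6, 5, 5, 7, 7, 2, 4)), "y")
  cm <- cell_means(tt, "y")
  expect_equal(unname(cm$cross_means["L1", "T1"]), 5)  # mean of {4, 6}
  tt2 <- trial_table(data.frame(line = c("L1", "L1", "L2", "L2"),
                                tester = rep(c("T1", "T2"), 2),
                                env = "E1", rep = 1L, y = 7), "y")
  cm2 <- cell_means(tt2, "y")
  expect_equal(unname(c(cm2$overall_mean, cm2$line_means, cm2$tester_means)),
               rep(7, 5))
  tt3 <- trial_table(data.frame(line = c("L1", "L1", "L2"),
                                tester = c("T1", "T2", "T1"),
                                env = "E1", rep = 1L,
                                y = c(1, 2, NA)), "y")
  expect_error(cell_means(tt3, "y"), "L2 x T1")
})

test_that("GCA/SCA/HSGCA on the 3x2 worked table", {
  ef <- estimate_effects(cell_means(spec_trial(), "y"))
  expect_equal(unname(ef$gca_line), c(0, 0, 0))
  expect_equal(unname(ef$gca_tester), c(1, -1))
  expect_equal(unname(ef$sca),
               matrix(c(0, 2, -2, 0, -2, 2), 3, 2), tolerance = 1e-12)
  # hsgca identity: hsgca(L2, T1) = X_21 - tester1 mean = 12 - 10
  expect_equal(unname(ef$hsgca["L2", "T1"]), 2)
  expect_equal(ef$hsgca, sweep(cell_means(spec_trial(), "y")$cross_means,
                               2, c(10, 8)), ignore_attr = TRUE)
})

test_that("effects on a constant table are all zero; <2 testers rejected", {
  cm <- make_means(matrix(5, 3, 2, dimnames = list(paste0("L", 1:3),
                                                   c("T1", "T2"))))
  ef <- estimate_effects(cm)
  expect_true(all(unlist(ef[c("gca_line", "gca_tester", "sca")]) == 0))
  cm1 <- make_means(matrix(1:3, 3, 1, dimnames = list(paste0("L", 1:3), "T1")))
  expect_error(estimate_effects(cm1), "2 lines and")
})

test_that("zero-sum and HSGCA identities hold on simulated balanced data", {
  sim <- simulate_trial(sim_config(n_lines = 15, n_envs = 3, seed = 8))
  for (tr in c("grain_yield", "pva")) {
    cm <- cell_means(sim$trial, tr)
    ef <- estimate_effects(cm)
    scale <- max(1, abs(cm$overall_mean))
    expect_lt(abs(sum(ef$gca_line)), 1e-10 * scale)
    expect_lt(abs(sum(ef$gca_tester)), 1e-10 * scale)
    expect_lt(max(abs(rowSums(ef$sca))), 1e-10 * scale)
    expect_lt(max(abs(colSums(ef$sca))), 1e-10 * scale)
    expect_identical(ef$hsgca, sweep(cm$cross_means, 2, cm$tester_means))
    expect_equal(ef$hsgca, ef$sca + ef$gca_line, tolerance = 1e-10)
  }
})

test_that("ANOVA df follow the closed forms and SS are additive", {
  sim <- simulate_trial(sim_config(n_lines = 6, n_testers = 3, n_envs = 4,
                                   n_reps = 2, seed = 5))
  an <- anova_line_by_tester(sim$trial, "pva")
  tab <- an$table
  df_of <- function(s) tab$df[tab$source == s]
  expect_equal(df_of("Environment"), 3)
  expect_equal(df_of("Rep(Env)"), 4)
  expect_equal(df_of("Line (GCA)"), 5)
  expect_equal(df_of("Tester (GCA)"), 2)
  expect_equal(df_of("Line x Tester (SCA)"), 10)
  expect_equal(df_of("Hybrid"), 17)
  expect_equal(df_of("Line x Env"), 15)
  expect_equal(df_of("Line x Tester x Env"), 30)
  expect_equal(df_of("Error"), 6 * 3 * 4 * 2 - 1 - 3 - 4 - 17 - 51)
  y <- sim$trial$data$pva
  ss_of <- function(s) tab$sum_sq[tab$source == s]
  total <- sum((y - mean(y))^2)
  expect_equal(ss_of("Environment") + ss_of("Rep(Env)") + ss_of("Hybrid") +
                 ss_of("Hybrid x Env") + ss_of("Error"), total,
               tolerance = 1e-8)
  # nested partitions add to their parents
  expect_equal(ss_of("Hybrid"),
               ss_of("Line (GCA)") + ss_of("Tester (GCA)") +
                 ss_of("Line x Tester (SCA)"), tolerance = 1e-8)
  expect_equal(ss_of("Hybrid x Env"),
               ss_of("Line x Env") + ss_of("Tester x Env") +
                 ss_of("Line x Tester x Env"), tolerance = 1e-8)
})

test_that("GCA/SCA estimation error shrinks as environments grow", {
  err_at <- function(ne) {
    errs <- vapply(1:5, function(s) {
      sim <- simulate_trial(sim_config(
        n_lines = 10, n_envs = ne,
        traits = list(y = list(mu = 0, var_gca_line = 1, var_gca_tester = 0.5,
                               var_sca = 1, var_env = 1, var_rep = 0,
                               var_gxe = 0.5, var_error = 2)),
        seed = 500 + s))
      ef <- estimate_effects(cell_means(sim$trial, "y"))
      mean(abs(ef$gca_line - sim$truth$y$gca_line)) +
        mean(abs(ef$sca - sim$truth$y$sca))
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(2), err_at(8), err_at(32))
  expect_true(all(diff(e) < 0))
})

test_that("repeatability approaches its limits", {
  base <- list(mu = 10, var_gca_line = 0, var_gca_tester = 0, var_sca = 0,
               var_env = 0, var_rep = 0, var_gxe = 0, var_error = 1)
  sim0 <- simulate_trial(sim_config(n_lines = 20, n_envs = 4,
                                    traits = list(y = base), seed = 31))
  an0 <- anova_line_by_tester(sim0$trial, "y")
  expect_lt(an0$repeatability, 0.5)
  high <- base; high$var_gca_line <- 50; high$var_sca <- 20
  sim1 <- simulate_trial(sim_config(n_lines = 20, n_envs = 4,
                                    traits = list(y = high), seed = 31))
  an1 <- anova_line_by_tester(sim1$trial, "y")
  expect_gt(an1$repeatability, 0.95)
})

test_that("unbalanced data warn; missing cells tolerated through cell means", {
  sim <- simulate_trial(sim_config(n_lines = 6, n_envs = 3, seed = 12))
  d <- sim$trial$data
  d$pva[3] <- NA
  tt <- trial_table(d, sim$trial$traits)
  expect_warning(an <- anova_line_by_tester(tt, "pva"), "unbalanced")
  expect_true(all(is.finite(an$table$mean_square)))
})

test_that("LSD: frozen cross-implementation value, scaling, normal limit", {
  sim <- simulate_trial(sim_config(n_lines = 6, n_envs = 3, seed = 5))
  an <- anova_line_by_tester(sim$trial, "pva")
  ms_err <- an$table$mean_square[an$table$source == "Error"]
  df_err <- an$table$df[an$table$source == "Error"]
  # doubling MS_error multiplies LSD by sqrt(2)
  an2 <- an
  an2$table$mean_square[an2$table$source == "Error"] <- 2 * ms_err
  expect_equal(lsd(an2, 0.05, 4), sqrt(2) * lsd(an, 0.05, 4))
  # frozen oracle: scipy.stats.t.ppf(0.975, 500) on MS=1.36, n=16
  an3 <- an
  an3$table$mean_square[an3$table$source == "Error"] <- 1.36
  an3$table$df[an3$table$source == "Error"] <- 500
  expect_equal(lsd(an3, 0.05, 16), 0.810074741462432, tolerance = 1e-6)
  # large-df normal limit: t quantile within 1% of 1.96
  an4 <- an
  an4$table$mean_square[an4$table$source == "Error"] <- 1
  an4$table$df[an4$table$source == "Error"] <- 2000
  expect_equal(lsd(an4, 0.05, 2), 1.9611508260994377, tolerance = 1e-9)
  expect_lt(abs(lsd(an4, 0.05, 2) / 1.959964 - 1), 0.01)
  expect_error(lsd(an, 1.5, 4), "alpha")
})
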