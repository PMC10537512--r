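two_tester_sca <- function(s1, lines = NULL) {
  if (is.null(lines)) lines <- sprintf("L%02d", seq_along(s1))
  m <- cbind(T1 = s1, T2 = -s1)
  rownames(m) <- lines
  m
}

test_that("SCA rule: sign opposition, magnitude floor, mean condition", {
  sca <- two_tester_sca(c(150, -150, 60, 0, 200))
  ef <- make_effects(sca, trait = "grain_yield")
  cm <- make_means(matrix(6000, 5, 2,
                          dimnames = list(rownames(sca), c("T1", "T2"))),
                   trait = "grain_yield")
  conf <- grouping_config()
  a <- assign_sca(ef, cm, check_mean = 6000, lsd_value = 300, conf,
                  trait = "grain_yield")
  expect_equal(a$group,
               c("HGB",        # +150 with T1, -150 with T2
                 "HGA",        # reversed signs
                 "unassigned", # |60| below the 100 kg/ha floor
                 "unassigned", # exactly zero SCA
                 "HGB"))
  # mean condition: best testcross mean below check - LSD blocks assignment
  cm_low <- make_means(matrix(5000, 5, 2,
                              dimnames = dimnames(cm$cross_means)),
                       trait = "grain_yield")
  a2 <- assign_sca(ef, cm_low, check_mean = 6000, lsd_value = 300, conf,
                   trait = "grain_yield")
  expect_true(all(a2$group == "unassigned"))
  # boundary: best mean exactly at check - LSD passes ("not significantly different")
  cm_edge <- make_means(matrix(5700, 5, 2,
                               dimnames = dimnames(cm$cross_means)),
                        trait = "grain_yield")
  a3 <- assign_sca(ef, cm_edge, check_mean = 6000, lsd_value = 300, conf,
                   trait = "grain_yield")
  expect_equal(a3$group[1], "HGB")
  expect_error(assign_sca(ef, cm, check_mean = NA, lsd_value = 300, conf),
               "check_mean")
})

test_that("per-trait magnitude floors: pva uses 0.05, unknown traits 0", {
  sca <- two_tester_sca(c(0.04, 0.06))
  cm <- make_means(matrix(12, 2, 2, dimnames = list(rownames(sca),
                                                    c("T1", "T2"))))
  conf <- grouping_config()
  a <- assign_sca(make_effects(sca, trait = "pva"), cm, 10, 1, conf, "pva")
  expect_equal(a$group, c("unassigned", "HGB"))
  a2 <- assign_sca(make_effects(sca, trait = "other"), cm, 10, 1, conf,
                   "other")
  expect_equal(a2$group, c("HGB", "HGB"))
})

test_that("HSGCA rule: opposite signs, same-sign tie-break, exact tie", {
  h <- rbind(L01 = c(0.8, -0.3),   # positive only with T1 -> HGB
             L02 = c(-0.2, 0.6),   # positive only with T2 -> HGA
             L03 = c(0.5, 0.2),    # both positive, smaller with T2 -> HGA
             L04 = c(-0.4, -0.1),  # both negative, smaller (T1) -> HGB
             L05 = c(0.3, 0.3))    # exact tie -> first tester -> HGB
  colnames(h) <- c("T1", "T2")
  ef <- make_effects(sca = h, hsgca = h)
  conf <- grouping_config()
  a <- assign_hsgca(ef, conf)
  expect_equal(a$group, c("HGB", "HGA", "HGA", "HGB", "HGB"))
  expect_equal(attr(a, "ties"), "L05")
  # method is total: every line assigned
  expect_false(any(a$group == "unassigned"))
  # max_value tie-break flips only the same-sign cases
  a2 <- assign_hsgca(ef, grouping_config(tie_break = "max_value"))
  expect_equal(a2$group, c("HGB", "HGA", "HGB", "HGA", "HGA"))
})

test_that("assign_hsgca rejects more than two testers", {
  h <- matrix(rnorm(9), 3, dimnames = list(paste0("L", 1:3),
                                           paste0("T", 1:3)))
  expect_error(assign_hsgca(make_effects(sca = h, hsgca = h),
                            grouping_config()),
               "two testers")
})

test_that("swapping the tester-group map swaps every label and nothing else", {
  set.seed(14)
  h <- cbind(T1 = rnorm(20), T2 = rnorm(20))
  rownames(h) <- sprintf("L%02d", 1:20)
  ef <- make_effects(sca = h, hsgca = h)
  a <- assign_hsgca(ef, grouping_config())
  b <- assign_hsgca(ef, grouping_config(
    tester_to_group = c(T1 = "HGA", T2 = "HGB")))
  swap <- c(HGA = "HGB", HGB = "HGA")
  expect_equal(b$group, unname(swap[a$group]))
})

test_that("two-tester SCA antisymmetry makes the rule a sign test", {
  sim <- simulate_trial(sim_config(n_lines = 10, n_envs = 2, seed = 6))
  ef <- estimate_effects(cell_means(sim$trial, "pva"))
  expect_equal(ef$sca[, 1], -ef$sca[, 2], tolerance = 1e-10)
})

test_that("Spearman concordance and agreement percentages", {
  mk <- function(groups, scores, lines = sprintf("L%02d", seq_along(groups))) {
    a <- data.frame(line = lines, group = groups, score = scores,
                    stringsAsFactors = FALSE)
    structure(a, method = "X",
              class = c("heterotic_assignment", "data.frame"))
  }
  a <- mk(c("HGA", "HGA", "HGB"), c(1, 2, 3))
  b <- mk(c("HGA", "HGA", "HGB"), c(10, 20, 30))
  cc <- compare_methods(list(A = a, B = b))
  expect_equal(cc$rho["A", "B"], 1)
  expect_equal(cc$agreement_pct["A", "B"], 100)
  b2 <- mk(c("HGA", "HGA", "HGB"), c(3, 2, 1))
  expect_equal(compare_methods(list(A = a, B = b2))$rho["A", "B"], -1,
               ignore_attr = TRUE)
  # unassigned counts against agreement even when it matches
  c2 <- mk(c("HGA", "unassigned", "unassigned"), c(1, 2, 3))
  c3 <- mk(c("HGA", "HGB", "unassigned"), c(1, 2, 3))
  expect_equal(compare_methods(list(A = c2, B = c3))$agreement_pct["A", "B"],
               100 / 3, ignore_attr = TRUE)
  # mismatched line sets
  d <- mk(c("HGA", "HGB"), c(1, 2), lines = c("L01", "LXX"))
  expect_error(compare_methods(list(A = a, B = d)), "different line sets")
})

test_that("HSGCA grouping recovers planted labels when signal dominates", {
  gs <- stats::setNames(rep(c("HGA", "HGB"), 10), sprintf("L%02d", 1:20))
  hits <- vapply(1:5, function(s) {
    sim <- simulate_trial(sim_config(
      n_lines = 20, n_envs = 8, group_structure = gs,
      traits = list(pva = list(mu = 12, var_gca_line = 0.05,
                               var_gca_tester = 0.05, var_sca = 1,
                               var_env = 1, var_rep = 0, var_gxe = 0.05,
                               var_error = 0.25)),
      seed = 700 + s))
    ef <- estimate_effects(cell_means(sim$trial, "pva"))
    a <- assign_hsgca(ef, grouping_config())
    mean(a$group == sim$truth$groups[a$line])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
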