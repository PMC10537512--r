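## Combined line-by-tester analysis across environments: cross means, GCA /
## SCA / HSGCA effects, the sequential ANOVA with its EMS-based F tests,
## entry-mean repeatability, CV and the LSD companion statistic.

#' Cross, line, tester and overall means for one trait
#'
#' Cross means are arithmetic means over env x rep plot observations
#' (missing cells excluded).  Margins (line means, tester means, overall
#' mean) are computed from the table of cross means, not by pooling raw
#' plots, so mildly unbalanced replication does not bias them.  Check-hybrid
#' plots (line id equal to a tester id) are kept out of the line set; their
#' cross means are available in `check_means`.
#'
#' @param trial a [trial_table].
#' @param trait trait name.
#' @return object of class `cross_means`: list with `overall_mean`,
#'   `line_means`, `tester_means`, `cross_means` (lines x testers matrix),
#'   `n_obs` (same shape), `check_means` (named by check line id, or NULL),
#'   `trait`.
#' @export
cell_means <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"), trait %in% trial$traits)
  d <- trial$data[!trial$data$is_check, , drop = FALSE]
  lines <- trial$lines; testers <- trial$testers
  y <- d[[trait]]
  li <- factor(d$line, levels = lines)
  ti <- factor(d$tester, levels = testers)
  ok <- !is.na(y)
  n_obs <- table(li[ok], ti[ok])
  if (any(n_obs == 0)) {
    idx <- which(n_obs == 0, arr.ind = TRUE)[1, ]
    stop("no observations for cross ", lines[idx[1]], " x ",
         testers[idx[2]], " in trait '", trait, "'")
  }
  cm <- tapply(y, list(li, ti), mean, na.rm = TRUE)
  line_means <- rowMeans(cm)
  tester_means <- colMeans(cm)
  overall <- mean(cm)
  check_means <- NULL
  chk <- trial$data[trial$data$is_check, , drop = FALSE]
  if (nrow(chk) > 0)
    check_means <- tapply(chk[[trait]], chk$line, mean, na.rm = TRUE)
  structure(list(overall_mean = overall, line_means = line_means,
                 tester_means = tester_means, cross_means = cm,
                 n_obs = unclass(n_obs), check_means = check_means,
                 trait = trait),
            class = "cross_means")
}

#' GCA, SCA and HSGCA effects from cross means
#'
#' Applies the classical line-by-tester estimators verbatim:
#' \deqn{GCA_j = \bar X_{.j} - \bar X_{..}}
#' \deqn{SCA_{ji} = \bar X_{ji} - \bar X_{.j} - \bar X_{i.} + \bar X_{..}}
#' \deqn{HSGCA_{ji} = GCA_j + SCA_{ji} = \bar X_{ji} - \bar X_{i.}}
#' where j indexes lines and i testers.  The last identity (cross mean minus
#' tester mean) is verified internally as a self-check.  Standard errors per
#' effect class are filled in when an [anova_line_by_tester()] result is
#' supplied (they need an error mean square); otherwise `NA`.
#'
#' @param means a [cell_means()] result.
#' @param anova optional `lxt_anova` for standard errors; the denominator
#'   mean squares match the F-test denominators (the x Env interactions).
#' @return object of class `effects_table`: list with `trait`, `gca_line`,
#'   `gca_tester`, `sca` (lines x testers), `hsgca` (lines x testers), `se`
#'   (named: gca_line, gca_tester, sca).
#' @export
estimate_effects <- function(means, anova = NULL) {
  stopifnot(inherits(means, "cross_means"))
  if (length(means$line_means) < 2 || length(means$tester_means) < 2)
    stop("need at least 2 lines and 2 testers")
  gl <- means$line_means - means$overall_mean
  gt <- means$tester_means - means$overall_mean
  sca <- sweep(sweep(means$cross_means, 1, means$line_means),
               2, means$tester_means) + means$overall_mean
  # cross mean minus tester mean: bit-exact form of GCA + SCA
  hsgca <- sweep(means$cross_means, 2, means$tester_means)
  scale <- max(1, abs(means$overall_mean))
  stopifnot(max(abs(hsgca - (sca + gl))) < 1e-8 * scale)
  se <- c(gca_line = NA_real_, gca_tester = NA_real_, sca = NA_real_)
  if (!is.null(anova)) {
    stopifnot(inherits(anova, "lxt_anova"))
    r <- anova$design["n_reps"]; e <- anova$design["n_envs"]
    nl <- anova$design["n_lines"]; nt <- anova$design["n_testers"]
    ms <- function(src) anova$table$mean_square[anova$table$source == src]
    se <- c(gca_line = sqrt(ms("Line x Env") / (r * e * nt)),
            gca_tester = sqrt(ms("Tester x Env") / (r * e * nl)),
            sca = sqrt(ms("Line x Tester x Env") / (r * e)))
  }
  structure(list(trait = means$trait, gca_line = gl, gca_tester = gt,
                 sca = sca, hsgca = hsgca, se = se),
            class = "effects_table")
}

#' Combined line-by-tester ANOVA across environments
#'
#' Sequential sums of squares for the decomposition Environment + Rep(Env) +
#' Hybrid + Hybrid x Env + Error, with Hybrid partitioned into Line (GCA),
#' Tester (GCA) and Line x Tester (SCA) and Hybrid x Env partitioned
#' likewise.  Computed from factor-level means under the balanced closed
#' forms (a warning is issued for unbalanced cell counts; mild missingness
#' is tolerated through the cell-mean margins).  F denominators follow the
#' expected-mean-square logic for random environments: Line, Tester and
#' Line x Tester are tested against their matching x Env interaction,
#' Hybrid against Hybrid x Env, Environment against Rep(Env), and all x Env
#' interactions against the error mean square.
#'
#' Entry-mean repeatability uses moment estimators
#' `s2_e = MS_error`, `s2_he = (MS_HxE - MS_error) / r`,
#' `s2_h = (MS_H - MS_HxE) / (r e)` (each truncated at zero):
#' \deqn{rep = s^2_h / (s^2_h + s^2_{he}/e + s^2_e/(re))}
#' and `cv_pct = 100 sqrt(MS_error) / overall mean`.
#'
#' @param trial a [trial_table]; needs >= 2 environments and >= 2 reps for
#'   the full table (single-environment input returns the x Env rows as NA
#'   with a flag).
#' @param trait trait name.
#' @return object of class `lxt_anova`: list with `table` (data.frame:
#'   source, df, sum_sq, mean_square, F, p), `repeatability`, `cv_pct`,
#'   `design`, `trait`, `single_env` flag.
#' @export
anova_line_by_tester <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"), trait %in% trial$traits)
  d <- trial$data[!trial$data$is_check, , drop = FALSE]
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  lines <- trial$lines; testers <- trial$testers
  nl <- length(lines); nt <- length(testers)
  envs <- sort(unique(d$env)); ne <- length(envs)
  nr <- max(d$rep)
  if (nl < 2 || nt < 2) stop("need >= 2 lines and >= 2 testers")
  y <- d[[trait]]
  li <- factor(d$line, levels = lines)
  ti <- factor(d$tester, levels = testers)
  ei <- factor(d$env, levels = envs)
  ri <- factor(d$rep, levels = seq_len(nr))

  counts <- table(li, ti, ei, ri)
  balanced <- all(counts == 1)
  if (!balanced)
    warning("unbalanced data: sums of squares use balanced closed forms ",
            "on cell means and are approximate")

  gm <- mean(y)
  mean_of <- function(...) tapply(y, list(...), mean)

  # marginal and cell means
  m_e <- mean_of(ei); m_er <- mean_of(ei, ri)
  m_lt <- mean_of(li, ti); m_l <- rowMeans(m_lt); m_t <- colMeans(m_lt)
  m_le <- mean_of(li, ei); m_te <- mean_of(ti, ei)
  m_lte <- mean_of(li, ti, ei)

  ss_env <- nr * nl * nt * sum((m_e - gm)^2)
  ss_rep <- nl * nt *
    sum((as.vector(m_er) - as.vector(m_e)[rep(seq_len(ne), nr)])^2)
  ss_line <- nr * ne * nt * sum((m_l - gm)^2)
  ss_tester <- nr * ne * nl * sum((m_t - gm)^2)
  ss_lxt <- nr * ne * sum((sweep(sweep(m_lt, 1, m_l), 2, m_t) + gm)^2)
  ss_hyb <- ss_line + ss_tester + ss_lxt
  ss_le <- nr * nt *
    sum((sweep(sweep(m_le, 1, m_l), 2, m_e) + gm)^2)
  ss_te <- nr * nl *
    sum((sweep(sweep(m_te, 1, m_t), 2, m_e) + gm)^2)
  dev_lte <- m_lte
  for (k in seq_len(ne)) {
    blk <- m_lte[, , k] - m_lt - (m_le[, k] - m_l) -
      matrix(m_te[, k] - m_t, nl, nt, byrow = TRUE) + (m_e[k] - gm)
    dev_lte[, , k] <- blk
  }
  ss_lte <- nr * sum(dev_lte^2)
  ss_hxe <- ss_le + ss_te + ss_lte
  ss_total <- sum((y - gm)^2)
  ss_error <- ss_total - (ss_env + ss_rep + ss_hyb + ss_hxe)

  nh <- nl * nt
  df <- c(Environment = ne - 1,
          `Rep(Env)` = ne * (nr - 1),
          Hybrid = nh - 1,
          `Line (GCA)` = nl - 1,
          `Tester (GCA)` = nt - 1,
          `Line x Tester (SCA)` = (nl - 1) * (nt - 1),
          `Hybrid x Env` = (nh - 1) * (ne - 1),
          `Line x Env` = (nl - 1) * (ne - 1),
          `Tester x Env` = (nt - 1) * (ne - 1),
          `Line x Tester x Env` = (nl - 1) * (nt - 1) * (ne - 1))
  df_error <- nrow(d) - 1 - sum(df[c("Environment", "Rep(Env)", "Hybrid",
                                     "Hybrid x Env")])
  if (df_error < 0) stop("negative error degrees of freedom")
  df <- c(df, Error = df_error)

  ss <- c(ss_env, ss_rep, ss_hyb, ss_line, ss_tester, ss_lxt,
          ss_hxe, ss_le, ss_te, ss_lte, ss_error)
  single_env <- ne < 2
  msq <- ifelse(df > 0, ss / df, NA_real_)
  names(msq) <- names(df)

  denom <- c(Environment = "Rep(Env)", `Rep(Env)` = "Error",
             Hybrid = "Hybrid x Env", `Line (GCA)` = "Line x Env",
             `Tester (GCA)` = "Tester x Env",
             `Line x Tester (SCA)` = "Line x Tester x Env",
             `Hybrid x Env` = "Error", `Line x Env` = "Error",
             `Tester x Env` = "Error", `Line x Tester x Env` = "Error",
             Error = NA)
  Fv <- pv <- rep(NA_real_, length(df))
  names(Fv) <- names(pv) <- names(df)
  for (s in names(df)) {
    dn <- denom[[s]]
    if (is.na(dn)) next
    if (single_env && grepl("Env", s)) next
    if (single_env && dn != "Error") next
    if (!is.finite(msq[[dn]]) || msq[[dn]] <= 0 || df[[dn]] < 1) next
    Fv[[s]] <- msq[[s]] / msq[[dn]]
    pv[[s]] <- stats::pf(Fv[[s]], df[[s]], df[[dn]], lower.tail = FALSE)
  }
  if (single_env) {
    xenv <- grepl("x Env|Environment", names(df)) & names(df) != "Error"
    msq[xenv & grepl("x Env", names(df))] <- NA_real_
  }

  ms_err <- msq[["Error"]]
  s2_e <- ms_err
  s2_he <- max((msq[["Hybrid x Env"]] - ms_err) / nr, 0)
  s2_h <- max((msq[["Hybrid"]] - msq[["Hybrid x Env"]]) / (nr * ne), 0)
  if (single_env) {
    s2_he <- 0
    s2_h <- max((msq[["Hybrid"]] - ms_err) / nr, 0)
  }
  rpt <- s2_h / (s2_h + s2_he / ne + s2_e / (nr * ne))
  cv <- 100 * sqrt(ms_err) / gm

  structure(list(table = data.frame(source = names(df), df = unname(df),
                                    sum_sq = unname(ss),
                                    mean_square = unname(msq),
                                    F = unname(Fv), p = unname(pv),
                                    stringsAsFactors = FALSE),
                 repeatability = unname(rpt), cv_pct = unname(cv),
                 variance_components = c(hybrid = s2_h, hybrid_x_env = s2_he,
                                         error = s2_e),
                 design = c(n_lines = nl, n_testers = nt, n_envs = ne,
                            n_reps = nr),
                 trait = trait, single_env = single_env),
            class = "lxt_anova")
}

#' @export
print.lxt_anova <- function(x, ...) {
  cat("Combined line x tester ANOVA -", x$trait, "\n")
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, 6)
  tab$mean_square <- signif(tab$mean_square, 6)
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("repeatability = %.3f | CV = %.2f%%\n",
              x$repeatability, x$cv_pct))
  invisible(x)
}

#' Least significant difference between two means
#'
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 MS_error / n)` where `n` is the
#' number of observations behind each compared mean.
#'
#' @param anova an `lxt_anova` result (its Error row supplies MS and df).
#' @param alpha significance level in (0, 1).
#' @param n_obs_per_mean observations per mean.
#' @return the LSD on the trait's scale.
#' @export
lsd <- function(anova, alpha = 0.05, n_obs_per_mean) {
  stopifnot(inherits(anova, "lxt_anova"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  stopifnot(n_obs_per_mean >= 1)
  err <- anova$table[anova$table$source == "Error", ]
  if (err$df < 1) stop("error df must be >= 1")
  stats::qt(1 - alpha / 2, err$df) *
    sqrt(2 * err$mean_square / n_obs_per_mean)
}
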