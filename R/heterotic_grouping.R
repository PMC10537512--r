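## Assignment of lines to heterotic groups from SCA or HSGCA effects with
## two testers, plus Spearman/agreement concordance between methods.

#' Grouping configuration
#'
#' @param tester_to_group named character vector mapping each tester id to
#'   the group a line joins when its effect with that tester is positive.
#'   Default `c(T1 = "HGB", T2 = "HGA")`: lines combining well with tester 1
#'   belong to group B (the group tester 1 does not represent), and vice
#'   versa.
#' @param alpha significance level for the testcross-mean LSD check.
#' @param min_sca_magnitude named numeric, per trait: lines whose largest
#'   absolute SCA falls below this are left unassigned by the SCA method.
#'   Defaults: 100 kg/ha for `grain_yield`, 0.05 ug/g for `pva`; 0 for any
#'   other trait.
#' @param tie_break `"min_value"` (default) or `"max_value"`: when HSGCA has
#'   the same sign with both testers, the line goes to the group of the
#'   tester with the smaller (resp. larger) HSGCA value — `min_value` is the
#'   literal "smallest positive or the largest-magnitude negative" reading.
#' @return list of class `grouping_config`.
#' @export
grouping_config <- function(tester_to_group = c(T1 = "HGB", T2 = "HGA"),
                            alpha = 0.05,
                            min_sca_magnitude = c(grain_yield = 100,
                                                  pva = 0.05),
                            tie_break = c("min_value", "max_value")) {
  tie_break <- match.arg(tie_break)
  if (length(tester_to_group) != 2 ||
      length(unique(tester_to_group)) != 2)
    stop("tester_to_group must map exactly two testers to two distinct groups")
  structure(list(tester_to_group = tester_to_group, alpha = alpha,
                 min_sca_magnitude = min_sca_magnitude,
                 tie_break = tie_break),
            class = "grouping_config")
}

# resolve the config's tester map against the testers present in an
# effects table; unnamed/mismatched configs fall back to tester order
resolve_tester_map <- function(config, testers) {
  map <- config$tester_to_group
  if (!all(names(map) %in% testers)) {
    if (length(testers) != 2)
      stop("method defined for exactly two testers; got ",
           length(testers))
    map <- stats::setNames(unname(map), testers)
  }
  map[testers]
}

min_mag <- function(config, trait) {
  th <- config$min_sca_magnitude
  if (trait %in% names(th)) unname(th[[trait]]) else 0
}

#' SCA-based heterotic assignment
#'
#' A line joins the group keyed to a tester when its SCA with that tester is
#' positive, its SCA with the other tester is negative, and its best
#' testcross mean is not significantly lower than the tester-by-tester check
#' cross (operationalized as best mean >= check mean - LSD).  Lines whose
#' largest absolute SCA falls below the per-trait magnitude floor, whose SCA
#' signs do not oppose, or that fail the mean condition stay unassigned.
#'
#' @param effects an [estimate_effects()] result.
#' @param means the matching [cell_means()] result.
#' @param check_mean mean of the tester x tester check cross.
#' @param lsd_value the [lsd()] statistic on the same trait scale.
#' @param config a [grouping_config()].
#' @param trait trait name (defaults to the effects table's trait); keys the
#'   magnitude floor.
#' @return object of class `heterotic_assignment`: data.frame with columns
#'   `line`, `group` (`HGA`/`HGB`/`unassigned`), effect values with each
#'   tester, testcross means, plus attributes `method`, `trait`,
#'   `check_mean`, `lsd`.
#' @export
assign_sca <- function(effects, means, check_mean, lsd_value, config,
                       trait = effects$trait) {
  stopifnot(inherits(effects, "effects_table"),
            inherits(means, "cross_means"))
  if (is.null(check_mean) || is.na(check_mean))
    stop("check_mean (tester x tester cross mean) is required")
  testers <- colnames(effects$sca)
  map <- resolve_tester_map(config, testers)
  t1 <- testers[1]; t2 <- testers[2]
  floor_mag <- min_mag(config, trait)
  lines <- rownames(effects$sca)
  s1 <- effects$sca[, t1]; s2 <- effects$sca[, t2]
  best <- pmax(means$cross_means[, t1], means$cross_means[, t2])
  mean_ok <- best >= check_mean - lsd_value
  group <- rep("unassigned", length(lines))
  big <- pmax(abs(s1), abs(s2)) >= floor_mag
  group[s1 > 0 & s2 < 0 & mean_ok & big] <- map[[t1]]
  group[s2 > 0 & s1 < 0 & mean_ok & big] <- map[[t2]]
  out <- data.frame(line = lines, group = group,
                    sca_t1 = s1, sca_t2 = s2,
                    mean_t1 = means$cross_means[, t1],
                    mean_t2 = means$cross_means[, t2],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[3:6] <- c(paste0("sca_", c(t1, t2)), paste0("mean_", c(t1, t2)))
  structure(out, method = "SCA", trait = trait, check_mean = check_mean,
            lsd = lsd_value, class = c("heterotic_assignment", "data.frame"))
}

#' HSGCA-based heterotic assignment
#'
#' A line with positive HSGCA with exactly one tester joins the group keyed
#' to that tester.  When HSGCA carries the same sign with both testers the
#' tie-break picks a tester by value (`min_value` default: the smaller,
#' i.e. the smallest positive or the most negative).  Every line is
#' assigned; an exact value tie falls to the first tester (logged via
#' attribute `ties`).
#'
#' @inheritParams assign_sca
#' @return a `heterotic_assignment` (see [assign_sca()]); every row
#'   assigned.
#' @export
assign_hsgca <- function(effects, config, trait = effects$trait) {
  stopifnot(inherits(effects, "effects_table"))
  testers <- colnames(effects$hsgca)
  if (length(testers) != 2)
    stop("HSGCA grouping is defined for exactly two testers; got ",
         length(testers))
  map <- resolve_tester_map(config, testers)
  t1 <- testers[1]; t2 <- testers[2]
  h1 <- effects$hsgca[, t1]; h2 <- effects$hsgca[, t2]
  lines <- rownames(effects$hsgca)
  pick <- character(length(lines))
  ties <- character(0)
  for (i in seq_along(lines)) {
    if (h1[i] > 0 && h2[i] <= 0) {
      pick[i] <- t1
    } else if (h2[i] > 0 && h1[i] <= 0) {
      pick[i] <- t2
    } else {
      if (h1[i] == h2[i]) ties <- c(ties, lines[i])
      smaller <- if (h1[i] <= h2[i]) t1 else t2
      pick[i] <- if (config$tie_break == "min_value") smaller
                 else setdiff(c(t1, t2), smaller)
    }
  }
  group <- unname(map[pick])
  out <- data.frame(line = lines, group = group,
                    h1 = h1, h2 = h2, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[3:4] <- paste0("hsgca_", c(t1, t2))
  structure(out, method = "HSGCA", trait = trait, ties = ties,
            class = c("heterotic_assignment", "data.frame"))
}

#' Concordance between grouping methods
#'
#' Pairwise Spearman rank correlation of per-line scores (default score: the
#' line's effect value with the first tester under each method) and pairwise
#' agreement percentage (share of lines given the same group label;
#' unassigned lines count as disagreements but stay in the denominator).
#' Spearman p-values are exact for n <= 10 (full null distribution) and
#' t-approximate otherwise.
#'
#' @param assignments named list of `heterotic_assignment` objects over the
#'   same line set.
#' @param scores optional named list (same names) of per-line numeric score
#'   vectors; default: each assignment's first effect column (SCA or HSGCA
#'   with tester 1).
#' @return object of class `concordance_report`: list with `rho`, `p`,
#'   `agreement_pct` (method x method matrices) and `n`.
#' @export
compare_methods <- function(assignments, scores = NULL) {
  stopifnot(is.list(assignments), length(assignments) >= 2)
  if (is.null(names(assignments)))
    names(assignments) <- paste0("method", seq_along(assignments))
  lines <- assignments[[1]]$line
  for (a in assignments) {
    if (!setequal(a$line, lines))
      stop("assignments cover different line sets")
  }
  if (is.null(scores)) {
    scores <- lapply(assignments, function(a) {
      v <- a[[3]]  # first effect column, tester-1 keyed
      stats::setNames(v, a$line)[lines]
    })
  } else {
    stopifnot(identical(names(scores), names(assignments)))
    scores <- lapply(scores, function(s) s[lines])
  }
  m <- length(assignments)
  nm <- names(assignments)
  rho <- p <- agree <- matrix(NA_real_, m, m, dimnames = list(nm, nm))
  n <- length(lines)
  for (i in seq_len(m)) {
    rho[i, i] <- 1; p[i, i] <- 0; agree[i, i] <- 100
    gi <- stats::setNames(assignments[[i]]$group, assignments[[i]]$line)[lines]
    for (j in seq_len(m)) {
      if (j <= i) next
      ct <- suppressWarnings(
        stats::cor.test(scores[[i]], scores[[j]], method = "spearman",
                        exact = n <= 10))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      gj <- stats::setNames(assignments[[j]]$group,
                            assignments[[j]]$line)[lines]
      same <- gi == gj & gi != "unassigned"
      agree[i, j] <- agree[j, i] <- 100 * sum(same) / n
    }
  }
  structure(list(rho = rho, p = p, agreement_pct = agree, n = n),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance over", x$n, "lines\nSpearman rho:\n")
  print(round(x$rho, 4))
  cat("agreement (%):\n")
  print(round(x$agreement_pct, 1))
  invisible(x)
}
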