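## Generators for line-by-tester trials and structured genotype panels with
## known ground truth.  Defaults emulate a 60-line x 2-tester testcross
## series evaluated in 8 environments with 2 replications, genotyped at
## ~2000 biallelic SNPs drawn from 3 latent subpopulations.

#' Simulation configuration
#'
#' Bundles every knob of the two generators.  Trait variance defaults are
#' moment estimates back-derived from a published combined line-by-tester
#' ANOVA of such a trial (see the methods vignette for the arithmetic);
#' marker defaults emulate a moderately differentiated (Fst = 0.3) panel of
#' near-inbred lines from 3 subpopulations.
#'
#' @param n_lines,n_testers,n_envs,n_reps trial dimensions.
#' @param traits named list; one element per trait, each a list with `mu`
#'   and the variance components `var_gca_line`, `var_gca_tester`,
#'   `var_sca`, `var_env`, `var_rep` (replicate within environment),
#'   `var_gxe` (shared by line x env, tester x env and line x tester x env)
#'   and `var_error`.
#' @param group_structure optional named character vector `line -> "HGA"/"HGB"`.
#'   When given, SCA effects are planted deterministically at
#'   `+sqrt(var_sca)` for line-tester pairs of opposite nominal groups and
#'   `-sqrt(var_sca)` otherwise (then re-centred), so grouping methods have
#'   a recoverable truth.
#' @param tester_groups nominal group of each tester itself; default: tester
#'   1 belongs to HGA, tester 2 to HGB, so lines combining well with tester
#'   1 are HGB lines.
#' @param n_markers,K,fst,admixture_alpha,het_rate,missing_rate marker-panel
#'   knobs: number of biallelic SNPs, latent subpopulations, Balding-Nichols
#'   differentiation, Dirichlet admixture concentration, probability that a
#'   truly heterozygous draw stays heterozygous (residual non-inbredness),
#'   and missing-call rate.
#' @param seed integer; fully determines both generators.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 60, n_testers = 2, n_envs = 8, n_reps = 2,
                       traits = list(
                         grain_yield = list(mu = 6100, var_gca_line = 2.5e5,
                                            var_gca_tester = 1.2e4,
                                            var_sca = 5.0e5, var_env = 3.0e6,
                                            var_rep = 0, var_gxe = 2.0e5,
                                            var_error = 1.14e6),
                         pva = list(mu = 12, var_gca_line = 1.26,
                                    var_gca_tester = 1.56, var_sca = 0.154,
                                    var_env = 3.8, var_rep = 0,
                                    var_gxe = 0.95, var_error = 1.36)),
                       group_structure = NULL,
                       tester_groups = NULL,
                       n_markers = 2000, K = 3, fst = 0.3,
                       admixture_alpha = 0.1, het_rate = 0.25,
                       missing_rate = 0.05, seed = 1) {
  stopifnot(n_lines >= 2, n_testers >= 2, n_envs >= 1, n_reps >= 1,
            n_markers >= 1, K >= 1, fst > 0, fst < 1,
            admixture_alpha > 0, het_rate >= 0, het_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  for (tr in names(traits)) {
    vv <- traits[[tr]]
    vv$var_rep <- vv$var_rep %||% 0
    if (any(unlist(vv[startsWith(names(vv), "var_")]) < 0))
      stop("negative variance in trait '", tr, "'")
    traits[[tr]] <- vv
  }
  testers <- paste0("T", seq_len(n_testers))
  if (is.null(tester_groups))
    tester_groups <- stats::setNames(rep(c("HGA", "HGB"),
                                         length.out = n_testers), testers)
  if (!is.null(group_structure)) {
    stopifnot(all(group_structure %in% c("HGA", "HGB")))
  }
  structure(list(n_lines = n_lines, n_testers = n_testers, n_envs = n_envs,
                 n_reps = n_reps, traits = traits,
                 group_structure = group_structure,
                 tester_groups = tester_groups,
                 n_markers = n_markers, K = K, fst = fst,
                 admixture_alpha = admixture_alpha, het_rate = het_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

line_ids <- function(n) sprintf("L%02d", seq_len(n))

#' Simulate a line-by-tester trial
#'
#' Plot model: `y = mu + env + rep(env) + gca_line + gca_tester + sca +
#' line:env + tester:env + line:tester:env + error`, every term i.i.d.
#' normal with its configured variance.  After sampling, each effect vector
#' is centred within its factor (SCA is double-centred), so the classical
#' zero-sum constraints hold exactly and the textbook GCA/SCA estimators are
#' exactly unbiased on the generated truth.  With `group_structure`, SCA is
#' planted at `+-sqrt(var_sca)` by group opposition instead of sampled.
#'
#' @param config a [sim_config()].
#' @return list with `trial` (a [trial_table]) and `truth` (per trait:
#'   `gca_line`, `gca_tester`, `sca` matrix lines x testers; plus `groups`
#'   when planted).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nl <- config$n_lines; nt <- config$n_testers
  ne <- config$n_envs; nr <- config$n_reps
  lines <- line_ids(nl)
  testers <- names(config$tester_groups)
  envs <- sprintf("E%02d", seq_len(ne))

  grid <- expand.grid(line = lines, tester = testers, env = envs,
                      rep = seq_len(nr), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  li <- match(grid$line, lines); ti <- match(grid$tester, testers)
  ei <- match(grid$env, envs); ri <- grid$rep

  truth <- list()
  for (tr in names(config$traits)) {
    v <- config$traits[[tr]]
    gl <- center(stats::rnorm(nl, 0, sqrt(v$var_gca_line)))
    gt <- center(stats::rnorm(nt, 0, sqrt(v$var_gca_tester)))
    if (!is.null(config$group_structure)) {
      gs <- config$group_structure[lines]
      if (any(is.na(gs))) stop("group_structure must cover every line")
      d <- sqrt(v$var_sca)
      opp <- outer(gs, config$tester_groups, "!=")
      sca <- ifelse(opp, d, -d)
    } else {
      sca <- matrix(stats::rnorm(nl * nt, 0, sqrt(v$var_sca)), nl, nt)
    }
    sca <- double_center(sca)
    dimnames(sca) <- list(lines, testers)
    env_eff <- center(stats::rnorm(ne, 0, sqrt(v$var_env)))
    rep_eff <- matrix(stats::rnorm(ne * nr, 0, sqrt(v$var_rep)), ne, nr)
    rep_eff <- rep_eff - rowMeans(rep_eff)
    le <- double_center(matrix(stats::rnorm(nl * ne, 0, sqrt(v$var_gxe)), nl, ne))
    te <- double_center(matrix(stats::rnorm(nt * ne, 0, sqrt(v$var_gxe)), nt, ne))
    lte <- array(stats::rnorm(nl * nt * ne, 0, sqrt(v$var_gxe)), c(nl, nt, ne))
    lte <- sweep(lte, c(2, 3), apply(lte, c(2, 3), mean))
    lte <- sweep(lte, c(1, 3), apply(lte, c(1, 3), mean))
    y <- v$mu + env_eff[ei] + rep_eff[cbind(ei, ri)] +
      gl[li] + gt[ti] + sca[cbind(li, ti)] +
      le[cbind(li, ei)] + te[cbind(ti, ei)] + lte[cbind(li, ti, ei)] +
      stats::rnorm(nrow(grid), 0, sqrt(v$var_error))
    grid[[tr]] <- y
    truth[[tr]] <- list(gca_line = stats::setNames(gl, lines),
                        gca_tester = stats::setNames(gt, testers),
                        sca = sca)
  }
  if (!is.null(config$group_structure))
    truth$groups <- config$group_structure[lines]
  list(trial = trial_table(grid, names(config$traits)), truth = truth)
}

center <- function(x) x - mean(x)

double_center <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m - rowMeans(m)
}

#' Simulate a structured genotype panel
#'
#' Balding-Nichols model: per marker an ancestral frequency
#' `p ~ U(0.05, 0.95)`; subpopulation frequencies
#' `~ Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`; per sample admixture
#' proportions `~ Dirichlet(alpha, ..., alpha)`; genotype = two binomial
#' allele draws from the sample's mixed frequency.  Heterozygous draws then
#' collapse to a random homozygote with probability `1 - het_rate`
#' (mimicking inbreds), and calls are masked missing at `missing_rate`.
#' Samples are the `n_lines` lines plus the testers (testers drawn from
#' subpopulations 1 and 2 with near-pure ancestry).
#'
#' @param config a [sim_config()].
#' @return list with `geno` (a [genotype_matrix]) and `truth` (list with
#'   `Q` samples x K admixture proportions, `F` K x markers subpopulation
#'   frequencies, `pop` = per-sample argmax ancestry).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  K <- config$K; m <- config$n_markers
  samples <- c(line_ids(config$n_lines), names(config$tester_groups))
  n <- length(samples)

  p_anc <- stats::runif(m, 0.05, 0.95)
  if (K > 1) {
    shp1 <- p_anc * (1 - config$fst) / config$fst
    shp2 <- (1 - p_anc) * (1 - config$fst) / config$fst
    F <- t(vapply(seq_len(K),
                  function(k) stats::rbeta(m, shp1, shp2),
                  numeric(m)))
  } else {
    F <- matrix(p_anc, 1, m)
  }

  Q <- rdirichlet(n, rep(config$admixture_alpha, K))
  # testers anchor subpopulations 1 and 2 with near-pure ancestry
  nt <- config$n_testers
  for (i in seq_len(nt)) {
    k <- ((i - 1) %% K) + 1
    q <- rep(0.01 / max(K - 1, 1), K); q[k] <- 1 - sum(q[-k])
    Q[config$n_lines + i, ] <- q
  }

  pi_mat <- Q %*% F                      # n x m mixed alt frequencies
  calls <- matrix(stats::rbinom(n * m, 2L, pi_mat), n, m)
  het <- calls == 1L
  collapse <- het & (stats::runif(n * m) > config$het_rate)
  calls[collapse] <- 2L * stats::rbinom(sum(collapse), 1L, 0.5)
  if (config$missing_rate > 0)
    calls[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  dimnames(calls) <- list(samples, sprintf("M%04d", seq_len(m)))
  markers <- data.frame(marker_id = colnames(calls),
                        chrom = as.character(((seq_len(m) - 1) %% 10) + 1),
                        pos = as.integer(seq_len(m) * 1000L),
                        stringsAsFactors = FALSE)
  rownames(Q) <- samples
  list(geno = genotype_matrix(calls, markers),
       truth = list(Q = Q, F = F,
                    pop = stats::setNames(max.col(Q), samples)))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}
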