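# In-code fixtures shared across test files.  Everything is generated at
# test time; no binary data.

# 3 lines x 2 testers, one observation per cross:
#   T1  T2
# L1 10   8
# L2 12   6
# L3  8  10
spec_trial <- function() {
  trial_table(data.frame(
    line = rep(c("L1", "L2", "L3"), each = 2),
    tester = rep(c("T1", "T2"), 3),
    env = "E1", rep = 1L,
    y = c(10, 8, 12, 6, 8, 10)), traits = "y")
}

# effects_table with chosen values (bypasses estimation; our own S3 class)
make_effects <- function(sca, hsgca = NULL, gca_line = NULL, trait = "pva") {
  lines <- rownames(sca)
  testers <- colnames(sca)
  if (is.null(gca_line))
    gca_line <- stats::setNames(rep(0, length(lines)), lines)
  if (is.null(hsgca)) hsgca <- sca + gca_line
  structure(list(trait = trait, gca_line = gca_line,
                 gca_tester = stats::setNames(rep(0, length(testers)),
                                              testers),
                 sca = sca, hsgca = hsgca,
                 se = c(gca_line = NA, gca_tester = NA, sca = NA)),
            class = "effects_table")
}

# minimal cross_means consistent with a cross-mean matrix
make_means <- function(cm, trait = "pva") {
  structure(list(overall_mean = mean(cm), line_means = rowMeans(cm),
                 tester_means = colMeans(cm), cross_means = cm,
                 n_obs = matrix(1, nrow(cm), ncol(cm)),
                 check_means = NULL, trait = trait),
            class = "cross_means")
}

# genotype matrix from a plain dosage matrix
make_geno <- function(calls) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("M%03d", seq_len(ncol(calls)))
  genotype_matrix(calls)
}

# tiny VCF written to a temp file
write_test_vcf <- function(records) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    records), path)
  path
}

vcf_rec <- function(pos, id, alt, gts)
  paste("1", pos, id, "A", alt, ".", ".", ".", "GT",
        paste(gts, collapse = "\t"), sep = "\t")

# best label-permutation accuracy of predicted vs true cluster labels;
# preds may contain "mixed" (always counted wrong)
perm_accuracy <- function(pred, truth, K) {
  perms <- perms_of(seq_len(K))
  best <- 0
  for (p in perms) {
    mapped <- rep(NA_integer_, length(pred))
    ok <- pred != "mixed"
    mapped[ok] <- p[as.integer(pred[ok])]
    best <- max(best, mean(!is.na(mapped) & mapped == truth))
  }
  best
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# exhaustive minimum within-cluster sum of squares over all partitions of
# n items into exactly K non-empty clusters, from a distance matrix
# (within-SS of a cluster = sum of squared pairwise distances / size)
brute_force_wss <- function(D, K) {
  n <- nrow(D)
  d2 <- D^2
  wss <- function(part) {
    s <- 0
    for (g in unique(part)) {
      idx <- which(part == g)
      if (length(idx) > 1) {
        m <- d2[idx, idx]
        s <- s + sum(m[upper.tri(m)]) / length(idx)
      }
    }
    s
  }
  best <- Inf
  rec <- function(assign, maxg) {
    i <- length(assign) + 1
    if (i > n) {
      if (length(unique(assign)) == K) best <<- min(best, wss(assign))
      return()
    }
    for (g in seq_len(min(maxg + 1, K))) rec(c(assign, g), max(maxg, g))
  }
  rec(integer(0), 0L)
  list(min_wss = best, wss = wss)
}
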