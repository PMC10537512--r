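## Readers/writers and the two core containers shared by every other module:
## a plot-level testcross trial table and a dosage-coded genotype matrix.

#' Construct a trial table
#'
#' Plot-level container for a line-by-tester testcross trial.  One row per
#' plot observation with the design factors (`line`, `tester`, `env`, `rep`,
#' optional `block`) and one numeric column per trait.  The cross between the
#' two testers (the check hybrid) is representable as a row whose `line`
#' equals a tester id; such rows are flagged `is_check` and excluded from the
#' line set and from combining-ability analyses, but their means remain
#' available as the grouping check.
#'
#' @param data data.frame with columns `line`, `tester`, `env`, `rep`,
#'   optionally `block`, plus one numeric column per trait.  Missing trait
#'   values are `NA`, never zero.
#' @param traits character vector naming the trait columns.
#' @return An object of class `trial_table`: a list with elements `data`
#'   (the validated data.frame, with an added logical `is_check`), `traits`,
#'   `lines`, `testers`, and `design = c(n_lines, n_testers, n_envs, n_reps)`.
#' @export
trial_table <- function(data, traits) {
  stopifnot(is.data.frame(data), is.character(traits), length(traits) >= 1)
  needed <- c("line", "tester", "env", "rep")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0)
    stop("trial table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(traits, names(data))
  if (length(miss) > 0)
    stop("trait column(s) not present: ", paste(miss, collapse = ", "))
  data$line <- as.character(data$line)
  data$tester <- as.character(data$tester)
  data$env <- as.character(data$env)
  data$rep <- as.integer(data$rep)
  if (any(is.na(data$rep)) || any(data$rep < 1))
    stop("'rep' must be a positive integer for every record")
  if (!"block" %in% names(data)) data$block <- NA_character_
  for (tr in traits) {
    if (!is.numeric(data[[tr]]))
      stop("trait column '", tr, "' is not numeric")
    if (any(is.infinite(data[[tr]])))
      stop("trait column '", tr, "' contains non-finite values")
  }
  key <- paste(data$line, data$tester, data$env, data$rep, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate plot key (line/tester/env/rep): ", dup)
  }
  testers <- sort(unique(data$tester))
  data$is_check <- data$line %in% testers
  lines <- sort(unique(data$line[!data$is_check]))
  noncheck <- data[!data$is_check, , drop = FALSE]
  design <- c(n_lines = length(lines),
              n_testers = length(testers),
              n_envs = length(unique(noncheck$env)),
              n_reps = max(noncheck$rep))
  structure(list(data = data, traits = traits, lines = lines,
                 testers = testers, design = design),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  d <- x$design
  cat(sprintf("trial_table: %d plots | %d lines x %d testers x %d envs x %d reps\n",
              nrow(x$data), d[1], d[2], d[3], d[4]))
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  if (any(x$data$is_check))
    cat("check-hybrid plots:", sum(x$data$is_check), "\n")
  invisible(x)
}

#' Read a plot-level testcross trial from CSV
#'
#' Long-format CSV, one row per plot.  Mandatory columns `line`, `tester`,
#' `env`, `rep` (renameable through `schema`) plus at least one trait
#' column; every column not claimed by the design is treated as a trait.
#' Empty trait cells become missing values (`NA`), never zeros; non-numeric
#' trait cells and duplicate plot keys are hard errors.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping standard names
#'   (`line`, `tester`, `env`, `rep`, `block`) to the file's column names;
#'   defaults to the identity mapping.
#' @param traits optional character vector of trait column names; default:
#'   every non-design column.
#' @return A [trial_table].
#' @export
read_trial_csv <- function(path, schema = NULL, traits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("NA", ""))
  std <- c("line", "tester", "env", "rep", "block")
  map <- stats::setNames(std, std)
  if (!is.null(schema)) map[names(schema)] <- unname(schema)
  for (s in setdiff(std, "block")) {
    if (!map[[s]] %in% names(raw))
      stop("mandatory column '", map[[s]], "' (", s, ") not found in ", path)
  }
  out <- data.frame(line = raw[[map[["line"]]]],
                    tester = raw[[map[["tester"]]]],
                    env = raw[[map[["env"]]]],
                    rep = raw[[map[["rep"]]]],
                    stringsAsFactors = FALSE)
  if (map[["block"]] %in% names(raw)) out$block <- raw[[map[["block"]]]]
  if (is.null(traits))
    traits <- setdiff(names(raw), intersect(unname(map), names(raw)))
  if (length(traits) < 1)
    stop("no trait columns found in ", path)
  for (tr in traits) {
    v <- raw[[tr]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0)
      stop("non-numeric value '", v[bad[1]], "' in trait column '", tr,
           "', data row ", bad[1])
    out[[tr]] <- num
  }
  trial_table(out, traits)
}

#' Construct a genotype matrix
#'
#' Biallelic SNP calls coded as alternate-allele dosage: 0, 1, 2 or `NA`
#' (missing).  Samples in rows, markers in columns.
#'
#' @param calls integer matrix, samples x markers, entries in `{0, 1, 2, NA}`,
#'   with sample ids as rownames and marker ids as colnames.
#' @param markers optional data.frame with columns `marker_id`, `chrom`,
#'   `pos` (1-based); defaults to unknown coordinates.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers = NULL) {
  stopifnot(is.matrix(calls))
  # R normalizes zero-length dimname components to NULL, so an empty
  # (all-filtered) matrix is legal without colnames
  if (is.null(rownames(calls)) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("calls must carry sample rownames and marker colnames")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids")
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid call '", calls[idx[1], idx[2]], "' at sample ",
         rownames(calls)[idx[1]], ", marker ", colnames(calls)[idx[2]],
         " (must be 0, 1, 2 or NA)")
  }
  storage.mode(calls) <- "integer"
  ids <- colnames(calls) %||% character(0)
  if (is.null(markers)) {
    markers <- data.frame(marker_id = ids,
                          chrom = rep(NA_character_, ncol(calls)),
                          pos = rep(NA_integer_, ncol(calls)),
                          stringsAsFactors = FALSE)
  }
  stopifnot(identical(markers$marker_id, ids))
  if (any(!is.na(markers$pos) & markers$pos < 0))
    stop("marker positions must be non-negative")
  structure(list(calls = calls, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read biallelic SNP genotypes
#'
#' Two dialects.  `"matrix"`: CSV with sample ids in the first column,
#' marker ids in the header, cells in `{0, 1, 2, NA}` (alternate-allele
#' dosage).  `"vcf"`: VCF v4.x, GT field; diploid calls are mapped to
#' alternate-allele dosage, half-missing calls (e.g. `./1`) to missing, and
#' multi-allelic records are skipped with a reported count.
#'
#' @param path path to the genotype file.
#' @param dialect `"matrix"` or `"vcf"`.
#' @return A [genotype_matrix].  For VCF input the number of skipped
#'   multi-allelic records is attached as attribute `n_skipped_multiallelic`
#'   and reported via `message()`.
#' @export
read_genotypes <- function(path, dialect = c("matrix", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "matrix") read_genotypes_matrix(path) else read_genotypes_vcf(path)
}

read_genotypes_matrix <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop("matrix-csv needs a sample column plus markers")
  samples <- raw[[1]]
  markers <- names(raw)[-1]
  calls <- matrix(NA_integer_, nrow(raw), length(markers),
                  dimnames = list(samples, markers))
  for (j in seq_along(markers)) {
    v <- raw[[j + 1]]
    num <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(num) | !num %in% 0:2))
    if (length(bad) > 0)
      stop("unparseable genotype '", v[bad[1]], "' at sample ",
           samples[bad[1]], ", marker ", markers[j])
    calls[, j] <- num
  }
  genotype_matrix(calls)
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  keep <- n_alt == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_genotypes: skipped ", n_skip, " multi-allelic record(s)")
  vcf <- vcf[keep, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  dose <- apply(gt, c(1, 2), gt_to_dosage)
  calls <- t(dose)  # samples x markers
  markers <- data.frame(marker_id = rownames(gt),
                        chrom = as.character(GenomeInfoDb::seqnames(rr)),
                        pos = BiocGenerics::start(rr),
                        stringsAsFactors = FALSE)
  colnames(calls) <- markers$marker_id
  genotype_matrix(calls, markers)
}

# "0/1", "0|1", "./." -> dosage; any half-missing or non-diploid -> NA/error
gt_to_dosage <- function(g) {
  if (is.na(g) || g == ".") return(NA_integer_)
  al <- strsplit(g, "[/|]")[[1]]
  if (length(al) != 2L)
    stop("non-diploid GT '", g, "'")
  if (any(al == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(al))
  if (any(is.na(a)) || any(!a %in% 0:1))
    stop("unparseable GT allele in '", g, "'")
  sum(a)
}

#' Grain yield adjusted to 15% moisture
#'
#' Converts plot fresh grain weight and harvest moisture to yield in kg/ha
#' on a 15%-moisture basis:
#' `yield = fresh_weight_kg * (100 - moisture_pct) / 85 * 10000 / plot_area_m2`.
#' At exactly 15% moisture the adjustment is the identity.  The shelling /
#' plot-factor convention is this formula itself; it is recorded in the
#' run-log metadata of [run_pipeline()].
#'
#' @param fresh_weight_kg plot grain weight at harvest, kg.
#' @param moisture_pct grain moisture at harvest, percent, in `[0, 100)`.
#' @param plot_area_m2 harvested plot area, m2.  Default 3.75 (a single
#'   5 m row at 0.75 m spacing).
#' @return yield in kg/ha (vectorized).
#' @export
compute_grain_yield <- function(fresh_weight_kg, moisture_pct,
                                plot_area_m2 = 3.75) {
  if (any(!is.finite(fresh_weight_kg)) || any(!is.finite(moisture_pct)) ||
      any(!is.finite(plot_area_m2)))
    stop("inputs must be finite")
  if (any(moisture_pct < 0) || any(moisture_pct >= 100))
    stop("moisture_pct must lie in [0, 100)")
  if (any(plot_area_m2 <= 0)) stop("plot_area_m2 must be positive")
  fresh_weight_kg * (100 - moisture_pct) / 85 * 10000 / plot_area_m2
}

#' Export a dendrogram as a newick string
#'
#' Accepts an `hclust` merge tree (as produced by [ward_cluster()]) and
#' returns a newick string in which leaf-to-root path lengths equal the
#' merge heights (ultrametric).  Leaf names round-trip through
#' [ape::read.tree()].
#'
#' @param tree an `hclust` object, or a single leaf label for the trivial
#'   one-sample tree.
#' @return a newick string (terminated by `;`).
#' @export
write_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L)
    return(paste0(tree, ";"))
  if (inherits(tree, "ward_cluster")) tree <- tree$hclust
  if (!inherits(tree, "hclust"))
    stop("tree must be an hclust object (or a single leaf name)")
  phy <- ape::as.phylo(tree)
  # as.phylo.hclust halves merge heights; restore them so a two-leaf tree
  # merged at h exports as (A:h,B:h);
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy)
}
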