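# Exact binomial diagnostics for 2x2 count tables.

as_2x2 <- function(m) {
  if (is.matrix(m) && all(dim(m) == c(2L, 2L))) {
    if (any(m < 0) || any(m != round(m)))
      stop("counts must be nonnegative integers", call. = FALSE)
    if (sum(m) == 0) stop("table total must be > 0", call. = FALSE)
    return(m)
  }
  stop("expected a 2x2 count matrix", call. = FALSE)
}

#' Contingency counts for a two-by-two table
#'
#' Fixed layout: rows are the first classifier (+ then -), columns the
#' second (+ then -).  For diagnostic metrics the rows are the test and
#' the columns the condition, so `a` = TP, `b` = FP, `c` = FN, `d` = TN;
#' for agreement statistics the two axes are the two raters.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return a 2x2 integer matrix with informative dimnames.
#' @examples
#' contingency_counts(21, 3, 4, 55)
#' @export
contingency_counts <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2L,
              dimnames = list(first = c("+", "-"), second = c("+", "-")))
  as_2x2(m)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The "exact" interval from Beta quantiles: `lo = qbeta(alpha/2, k,
#' n-k+1)` (0 when k = 0) and `hi = qbeta(1-alpha/2, k+1, n-k)` (1 when
#' k = n).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(lo, hi)`.
#' @examples
#' round(clopper_pearson(18, 20), 3)  # 0.683 0.988
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L || length(n) != 1L ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  check_scalar(conf, "conf", lower = 0, upper = 1, strict_lower = TRUE)
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Diagnostic test metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive values from
#' a 2x2 table (rows = test +/-, columns = condition +/-), each with its
#' exact Clopper-Pearson interval.  A metric whose denominator is zero is
#' reported as NA rather than raising an error.
#'
#' @param table a 2x2 count matrix (e.g. from [contingency_counts()]), so
#'   `table[1,1]` = TP, `table[1,2]` = FP, `table[2,1]` = FN, `table[2,2]`
#'   = TN.
#' @param conf confidence level for the intervals.
#' @return object of class `diagnostic_metrics`: a data frame with one row
#'   per metric (`estimate`, `lo`, `hi`, `k`, `n`).
#' @examples
#' diagnostic_metrics(contingency_counts(26, 2, 37, 18))
#' @export
diagnostic_metrics <- function(table, conf = 0.95) {
  m <- as_2x2(table)
  tp <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]
  one <- function(k, n) {
    if (n == 0) return(c(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                         k = k, n = n))
    ci <- clopper_pearson(k, n, conf)
    c(estimate = k / n, lo = unname(ci["lo"]), hi = unname(ci["hi"]),
      k = k, n = n)
  }
  out <- rbind(sensitivity = one(tp, tp + fn),
               specificity = one(tn, tn + fp),
               ppv = one(tp, tp + fp),
               npv = one(tn, tn + fn))
  structure(as.data.frame(out), conf = conf, class = c("diagnostic_metrics",
                                                       "data.frame"))
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  conf <- attr(x, "conf")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("%-12s undefined (zero denominator)\n", rownames(x)[i]))
    } else {
      cat(sprintf("%-12s %s (%d/%d) (%d%% CI: %s to %s)\n", rownames(x)[i],
                  format_percent(x$estimate[i]), x$k[i], x$n[i],
                  round(100 * conf), format_percent(x$lo[i]),
                  format_percent(x$hi[i])))
    }
  }
  invisible(x)
}

#' Cohen's unweighted kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = (a + d) / N` and chance agreement from the
#' table margins.  Degenerate margins (`p_e = 1`) yield NA.
#'
#' @param table a 2x2 count matrix (rows = rater 1 +/-, columns = rater 2
#'   +/-).
#' @return the kappa statistic (scalar).
#' @examples
#' round(cohen_kappa(contingency_counts(21, 3, 4, 55)), 3)  # 0.797
#' @export
cohen_kappa <- function(table) {
  m <- as_2x2(table)
  n <- sum(m)
  po <- (m[1, 1] + m[2, 2]) / n
  pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
  if (1 - pe == 0) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Raw agreement rate of a 2x2 table
#'
#' Proportion of concordant cases, `(a + d) / N`.
#'
#' @param table a 2x2 count matrix.
#' @return the agreement proportion.
#' @examples
#' agreement_rate(contingency_counts(21, 3, 4, 55))  # 76/83
#' @export
agreement_rate <- function(table) {
  m <- as_2x2(table)
  (m[1, 1] + m[2, 2]) / sum(m)
}

#' Published case-count tables of the carotid bruit study
#'
#' Loads the packaged count tables of the 96-artery auscultation study:
#' `stenosis` cross-tabulates the HR/RBS/HPF detection pattern against the
#' degree of occlusion, `plaque` against the presence of atherosclerotic
#' plaque on CT angiography.  Helper columns/derivations used throughout
#' the statistics: a case is bruit-positive when at least one of RBS and
#' HPF is positive.
#'
#' @return list with data frames `stenosis` and `plaque`, plus derived
#'   2x2 matrices: `rbs_vs_hpf` (agreement among HR-positive cases) and
#'   `bruit_vs_plaque` (test = bruit detection, condition = plaque, among
#'   HR-positive cases).
#' @export
carotid_study_tables <- function() {
  ext <- system.file("extdata", package = "ballsift")
  stenosis <- read.csv(file.path(ext, "table1_stenosis.csv"),
                       stringsAsFactors = FALSE)
  plaque <- read.csv(file.path(ext, "table2_plaque.csv"),
                     stringsAsFactors = FALSE)
  hrpos <- plaque[plaque$hr == "+", ]
  tot <- function(df) df$absence + df$presence
  cell <- function(df, rbs, hpf) sum(tot(df)[df$rbs == rbs & df$hpf == hpf])
  rbs_vs_hpf <- contingency_counts(cell(hrpos, "+", "+"),
                                   cell(hrpos, "+", "-"),
                                   cell(hrpos, "-", "+"),
                                   cell(hrpos, "-", "-"))
  bruit_pos <- hrpos$rbs == "+" | hrpos$hpf == "+"
  bruit_vs_plaque <- contingency_counts(sum(hrpos$presence[bruit_pos]),
                                        sum(hrpos$absence[bruit_pos]),
                                        sum(hrpos$presence[!bruit_pos]),
                                        sum(hrpos$absence[!bruit_pos]))
  list(stenosis = stenosis, plaque = plaque, rbs_vs_hpf = rbs_vs_hpf,
       bruit_vs_plaque = bruit_vs_plaque)
}
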