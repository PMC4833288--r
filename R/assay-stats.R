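#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' Interval used for per-plate fractions such as "percent fertile adults":
#' \eqn{\hat p \pm z \sqrt{\hat p (1-\hat p)/n}}, clipped to \[0, 1\].
#' A Wilson score interval is available via `method = "wilson"` for users who
#' want better small-n behaviour; the Wald form is the default.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return An object of class `proportion_ci`: a list with `k`, `n`, `level`,
#'   `p_hat`, `half_width`, `lower`, `upper`, `method`.
#' @examples
#' proportion_ci(50, 100)
#' @export
proportion_ci <- function(k, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("k must be a nonnegative integer")
  }
  if (k > n) stop("k > n: more successes than trials")
  if (!is.numeric(level) || level <= 0 || level >= 1) stop("level must be in (0,1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  if (method == "wald") {
    hw <- z * sqrt(p_hat * (1 - p_hat) / n)
    lower <- max(0, p_hat - hw)
    upper <- min(1, p_hat + hw)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p_hat + z^2 / (2 * n)) / denom
    hw <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, centre - hw)
    upper <- min(1, centre + hw)
  }
  structure(
    list(k = k, n = n, level = level, p_hat = p_hat,
         half_width = hw, lower = lower, upper = upper, method = method),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f, %g%% %s CI [%.4f, %.4f]\n",
              x$k, x$n, x$p_hat, 100 * x$level, x$method, x$lower, x$upper))
  invisible(x)
}

#' Welch (unequal-variance) two-sample t-test
#'
#' Two-sided Welch t-test with the Satterthwaite degrees of freedom, as used
#' for worm-length comparisons between genotype/condition groups. Unlike
#' [stats::t.test()], degenerate data are handled by convention: if both
#' samples have zero variance and equal means the test reports `t = 0`,
#' `p = 1`; zero variance with unequal means reports `p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `diff` (a - b).
#' @examples
#' welch_t(c(1, 2, 3), c(11, 12, 13))$p
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) {
      return(list(t = 0, df = na + nb - 2, p = 1,
                  mean_a = ma, mean_b = mb, diff = ma - mb))
    }
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0,
                mean_a = ma, mean_b = mb, diff = ma - mb))
  }
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean_a = ma, mean_b = mb, diff = ma - mb)
}

#' Annotate a single codon change
#'
#' Translates a reference and an alternate codon and classifies the amino-acid
#' change. Stop codons are written `STOP` in labels (e.g. `W83STOP`), matching
#' the compact genetics notation used for allele tables.
#'
#' @param ref_codon,alt_codon Length-3 DNA codons.
#' @param position 1-based residue index.
#' @param code Genetic code (see [genetic_code()]).
#' @return List with `from_aa`, `position`, `to_aa` (one-letter or `"STOP"`),
#'   `label` (e.g. `"D282N"`) and `category` in
#'   `missense`/`nonsense`/`silent`/`readthrough`.
#' @examples
#' annotate_codon_change("GAT", "AAT", 282)$label  # "D282N"
#' @export
annotate_codon_change <- function(ref_codon, alt_codon, position,
                                  code = genetic_code()) {
  if (!is.numeric(position) || length(position) != 1L || position < 1 ||
      position != round(position)) {
    stop("position must be a positive integer")
  }
  from <- translate_codon(ref_codon, code)
  to <- translate_codon(alt_codon, code)
  from_lab <- if (from == "*") "STOP" else from
  to_lab <- if (to == "*") "STOP" else to
  category <- if (from == to) {
    "silent"
  } else if (to == "*") {
    "nonsense"
  } else if (from == "*") {
    "readthrough"
  } else {
    "missense"
  }
  list(from_aa = from_lab, position = as.integer(position), to_aa = to_lab,
       label = paste0(from_lab, position, to_lab), category = category)
}

#' Annotate a table of allele records
#'
#' Applies [annotate_codon_change()] to every allele record (see
#' [load_allele_fixture()]) and returns the records with the derived label and
#' mutation category appended.
#'
#' @param records Data frame of allele records with columns `gene`, `allele`,
#'   `ref_codon`, `alt_codon`, `position`.
#' @param code Genetic code.
#' @return The input data frame with columns `label` and `category` added.
#' @export
annotate_allele_table <- function(records, code = genetic_code()) {
  if (nrow(records) == 0L) {
    records$label <- character(0)
    records$category <- character(0)
    return(records)
  }
  ann <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      annotate_codon_change(records$ref_codon[i], records$alt_codon[i],
                            records$position[i], code),
      error = function(e) {
        stop(sprintf("record %s(%s): %s", records$gene[i], records$allele[i],
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
  records$label <- vapply(ann, `[[`, "", "label")
  records$category <- vapply(ann, `[[`, "", "category")
  records
}
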