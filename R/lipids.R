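#' Quantify lipid amounts from raw intensities
#'
#' Single-point internal-standard scaling: within each lipid class every
#' species amount is `intensity / is_intensity * is_amount`, where the
#' internal-standard intensity and amount must be constant within a sample
#' and class. Amounts are then renormalized to mol% of the class total, so
#' the result is invariant to any overall intensity scale.
#'
#' @param records Data frame with columns `sample_id`, `condition`,
#'   `lipid_class`, `carbons`, `double_bonds`, `intensity`, `is_intensity`,
#'   `is_amount` (see [read_lipid_table()]).
#' @return Data frame in mol% dialect (`mol_percent` column), closure holding
#'   per sample and class.
#' @export
quantify_from_intensities <- function(records) {
  needed <- c("sample_id", "condition", "lipid_class", "carbons",
              "double_bonds", "intensity", "is_intensity", "is_amount")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(records$intensity)) || any(records$intensity <= 0)) {
    stop("intensities must be positive")
  }
  if (any(is.na(records$is_intensity)) || any(records$is_intensity <= 0) ||
      any(is.na(records$is_amount)) || any(records$is_amount <= 0)) {
    stop("missing or non-positive internal standard for some class")
  }
  key <- interaction(records$sample_id, records$lipid_class, drop = TRUE)
  one_is <- tapply(records$is_intensity, key, function(v) length(unique(v)) == 1L)
  if (!all(one_is)) {
    stop("internal-standard intensity must be unique per sample and class")
  }
  amount <- records$intensity / records$is_intensity * records$is_amount
  class_total <- tapply(amount, key, sum)[key]
  out <- records[c("sample_id", "condition", "lipid_class", "carbons",
                   "double_bonds")]
  out$mol_percent <- 100 * amount / as.numeric(class_total)
  attr(out, "mode") <- "mol_percent"
  out
}

#' Saturation summary of a composition profile
#'
#' Per lipid class: the mol% of saturated (0 double bonds), monounsaturated
#' (1) and polyunsaturated (>= 2) fatty acids, and the mean number of double
#' bonds per fatty acid (sum of mol% x double bonds / 100).
#'
#' @param profile Data frame in mol% dialect for one or more samples.
#' @return Data frame with one row per (sample_id, condition, lipid_class)
#'   and columns `sfa`, `mufa`, `pufa`, `mean_db`.
#' @export
saturation_summary <- function(profile) {
  needed <- c("sample_id", "lipid_class", "double_bonds", "mol_percent")
  missing <- setdiff(needed, names(profile))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"condition" %in% names(profile)) profile$condition <- NA_character_
  validate_lipid_closure(profile)
  split_key <- interaction(profile$sample_id, profile$lipid_class, drop = TRUE)
  rows <- lapply(split(profile, split_key), function(d) {
    data.frame(
      sample_id = d$sample_id[1],
      condition = d$condition[1],
      lipid_class = d$lipid_class[1],
      sfa = sum(d$mol_percent[d$double_bonds == 0]),
      mufa = sum(d$mol_percent[d$double_bonds == 1]),
      pufa = sum(d$mol_percent[d$double_bonds >= 2]),
      mean_db = sum(d$mol_percent * d$double_bonds) / 100,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$lipid_class), ]
}

#' Contrast fatty-acid saturation between two conditions
#'
#' Computes per-sample SFA mol% via [saturation_summary()] and tests the
#' group difference per lipid class with a Welch t-test.
#'
#' @param profiles Data frame in mol% dialect covering both groups.
#' @param contrast Length-2 character vector `c(treated, reference)`; the
#'   reported difference is treated minus reference.
#' @return Object of class `lipid_contrast`: data frame with one row per
#'   lipid class (`mean_a`, `mean_b`, `difference`, `t`, `df`, `p`, group
#'   sizes).
#' @export
compare_conditions <- function(profiles, contrast) {
  stopifnot(length(contrast) == 2L)
  summ <- saturation_summary(profiles)
  summ <- summ[summ$condition %in% contrast, ]
  if (nrow(summ) == 0) stop("no samples match the contrast conditions")
  rows <- lapply(split(summ, summ$lipid_class), function(d) {
    a <- d$sfa[d$condition == contrast[1]]
    b <- d$sfa[d$condition == contrast[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop(sprintf("class %s: each group needs >= 2 samples", d$lipid_class[1]))
    }
    w <- welch_t(a, b)
    data.frame(lipid_class = d$lipid_class[1],
               condition_a = contrast[1], condition_b = contrast[2],
               n_a = length(a), n_b = length(b),
               mean_a = w$mean_a, mean_b = w$mean_b, difference = w$diff,
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, metric = "sfa"), class = "lipid_contrast")
}

#' @export
print.lipid_contrast <- function(x, ...) {
  cat(sprintf("SFA mol%% contrast (%s - %s):\n",
              x$table$condition_a[1], x$table$condition_b[1]))
  print(x$table[, c("lipid_class", "mean_a", "mean_b", "difference", "p")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
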