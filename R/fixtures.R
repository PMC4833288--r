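#' Legal mosaic scoring symbols
#'
#' The graded tissue-scoring alphabet, ordered from fully negative to fully
#' positive. `"+/-"` means the majority of the tissue carried the transgene
#' marker, `"-/+"` that only a minority did. The ordinal ranks 0..3 underpin
#' the mismatch penalties used by [infer_losses()].
#'
#' @return Character vector `c("-", "-/+", "+/-", "+")`.
#' @export
mosaic_calls <- function() c("-", "-/+", "+/-", "+")

call_rank <- function(calls) {
  r <- match(calls, mosaic_calls()) - 1L
  if (anyNA(r)) stop("illegal mosaic call symbol: ",
                     paste(unique(calls[is.na(r)]), collapse = ", "))
  r
}

# format numerics so that write/read round-trips are exact at double precision
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA
  out
}

check_columns <- function(df, required, numeric_cols, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) & !anyNA(df[[col]])) {
      stop(sprintf("%s: non-numeric value in numeric column '%s'", path, col))
    }
    df[[col]] <- v
  }
  df
}

# ---- allele records (compact genetics notation) -----------------------------

parse_mutation_notation <- function(s) {
  m <- regmatches(s, regexec(
    "^(STOP|[A-Z])\\(([ACGT]{3})\\)([0-9]+)(STOP|[A-Z])\\(([ACGT]{3})\\)$", s))[[1]]
  if (length(m) != 6L) {
    stop(sprintf("malformed mutation notation: '%s'", s), call. = FALSE)
  }
  list(ref_codon = m[3], alt_codon = m[6], position = as.integer(m[4]))
}

#' Load the packaged mutant-allele table
#'
#' Reads the packaged table of five EMS-induced alleles (two in *paqr-2*,
#' three in *iglr-2*) recorded in compact `X(COD)posY(COD)` notation, and
#' expands the notation into reference codon, alternate codon and residue
#' position.
#'
#' @param path Path to the allele CSV; defaults to the packaged fixture.
#' @return Data frame with columns `gene`, `allele`, `orf_name`, `orf_length`,
#'   `ref_codon`, `alt_codon`, `position`.
#' @examples
#' alleles <- load_allele_fixture()
#' nrow(alleles)  # 5
#' @export
load_allele_fixture <- function(path = system.file("extdata", "table1_alleles.csv",
                                                   package = "memfluid")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("gene", "allele", "orf_name", "orf_length", "mutation"),
                      "orf_length", path)
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_mutation_notation(df$mutation[i]),
             error = function(e) stop(sprintf(
               "record %s(%s): %s", df$gene[i], df$allele[i],
               conditionMessage(e)), call. = FALSE))
  })
  out <- data.frame(
    gene = df$gene, allele = df$allele, orf_name = df$orf_name,
    orf_length = as.integer(df$orf_length),
    ref_codon = vapply(parsed, `[[`, "", "ref_codon"),
    alt_codon = vapply(parsed, `[[`, "", "alt_codon"),
    position = vapply(parsed, `[[`, 1L, "position"),
    stringsAsFactors = FALSE
  )
  bad <- out$position < 1L | out$position > out$orf_length
  if (any(bad)) {
    stop("residue position outside ORF for record(s): ",
         paste(out$allele[bad], collapse = ", "))
  }
  out
}

#' Read / write an expanded allele table
#'
#' Plain-CSV serialization of allele records with codons and position as
#' separate columns (the expanded form produced by [load_allele_fixture()]).
#'
#' @param path File path.
#' @param records Data frame of allele records.
#' @return `read_allele_table` returns the validated data frame;
#'   `write_allele_table` returns `path` invisibly.
#' @export
read_allele_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("gene", "allele", "orf_name", "orf_length",
                            "ref_codon", "alt_codon", "position"),
                      c("orf_length", "position"), path)
  ok <- grepl("^[ACGT]{3}$", df$ref_codon) & grepl("^[ACGT]{3}$", df$alt_codon)
  if (!all(ok)) {
    stop(sprintf("%s: illegal codon in record(s): %s", path,
                 paste(df$allele[!ok], collapse = ", ")))
  }
  df$orf_length <- as.integer(df$orf_length)
  df$position <- as.integer(df$position)
  df
}

#' @rdname read_allele_table
#' @export
write_allele_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- mosaic scoring tables --------------------------------------------------

parse_tissue_label <- function(raw) {
  m <- regmatches(raw, regexec("^(.*?)\\s*\\(([^)]*)\\)\\s*$", raw))[[1]]
  if (length(m) == 3L) list(name = m[2], annotation = m[3], raw = raw)
  else list(name = trimws(raw), annotation = NA_character_, raw = raw)
}

new_mosaic_table <- function(tissues, worm_ids, calls,
                             likely_missing = NULL, present_in = NULL,
                             source = NULL) {
  uncertain <- if (is.null(likely_missing)) rep(FALSE, length(worm_ids))
               else grepl("\\?", likely_missing)
  structure(
    list(tissues = tissues, worm_ids = worm_ids, calls = calls,
         likely_missing = likely_missing, present_in = present_in,
         uncertain = uncertain, source = source),
    class = "mosaic_table"
  )
}

#' @export
print.mosaic_table <- function(x, ...) {
  cat(sprintf("mosaic scoring table: %d tissues x %d worms\n",
              nrow(x$calls), ncol(x$calls)))
  if (!is.null(x$likely_missing)) {
    cat("summary rows: 'Likely missing from' / 'Present in' attached\n")
  }
  invisible(x)
}

#' Read a mosaic scoring TSV
#'
#' First column is the tissue label (lineage annotation in parentheses),
#' remaining columns one per worm. Cells must use the four-symbol alphabet of
#' [mosaic_calls()]. Two optional trailing rows labelled
#' `Likely missing from` and `Present in` are parsed as per-worm summary
#' strings; they are carried as data and never consumed by inference.
#'
#' @param path File path.
#' @return A `mosaic_table` object: tissue definitions, worm ids, the call
#'   matrix, summary rows and a per-worm `uncertain` flag (set when the
#'   recorded summary carries a `?`).
#' @export
read_mosaic_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("%s: expected tissue column plus worm columns", path))
  labels <- df[[1]]
  worm_ids <- names(df)[-1]
  summary_labels <- c("Likely missing from", "Present in")
  is_summary <- labels %in% summary_labels
  tissue_rows <- df[!is_summary, , drop = FALSE]
  calls <- as.matrix(tissue_rows[, -1, drop = FALSE])
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(ncol(calls))) {
      if (!(calls[i, j] %in% mosaic_calls())) {
        stop(sprintf("%s: illegal call '%s' at tissue '%s', worm '%s'",
                     path, calls[i, j], tissue_rows[[1]][i], worm_ids[j]))
      }
    }
  }
  tiss <- lapply(tissue_rows[[1]], parse_tissue_label)
  tissues <- data.frame(
    name = vapply(tiss, `[[`, "", "name"),
    annotation = vapply(tiss, `[[`, "", "annotation"),
    raw_label = vapply(tiss, `[[`, "", "raw"),
    stringsAsFactors = FALSE
  )
  rownames(calls) <- tissues$name
  colnames(calls) <- worm_ids
  get_summary <- function(lab) {
    idx <- which(labels == lab)
    if (length(idx) == 0) NULL else unname(unlist(df[idx[1], -1]))
  }
  new_mosaic_table(tissues, worm_ids, calls,
                   likely_missing = get_summary("Likely missing from"),
                   present_in = get_summary("Present in"),
                   source = path)
}

#' Write a mosaic scoring table as TSV
#'
#' Inverse of [read_mosaic_table()]; summary rows are written back when
#' present, so write-then-read is the identity on legal tables.
#'
#' @param table A `mosaic_table`.
#' @param path File path.
#' @export
write_mosaic_table <- function(table, path) {
  stopifnot(inherits(table, "mosaic_table"))
  body <- cbind(tissue = table$tissues$raw_label, as.data.frame(table$calls))
  names(body) <- c("tissue", table$worm_ids)
  rownames(body) <- NULL
  if (!is.null(table$likely_missing)) {
    body <- rbind(body, c("Likely missing from", table$likely_missing))
  }
  if (!is.null(table$present_in)) {
    body <- rbind(body, c("Present in", table$present_in))
  }
  utils::write.table(body, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged mosaic-analysis scoring table
#'
#' The packaged fixture records GFP scoring of 19 tissues in 16 glucose-
#' tolerant mosaic worms carrying a rescuing extrachromosomal array, together
#' with the per-worm "Likely missing from" / "Present in" summaries recorded
#' by the original scorers. Worm 12, whose recorded summary is annotated as
#' uncertain (`P1, most ABa?`), carries `uncertain = TRUE`.
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A validated `mosaic_table` with 19 tissue rows and 16 worms.
#' @examples
#' tab <- load_mosaic_fixture()
#' dim(tab$calls)  # 19 16
#' @export
load_mosaic_fixture <- function(path = system.file("extdata", "table2_mosaic.tsv",
                                                   package = "memfluid")) {
  tab <- read_mosaic_table(path)
  if (nrow(tab$calls) != 19L || ncol(tab$calls) != 16L) {
    stop(sprintf("fixture dimension violation: %d tissues x %d worms (expected 19 x 16)",
                 nrow(tab$calls), ncol(tab$calls)))
  }
  if (is.null(tab$likely_missing) || is.null(tab$present_in)) {
    stop("fixture is missing its summary rows")
  }
  tab
}

# ---- FRAP trace tables ------------------------------------------------------

#' Read / write FRAP trace CSVs
#'
#' The trace CSV holds one row per frame with columns `worm_id`, `group`,
#' `time_s`, `bleach_roi`, `reference_roi`. `read_frap_traces` splits rows by
#' worm and returns validated [frap_trace()] objects; `write_frap_traces`
#' serializes a list of traces losslessly (full double precision).
#'
#' @param path File path.
#' @param traces List of `frap_trace` objects.
#' @return `read_frap_traces` returns a named list of `frap_trace` objects.
#' @export
read_frap_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("worm_id", "group", "time_s", "bleach_roi", "reference_roi"),
                      c("time_s", "bleach_roi", "reference_roi"), path)
  out <- lapply(split(df, df$worm_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    frap_trace(worm_id = d$worm_id[1], group = d$group[1], times = d$time_s,
               bleach_roi = d$bleach_roi, reference_roi = d$reference_roi)
  })
  out[unique(df$worm_id)]
}

#' @rdname read_frap_traces
#' @export
write_frap_traces <- function(traces, path) {
  if (inherits(traces, "frap_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(worm_id = tr$worm_id, group = tr$group,
               time_s = fmt_num(tr$times),
               bleach_roi = fmt_num(tr$bleach_roi),
               reference_roi = fmt_num(tr$reference_roi),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- lipid composition tables -----------------------------------------------

#' Read / write lipid composition CSVs
#'
#' Two dialects are auto-detected by their columns: mol% tables
#' (`sample_id, condition, lipid_class, carbons, double_bonds, mol_percent`)
#' and raw-intensity tables (the same keys with
#' `intensity, is_intensity, is_amount` instead of `mol_percent`). For mol%
#' tables the per-sample, per-class closure (sum of mol% = 100 within 1e-6)
#' is enforced on read.
#'
#' @param path File path.
#' @param records Lipid data frame in either dialect.
#' @return `read_lipid_table` returns the validated data frame with attribute
#'   `mode` set to `"mol_percent"` or `"intensity"`.
#' @export
read_lipid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- c("sample_id", "condition", "lipid_class", "carbons", "double_bonds")
  if ("mol_percent" %in% names(df)) {
    df <- check_columns(df, c(keys, "mol_percent"),
                        c("carbons", "double_bonds", "mol_percent"), path)
    validate_lipid_closure(df, context = path)
    attr(df, "mode") <- "mol_percent"
  } else if (all(c("intensity", "is_intensity", "is_amount") %in% names(df))) {
    df <- check_columns(df, c(keys, "intensity", "is_intensity", "is_amount"),
                        c("carbons", "double_bonds", "intensity",
                          "is_intensity", "is_amount"), path)
    attr(df, "mode") <- "intensity"
  } else {
    stop(sprintf("%s: missing required column 'mol_percent' (or the intensity triplet)",
                 path))
  }
  df
}

#' @rdname read_lipid_table
#' @export
write_lipid_table <- function(records, path) {
  out <- records
  for (col in intersect(c("mol_percent", "intensity", "is_intensity", "is_amount"),
                        names(out))) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_lipid_closure <- function(df, tol = 1e-6, context = "lipid table") {
  sums <- tapply(df$mol_percent, interaction(df$sample_id, df$lipid_class,
                                             drop = TRUE), sum)
  bad <- abs(sums - 100) > tol
  if (any(bad)) {
    stop(sprintf("%s: mol%% does not sum to 100 within %g for: %s",
                 context, tol, paste(names(sums)[bad], collapse = ", ")))
  }
  invisible(TRUE)
}
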