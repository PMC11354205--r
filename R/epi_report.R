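# Cohort exclusions, ACR QCT classification, age/sex stratified tables and
# crude / age-standardized prevalence.

#' Five-year age bins from 20 to 85+
#'
#' Bins `[20,25), [25,30), ..., [80,85), [85,Inf)`, labelled `"20-24"`,
#' ..., `"85+"`.
#'
#' @return an `age_binning` list with `breaks` and `labels`.
#' @export
age_bins <- function() {
  breaks <- c(seq(20, 85, 5), Inf)
  labels <- c(paste(seq(20, 80, 5), seq(24, 84, 5), sep = "-"), "85+")
  structure(list(breaks = breaks, labels = labels), class = "age_binning")
}

#' @rdname age_bins
#' @param age numeric vector of ages (>= 20).
#' @param binning an `age_binning`.
#' @return `assign_age_bin()`: factor of bin labels.
#' @export
assign_age_bin <- function(age, binning = age_bins()) {
  if (any(age < binning$breaks[1]))
    qct_abort("ages below the first bin", "qct_bad_argument")
  cut(age, breaks = binning$breaks, labels = binning$labels, right = FALSE)
}

#' Apply the cohort exclusion flowchart
#'
#' Removes participants whose L1 is not covered by the scan or whose
#' trabecular measurement is infeasible (fracture / surgical implant /
#' vertebroplasty). A participant carrying both flags is counted once, under
#' missing-L1 (the first flowchart reason).
#'
#' @param records data frame with logical columns `flag_missing_L1` and
#'   `flag_fracture_implant`.
#' @return list with `included` (data frame) and `tally` (named counts:
#'   `missing_L1`, `fracture_implant`, `total_excluded`, `included`,
#'   `input`).
#' @export
apply_exclusions <- function(records) {
  if (!nrow(records))
    return(list(included = records,
                tally = c(missing_L1 = 0L, fracture_implant = 0L,
                          total_excluded = 0L, included = 0L, input = 0L)))
  e1 <- as.logical(records$flag_missing_L1)
  e2 <- !e1 & as.logical(records$flag_fracture_implant)
  included <- records[!e1 & !e2, , drop = FALSE]
  list(included = included,
       tally = c(missing_L1 = sum(e1), fracture_implant = sum(e2),
                 total_excluded = sum(e1 | e2), included = nrow(included),
                 input = nrow(records)))
}

#' Classify vBMD by the ACR QCT diagnostic criteria
#'
#' Osteoporosis below 80 mg/cm^3, osteopenia from 80 to 120 inclusive,
#' normal above 120; both printed boundaries belong to osteopenia.
#'
#' @param vbmd numeric vector of trabecular vBMD, mg/cm^3 (finite, > 0).
#' @return factor with levels `osteoporosis`, `osteopenia`, `normal`.
#' @examples
#' classify_acr(c(79.99, 80, 120, 121))
#' @export
classify_acr <- function(vbmd) {
  if (any(!is.finite(vbmd)) || any(vbmd <= 0))
    qct_abort("vBMD must be finite and positive", "qct_bad_argument")
  factor(ifelse(vbmd < 80, "osteoporosis",
                ifelse(vbmd <= 120, "osteopenia", "normal")),
         levels = c("osteoporosis", "osteopenia", "normal"))
}

quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                         names = FALSE)

#' Age/sex-stratified vBMD summary table
#'
#' One row per age bin with participant count, median and interquartile
#' range of vBMD for the combined cohort and per sex. Quartiles use the
#' linear-interpolation convention (R type 7, recorded in the attribute
#' `quantile_type`). Empty bins keep `n = 0` with `NA` statistics.
#'
#' @param records data frame with `age`, `sex` and a vBMD column.
#' @param binning an [age_bins()] binning.
#' @param value_col name of the vBMD column.
#' @return data frame, one row per bin.
#' @export
stratify_bmd <- function(records, binning = age_bins(), value_col = "vbmd") {
  if (!value_col %in% names(records))
    qct_abort(sprintf("records lack a '%s' column", value_col),
              "qct_bad_argument")
  if (any(!is.finite(records[[value_col]])))
    qct_abort("every record needs a finite vBMD", "qct_bad_argument")
  bin <- assign_age_bin(records$age, binning)
  one <- function(sel, prefix) {
    out <- data.frame(row.names = binning$labels)
    out[[paste0("n_", prefix)]] <- 0L
    out[[paste0("median_", prefix)]] <- NA_real_
    out[[paste0("q1_", prefix)]] <- NA_real_
    out[[paste0("q3_", prefix)]] <- NA_real_
    for (lb in binning$labels) {
      v <- records[[value_col]][sel & !is.na(bin) & bin == lb]
      out[lb, paste0("n_", prefix)] <- length(v)
      if (length(v)) {
        q <- quartiles(v)
        out[lb, paste0("median_", prefix)] <- q[2]
        out[lb, paste0("q1_", prefix)] <- q[1]
        out[lb, paste0("q3_", prefix)] <- q[3]
      }
    }
    out
  }
  res <- cbind(data.frame(bin = binning$labels),
               one(rep(TRUE, nrow(records)), "all"),
               one(records$sex == "female", "female"),
               one(records$sex == "male", "male"))
  rownames(res) <- NULL
  attr(res, "quantile_type") <- 7L
  res
}

#' Crude prevalence of osteoporosis and osteopenia
#'
#' Counts and percentages among participants at or above `min_age`, per sex
#' and combined. Percentages are kept unrounded (`pct`) with a half-up
#' one-decimal display value (`pct_display`). An empty denominator yields an
#' undefined-prevalence marker (`NA` percentages, `undefined = TRUE`), never
#' a fabricated 0%.
#'
#' @param records data frame with `age`, `sex` and a `category` column as
#'   from [classify_acr()].
#' @param min_age denominator age cut-off, years (default 50).
#' @return data frame with one row per (group, category): `group`,
#'   `denominator`, `category`, `count`, `pct`, `pct_display`, `undefined`.
#' @export
crude_prevalence <- function(records, min_age = 50) {
  if (!"category" %in% names(records))
    qct_abort("records must be classified first (category column)",
              "qct_bad_argument")
  eligible <- records[records$age >= min_age, , drop = FALSE]
  groups <- list(combined = rep(TRUE, nrow(eligible)),
                 male = eligible$sex == "male",
                 female = eligible$sex == "female")
  rows <- list()
  for (g in names(groups)) {
    sub <- eligible[groups[[g]], , drop = FALSE]
    denom <- nrow(sub)
    for (cat in c("osteoporosis", "osteopenia", "normal")) {
      cnt <- sum(sub$category == cat)
      pct <- if (denom > 0) 100 * cnt / denom else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, denominator = denom, category = cat, count = cnt,
        pct = pct, pct_display = round_half_up(pct, 1),
        undefined = denom == 0L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "min_age") <- min_age
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Per-bin prevalence of a diagnostic category
#'
#' @param records classified records (see [crude_prevalence()]).
#' @param category category whose prevalence is computed.
#' @param binning an [age_bins()] binning.
#' @param min_age bins entirely below this age are dropped.
#' @return data frame `bin`, `n`, `count`, `prevalence` (percent; `NA` for
#'   empty bins).
#' @export
prevalence_by_bin <- function(records, category = "osteoporosis",
                              binning = age_bins(), min_age = 50) {
  bin <- assign_age_bin(records$age, binning)
  keep <- binning$labels[binning$breaks[-1] > min_age &
                           binning$breaks[-length(binning$breaks)] >= min_age]
  out <- do.call(rbind, lapply(keep, function(lb) {
    sub <- records[!is.na(bin) & bin == lb, , drop = FALSE]
    n <- nrow(sub)
    cnt <- sum(sub$category == category)
    data.frame(bin = lb, n = n, count = cnt,
               prevalence = if (n > 0) 100 * cnt / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Direct age standardization of per-bin prevalence
#'
#' Computes the weighted average of per-bin prevalences using a standard
#' population's age-bin weights. Bins without observed prevalence are
#' dropped and the remaining weights renormalized, with a warning. The
#' result is a convex combination of the per-bin prevalences.
#'
#' @param per_bin data frame with `bin` and `prevalence` columns (percent),
#'   e.g. from [prevalence_by_bin()].
#' @param standard a `standard_population` (see
#'   [read_standard_population()]), or a named numeric vector of
#'   non-negative weights keyed by bin label.
#' @return the standardized prevalence (percent) with attributes
#'   `provenance` and `weights_used`.
#' @export
age_standardize <- function(per_bin, standard) {
  if (inherits(standard, "standard_population")) {
    w <- standard$weights
    prov <- standard$provenance
  } else {
    w <- standard
    prov <- attr(standard, "provenance") %||% "unnamed standard population"
  }
  if (any(w < 0)) qct_abort("negative standard-population weight",
                            "qct_bad_argument")
  obs <- per_bin[!is.na(per_bin$prevalence), , drop = FALSE]
  if (!nrow(obs))
    qct_abort("no bin has an observed prevalence", "qct_bad_argument")
  missing_w <- setdiff(obs$bin, names(w))
  if (length(missing_w))
    qct_abort(paste("standard population lacks weights for bins:",
                    paste(missing_w, collapse = ", ")), "qct_bad_argument")
  w_used <- w[obs$bin]
  if (length(w) != nrow(obs) || abs(sum(w_used) - 1) > 1e-9) {
    if (abs(sum(w_used) - 1) > 1e-9)
      warning("renormalizing standard-population weights over the ",
              nrow(obs), " bins with observed prevalence")
    w_used <- w_used / sum(w_used)
  }
  out <- sum(w_used * obs$prevalence)
  attr(out, "provenance") <- prov
  attr(out, "weights_used") <- w_used
  out
}

#' Read a standard population from CSV
#'
#' Expects columns `bin_label` and `weight`. The bundled file
#' `standard_population_synthetic.csv` is a clearly labelled *synthetic*
#' standard population (it is not a national census distribution); reports
#' always carry the provenance label of the standard they used.
#'
#' @param path CSV path; defaults to the bundled synthetic standard.
#' @return a `standard_population`: list of `weights` (named numeric,
#'   summing to 1) and `provenance`.
#' @export
read_standard_population <- function(path = system.file(
  "extdata", "standard_population_synthetic.csv", package = "qctscreen")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin_label", "weight") %in% names(tab)))
    qct_abort("standard population CSV needs bin_label and weight columns",
              "qct_bad_argument")
  w <- tab$weight
  if (any(w < 0)) qct_abort("negative weight in standard population",
                            "qct_bad_argument")
  names(w) <- tab$bin_label
  w <- w / sum(w)
  structure(list(weights = w,
                 provenance = attr(tab, "provenance") %||%
                   tools::file_path_sans_ext(basename(path))),
            class = "standard_population")
}

#' Build the full prevalence report
#'
#' Combines crude counts/percentages with age-standardized prevalences of
#' osteoporosis and osteopenia, per sex and combined, among participants at
#' or above `min_age`, plus the per-bin table underlying the
#' standardization.
#'
#' @param records classified records.
#' @param standard a `standard_population`.
#' @param min_age denominator age cut-off.
#' @return a `prevalence_report`: list with `crude`, `standardized` (data
#'   frame group x category), `per_bin` (list of per-group per-category
#'   tables), `standard_provenance`, `min_age`.
#' @export
prevalence_report <- function(records, standard = read_standard_population(),
                              min_age = 50) {
  crude <- crude_prevalence(records, min_age)
  groups <- list(combined = records,
                 male = records[records$sex == "male", , drop = FALSE],
                 female = records[records$sex == "female", , drop = FALSE])
  std_rows <- list(); per_bin <- list()
  for (g in names(groups)) {
    for (cat in c("osteoporosis", "osteopenia")) {
      pb <- prevalence_by_bin(groups[[g]], cat, min_age = min_age)
      per_bin[[paste(g, cat, sep = ".")]] <- pb
      std <- tryCatch(suppressWarnings(age_standardize(pb, standard)),
                      qct_error = function(e) NA_real_)
      std_rows[[length(std_rows) + 1L]] <- data.frame(
        group = g, category = cat, standardized_pct = as.numeric(std),
        standardized_display = round_half_up(as.numeric(std), 1),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(crude = crude, standardized = do.call(rbind, std_rows),
                 per_bin = per_bin,
                 standard_provenance = if (inherits(standard,
                                                    "standard_population"))
                   standard$provenance else "unnamed standard population",
                 min_age = min_age),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat("<prevalence_report> participants aged >=", x$min_age, "\n")
  cr <- x$crude
  for (g in unique(cr$group)) {
    sub <- cr[cr$group == g & cr$category != "normal", ]
    denom <- sub$denominator[1]
    cat(sprintf("  %s (n = %d):\n", g, denom))
    for (i in seq_len(nrow(sub))) {
      std <- x$standardized[x$standardized$group == g &
                              x$standardized$category == sub$category[i], ]
      cat(sprintf("    %-12s %4d (%s%%), age-standardized %s%%\n",
                  sub$category[i], sub$count[i],
                  formatC(sub$pct_display[i], format = "f", digits = 1),
                  formatC(std$standardized_display, format = "f",
                          digits = 1)))
    }
  }
  cat("  standard population:", x$standard_provenance, "\n")
  invisible(x)
}

#' Write a prevalence report as CSV plus a text summary
#'
#' @param report a `prevalence_report`.
#' @param csv_path,txt_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_prevalence_report <- function(report, csv_path, txt_path = NULL) {
  if (!is.null(csv_path)) {
    crude <- as.data.frame(report$crude)
    std <- report$standardized
    merged <- merge(crude, std, by = c("group", "category"), all.x = TRUE)
    merged$standard_population <- report$standard_provenance
    utils::write.csv(merged, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(c(csv = csv_path, txt = txt_path))
}
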