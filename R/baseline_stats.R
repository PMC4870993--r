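#' Kruskal-Wallis comparison of a continuous variable across groups
#'
#' Rank-based k-sample test with tie correction; the p-value uses the
#' chi-square approximation on k-1 degrees of freedom. When every
#' observation is identical the statistic is defined as 0 with p = 1
#' (no variation to rank).
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation (at least 2 non-empty groups).
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `kind`, `statistic`, `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(values, group, variable = "value") {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- if (is.factor(group)) group[keep] else factor(group[keep])
  if (nlevels(group) < 2) {
    stop("kruskal_wallis needs at least 2 groups with observations",
         call. = FALSE)
  }
  if (any(tabulate(group, nlevels(group)) == 0)) {
    stop("kruskal_wallis: a group has zero observations", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    h <- 0
    p <- 1
  } else {
    kt <- stats::kruskal.test(values, group)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  tibble::tibble(variable = variable, kind = "continuous", statistic = h,
                 df = nlevels(group) - 1L, p_value = p)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson X-squared (without continuity correction) with expected counts
#' from the row and column margins; df = (r-1)(c-1).
#'
#' @param contingency Matrix of non-negative integer counts, at least 2x2.
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `kind`, `statistic`, `df`,
#'   `p_value`.
#' @export
chi_square <- function(contingency, variable = "value") {
  tab <- as.matrix(contingency)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integer counts",
         call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an all-zero row or column (expected counts undefined)",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(variable = variable, kind = "categorical",
                 statistic = unname(ct$statistic),
                 df = as.integer(ct$parameter), p_value = ct$p.value)
}

summary_continuous <- function(baseline, groups, var, test = TRUE) {
  vals <- baseline[[var]]
  rows <- list()
  for (stat in c("mean_sd", "range")) {
    row <- tibble::tibble(variable = var, kind = "continuous", level = stat)
    for (g in groups) {
      v <- vals[baseline$gi_group == g]
      lab <- if (stat == "mean_sd") {
        sprintf("%.2f±%.2f", mean(v), stats::sd(v))
      } else {
        sprintf("%.2f – %.2f", min(v), max(v))
      }
      row[[paste0("count_g", g)]] <- NA_real_
      row[[paste0("pct_g", g)]] <- NA_real_
      row[[paste0("value_g", g)]] <- lab
    }
    rows[[stat]] <- row
  }
  out <- dplyr::bind_rows(rows)
  out$p_value <- if (test) {
    kruskal_wallis(vals, baseline$gi_group, var)$p_value
  } else {
    NA_real_
  }
  out
}

summary_categorical <- function(baseline, groups, var) {
  lv <- gi_levels[[var]]
  rows <- list()
  counts <- table(factor(as.character(baseline[[var]]), levels = lv),
                  factor(baseline$gi_group, levels = groups))
  for (l in lv) {
    row <- tibble::tibble(variable = var, kind = "categorical", level = l)
    for (g in groups) {
      n_g <- sum(counts[, as.character(g)])
      cnt <- counts[l, as.character(g)]
      pct <- if (n_g > 0) round(100 * cnt / n_g) else NA_real_
      row[[paste0("count_g", g)]] <- as.numeric(cnt)
      row[[paste0("pct_g", g)]] <- pct
      row[[paste0("value_g", g)]] <- sprintf("%d (%s%%)", cnt,
                                             ifelse(is.na(pct), "-", pct))
    }
    rows[[l]] <- row
  }
  out <- dplyr::bind_rows(rows)
  # not_recorded rows are reported but excluded from the test
  test_tab <- counts[setdiff(rownames(counts), "not_recorded"), , drop = FALSE]
  test_tab <- test_tab[rowSums(test_tab) > 0, colSums(test_tab) > 0,
                       drop = FALSE]
  out$p_value <- if (nrow(test_tab) >= 2 && ncol(test_tab) >= 2) {
    chi_square(test_tab, var)$p_value
  } else {
    NA_real_
  }
  out
}

#' Per-group demographics table with hypothesis tests
#'
#' Builds a Table-1-style report from a scored baseline table: per severity
#' group the count, mean, SD and range of continuous variables
#' (Kruskal-Wallis p-value) and level counts with whole-number percentages
#' for categorical variables (Pearson chi-square p-value, `not_recorded`
#' rows reported but excluded from the test).
#'
#' @param baseline A scored baseline table ([score_baseline()] output) or a
#'   `gi_cohort` (scored on the fly).
#' @return A tibble with columns `variable`, `kind`, `level`,
#'   `count_g*`/`pct_g*`/`value_g*` per group, and `p_value` (repeated
#'   across the variable's rows).
#' @export
demographics_table <- function(baseline) {
  if (inherits(baseline, "gi_cohort")) baseline <- baseline$baseline
  if (!("gi_group" %in% names(baseline))) baseline <- score_baseline(baseline)
  if (nrow(baseline) == 0) {
    return(tibble::tibble(variable = character(), kind = character(),
                          level = character(), p_value = numeric()))
  }
  groups <- sort(unique(baseline$gi_group))
  multi <- length(groups) >= 2
  blocks <- list()
  blocks$n <- {
    row <- tibble::tibble(variable = "n", kind = "count", level = "n")
    for (g in groups) {
      cnt <- sum(baseline$gi_group == g)
      row[[paste0("count_g", g)]] <- cnt
      row[[paste0("pct_g", g)]] <- NA_real_
      row[[paste0("value_g", g)]] <- as.character(cnt)
    }
    row$p_value <- NA_real_
    row
  }
  for (var in c("age", "va_logmar", "cup_disc")) {
    blocks[[var]] <- summary_continuous(baseline, groups, var, test = multi)
  }
  for (var in c("gender", "ethnicity", "diagnosis", "lens_status",
                "shaffer_grade", "surgery")) {
    blocks[[var]] <- summary_categorical(baseline, groups, var)
    if (!multi) blocks[[var]]$p_value <- NA_real_
  }
  dplyr::bind_rows(blocks)
}

#' Render a demographics table as text
#'
#' @param tbl Output of [demographics_table()].
#' @param format `"md"` for a markdown pipe table.
#' @return A character vector of lines, invisibly printed with `cat()`.
#' @export
format_demographics <- function(tbl, format = c("md")) {
  format <- match.arg(format)
  if (nrow(tbl) == 0) return(invisible(character()))
  value_cols <- grep("^value_g", names(tbl), value = TRUE)
  header <- c("Variable", "Level", sub("value_g", "GI group ", value_cols),
              "p-value")
  lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)), collapse = "|"),
                    "|"))
  prev_var <- ""
  for (i in seq_len(nrow(tbl))) {
    p <- tbl$p_value[i]
    p_lab <- if (is.na(p) || tbl$variable[i] == prev_var) "" else
      ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))
    var_lab <- if (tbl$variable[i] == prev_var) "" else tbl$variable[i]
    lines <- c(lines, paste0(
      "| ", var_lab, " | ", tbl$level[i], " | ",
      paste(vapply(value_cols, function(cl) as.character(tbl[[cl]][i]), ""),
            collapse = " | "),
      " | ", p_lab, " |"))
    prev_var <- tbl$variable[i]
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
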