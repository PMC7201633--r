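# Univariate association statistics: Pearson chi-square,
# Cochran-Mantel-Haenszel linear trend, and crude odds ratios with
# Woolf (log-normal) confidence intervals.

#' Registry of the coded analysis variables
#'
#' Level order, reference level (the category reported with cOR 1.00),
#' and whether the univariate test is the CMH trend (ordinal bands) or
#' the Pearson chi-square.
#' @return Named list.
#' @export
variable_registry <- function() {
  lv <- aki_levels
  mk <- function(var, ref, ordinal, desc)
    list(levels = lv[[var]], reference = ref, ordinal = ordinal, description = desc)
  list(
    age_band       = mk("age_band", "30-49", TRUE,  "age at admission, years (bands 29/50/70)"),
    gender         = mk("gender", "male", FALSE, "sex"),
    hypertension   = mk("hypertension", "no", FALSE, "pre-existing hypertension"),
    diabetes       = mk("diabetes", "no", FALSE, "pre-existing diabetes"),
    hm_category    = mk("hm_category", "lymphoma", FALSE, "hematologic malignancy category"),
    admission_type = mk("admission_type", "normal", FALSE, "emergent vs normal admission"),
    treatment      = mk("treatment", "untreated_palliative", FALSE, "anti-tumor treatment"),
    alt_high       = mk("alt_high", "no", FALSE, "ALT >= 40 U/L"),
    ast_high       = mk("ast_high", "no", FALSE, "AST >= 35 U/L"),
    tbil_high      = mk("tbil_high", "no", FALSE, "total bilirubin >= 20.4 umol/L"),
    scr_high       = mk("scr_high", "no", FALSE, "admission SCr >= 115 umol/L"),
    egfr_band      = mk("egfr_band", ">=90", TRUE, "eGFR, mL/min/1.73m2 (bands 90/60)"),
    sua_band       = mk("sua_band", "<=359", TRUE, "serum uric acid, umol/L (bands 360/421/481)"),
    albumin_low    = mk("albumin_low", "no", FALSE, "albumin < 35 g/L (hypoalbuminemia)"),
    hemoglobin_low = mk("hemoglobin_low", "no", FALSE, "hemoglobin < 115 g/L (anemia)"),
    wbc_high       = mk("wbc_high", "no", FALSE, "WBC >= 9.5e9/L"),
    sodium_band    = mk("sodium_band", "normal", FALSE, "serum sodium 137-147 mmol/L reference"),
    potassium_band = mk("potassium_band", "normal", FALSE, "serum potassium 3.5-5.3 mmol/L reference")
  )
}

#' Construct a contingency table of an exposure against AKI
#'
#' @param levels Ordered exposure level labels.
#' @param aki,non_aki Integer counts per level.
#' @param reference Reference level (defaults to the first).
#' @param ordinal Whether levels carry a natural order (enables the CMH
#'   trend test).
#' @return Object of class \code{contingency_table}.
#' @export
contingency_table <- function(levels, aki, non_aki, reference = levels[1],
                              ordinal = FALSE) {
  stopifnot(length(levels) == length(aki), length(aki) == length(non_aki),
            all(aki >= 0), all(non_aki >= 0), reference %in% levels)
  structure(data.frame(level = levels, aki = as.integer(aki),
                       non_aki = as.integer(non_aki), stringsAsFactors = FALSE),
            reference = reference, ordinal = ordinal,
            class = c("contingency_table", "data.frame"))
}

#' Cross-tabulate one coded variable against the AKI outcome
#' @param coded A \code{coded_cohort}.
#' @param variable Column name.
#' @return A \code{contingency_table} (observed levels only).
#' @export
xtab_aki <- function(coded, variable) {
  reg <- variable_registry()[[variable]]
  x <- coded[[variable]]
  keep <- !is.na(x) & !is.na(coded$aki)
  tab <- table(x[keep], coded$aki[keep])
  lev <- rownames(tab)[rowSums(tab) > 0]
  ref <- if (!is.null(reg) && reg$reference %in% lev) reg$reference else lev[1]
  contingency_table(lev, aki = tab[lev, "yes"], non_aki = tab[lev, "no"],
                    reference = ref, ordinal = !is.null(reg) && reg$ordinal)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c) for the 2x2 formed by the requested level against
#' the table's reference level; the CI is
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table A \code{contingency_table}.
#' @param level Exposure level to compare against the reference.
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to every
#'   cell (needed when a cell is zero; off by default).
#' @return List of class \code{or_result}: \code{level},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}.
#' @export
crude_or <- function(table, level, conf_level = 0.95, haldane = FALSE) {
  ref <- attr(table, "reference")
  if (level == ref) stop("level coincides with the reference level")
  i <- match(level, table$level); j <- match(ref, table$level)
  if (is.na(i)) stop(sprintf("no level '%s' in table", level))
  a <- table$aki[i]; b <- table$non_aki[i]
  c_ <- table$aki[j]; d <- table$non_aki[j]
  if (any(c(a, b, c_, d) == 0) && !haldane) {
    stop("zero cell in 2x2 table; rerun with haldane = TRUE for the Haldane-Anscombe correction")
  }
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(list(level = level, odds_ratio = or,
                 ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se)),
            class = "or_result")
}

#' Pearson chi-square test of an R x 2 contingency table
#'
#' Classic sum of (O - E)^2 / E without continuity correction,
#' df = R - 1.
#'
#' @param table A \code{contingency_table} with at least two levels.
#' @return List: \code{statistic}, \code{df}, \code{p_value}.
#' @export
pearson_chi2 <- function(table) {
  if (nrow(table) < 2L) stop("need at least two exposure levels")
  m <- cbind(table$aki, table$non_aki)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("zero expected cell count")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Cochran-Mantel-Haenszel linear trend test
#'
#' The Mantel-Haenszel correlation statistic M^2 = (N - 1) r^2 with
#' integer scores 1..K for the ordered exposure levels and 0/1 for the
#' outcome, compared to chi-square with 1 df.
#'
#' @param table An ordinal \code{contingency_table} with K >= 3 levels.
#' @return List: \code{statistic}, \code{df} (= 1), \code{p_value}.
#' @export
cmh_trend <- function(table) {
  if (!isTRUE(attr(table, "ordinal"))) stop("CMH trend test requires an ordinal table")
  K <- nrow(table)
  if (K < 3L) stop("need at least three ordered levels")
  n1 <- table$aki; n0 <- table$non_aki
  n <- n1 + n0; N <- sum(n)
  u <- seq_len(K)
  mu_u <- sum(u * n) / N
  mu_y <- sum(n1) / N
  cov_uy <- sum(u * n1) / N - mu_u * mu_y
  var_u <- sum(u^2 * n) / N - mu_u^2
  var_y <- mu_y * (1 - mu_y)
  r <- cov_uy / sqrt(var_u * var_y)
  stat <- (N - 1) * r^2
  list(statistic = stat, df = 1L, p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Univariate association report (the printed-table layout)
#'
#' For every variable: per-level totals, AKI counts and percentages,
#' the Pearson chi-square (nominal variables) or CMH trend (ordinal
#' bands), and crude odds ratios with 95 percent intervals against the
#' reference level. Works on a coded cohort or directly on a named list
#' of \code{contingency_table}s (e.g. the packaged fixture).
#'
#' @param x A \code{coded_cohort} or named list of contingency tables.
#' @return Object of class \code{table1_report}: list with \code{rows}
#'   (data frame), \code{overall} (n, aki, pct) and \code{notes}.
#' @export
table1_report <- function(x) {
  if (inherits(x, "coded_cohort")) {
    if (!nrow(x)) stop("coded cohort is empty")
    vars <- intersect(names(variable_registry()), names(x))
    tabs <- stats::setNames(lapply(vars, function(v) xtab_aki(x, v)), vars)
    tot <- sum(!is.na(x$aki)); tot_aki <- sum(x$aki == "yes", na.rm = TRUE)
  } else {
    tabs <- x
    tot_aki <- sum(tabs[[1]]$aki); tot <- sum(tabs[[1]]$aki + tabs[[1]]$non_aki)
  }
  notes <- character(0)
  rows <- list()
  degenerate_outcome <- tot_aki == 0 || tot_aki == tot
  if (degenerate_outcome) notes <- c(notes, "degenerate outcome: AKI all-absent or all-present; statistics skipped")
  for (v in names(tabs)) {
    tab <- tabs[[v]]
    ref <- attr(tab, "reference")
    if (nrow(tab) < 2L) {
      notes <- c(notes, sprintf("variable '%s' has a single observed level; statistics skipped", v))
      stat <- NULL
    } else if (degenerate_outcome) {
      stat <- NULL
    } else if (isTRUE(attr(tab, "ordinal")) && nrow(tab) >= 3L) {
      stat <- c(cmh_trend(tab), test = "cmh")
    } else {
      stat <- c(pearson_chi2(tab), test = "chi2")
    }
    for (i in seq_len(nrow(tab))) {
      lvl <- tab$level[i]
      or <- ci_l <- ci_h <- NA_real_
      if (!degenerate_outcome && nrow(tab) >= 2L) {
        if (lvl == ref) {
          or <- 1
        } else if (all(c(tab$aki[i], tab$non_aki[i],
                         tab$aki[tab$level == ref], tab$non_aki[tab$level == ref]) > 0)) {
          o <- crude_or(tab, lvl)
          or <- o$odds_ratio; ci_l <- o$ci_low; ci_h <- o$ci_high
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lvl, total = tab$aki[i] + tab$non_aki[i],
        aki = tab$aki[i],
        aki_pct = 100 * tab$aki[i] / (tab$aki[i] + tab$non_aki[i]),
        test = if (is.null(stat)) NA_character_ else stat$test,
        statistic = if (is.null(stat)) NA_real_ else stat$statistic,
        p_value = if (is.null(stat)) NA_real_ else stat$p_value,
        odds_ratio = or, ci_low = ci_l, ci_high = ci_h,
        reference = lvl == ref, stringsAsFactors = FALSE)
    }
  }
  structure(list(rows = do.call(rbind, rows),
                 overall = list(n = tot, aki = tot_aki, pct = 100 * tot_aki / tot),
                 notes = notes),
            class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat(sprintf("Univariate AKI report: %d patients, %d AKI (%.1f%%)\n",
              x$overall$n, x$overall$aki, x$overall$pct))
  print(x$rows, digits = 4)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
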