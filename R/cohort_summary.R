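#' Two-sided Fisher exact test by enumeration
#'
#' For 2x2 tables the p-value is computed exactly from the hypergeometric
#' distribution: the sum of probabilities of all tables with the observed
#' margins that are no more probable than the observed table (the
#' dominant two-sided convention).  Larger r x c tables are enumerated
#' exhaustively over all tables with the observed margins when that
#' enumeration is tractable (at most `max_tables` tables), otherwise the
#' p-value is estimated by Monte-Carlo sampling of margin-fixed tables.
#'
#' @param tab integer matrix of counts (rows = category, cols = class)
#' @param B Monte-Carlo samples for large tables
#' @param seed Monte-Carlo seed
#' @param max_tables enumeration budget for r x c tables
#' @return list with `p_value` and `method` ("exact" or "simulated")
#' @export
fisher_exact <- function(tab, B = 10000, seed = 1, max_tables = 2e6) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact needs a matrix of non-negative integer counts")
  }
  rel_tol <- 1 + 1e-7
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    # hypergeometric enumeration over the one free cell
    m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n_):min(k, m)
    probs <- stats::dhyper(support, m, n_, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n_, k)
    return(list(p_value = min(1, sum(probs[probs <= p_obs * rel_tol])),
                method = "exact"))
  }
  row_m <- rowSums(tab); col_m <- colSums(tab)
  tables <- enumerate_tables(row_m, col_m, max_tables)
  if (!is.null(tables)) {
    logp <- vapply(tables, table_log_prob, numeric(1),
                   row_m = row_m, col_m = col_m)
    p_obs <- table_log_prob(tab, row_m, col_m)
    p <- sum(exp(logp[logp <= p_obs + log(rel_tol)]))
    return(list(p_value = min(1, p), method = "exact"))
  }
  set.seed(seed)
  p_obs <- table_log_prob(tab, row_m, col_m)
  sims <- stats::r2dtable(B, row_m, col_m)
  hits <- vapply(sims, function(s) {
    table_log_prob(s, row_m, col_m) <= p_obs + log(rel_tol)
  }, logical(1))
  list(p_value = (sum(hits) + 1) / (B + 1), method = "simulated")
}

# log multivariate hypergeometric probability of a margin-fixed table
table_log_prob <- function(tab, row_m, col_m) {
  sum(lgamma(row_m + 1)) + sum(lgamma(col_m + 1)) -
    lgamma(sum(row_m) + 1) - sum(lgamma(tab + 1))
}

# all r x c integer tables with the given margins, or NULL if too many
enumerate_tables <- function(row_m, col_m, max_tables) {
  out <- list()
  count <- 0L
  r <- length(row_m); cc <- length(col_m)
  rec <- function(tab, i, rem_col) {
    if (count > max_tables) return(FALSE)
    if (i == r) {
      if (all(rem_col >= 0)) {
        tab[r, ] <- rem_col
        if (all(tab[r, ] >= 0) && sum(tab[r, ]) == row_m[r]) {
          count <<- count + 1L
          out[[count]] <<- tab
        }
      }
      return(TRUE)
    }
    fill_row <- function(row, j, rem) {
      if (count > max_tables) return(FALSE)
      if (j == cc) {
        if (rem <= rem_col[cc]) {
          row[cc] <- rem
          tab[i, ] <- row
          return(rec(tab, i + 1, rem_col - row))
        }
        return(TRUE)
      }
      for (v in 0:min(rem, rem_col[j])) {
        row[j] <- v
        if (!fill_row(row, j + 1, rem - v)) return(FALSE)
      }
      TRUE
    }
    fill_row(integer(cc), 1, row_m[i])
  }
  ok <- rec(matrix(0L, r, cc), 1, col_m)
  if (!ok || count > max_tables) return(NULL)
  out
}

#' Cohort summary table with per-class statistics
#'
#' Produces a Table-1-style summary: per-class n; mean (SD) with a pooled
#' two-sample Student t-test p-value for numeric variables (age,
#' pack-years); per-level counts with a Fisher exact p-value for
#' categorical variables (gender, plus any extra categorical columns
#' present).  Missing values are excluded per variable and the
#' denominators reported explicitly.
#'
#' @param subjects subject table with `class_label` and demographic columns
#' @param numeric_vars numeric variables to summarise
#' @param categorical_vars categorical variables to summarise
#' @param welch use Welch's t instead of pooled-variance Student's t
#' @return data.frame summary (one row per variable/level) with attribute
#'   `p_values`
#' @export
summarize_cohort <- function(subjects,
                             numeric_vars = c("age", "pack_years"),
                             categorical_vars = "gender",
                             welch = FALSE) {
  classes <- c("NC", "CA")
  if (!all(classes %in% subjects$class_label)) {
    stop("both classes (NC, CA) must be present")
  }
  rows <- list()
  p_values <- list()
  add_row <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  n_by <- table(factor(subjects$class_label, classes))
  add_row(variable = "n", level = "", nc = as.character(n_by["NC"]),
          ca = as.character(n_by["CA"]), p_value = NA_real_)

  for (v in intersect(numeric_vars, names(subjects))) {
    x_nc <- subjects[[v]][subjects$class_label == "NC"]
    x_ca <- subjects[[v]][subjects$class_label == "CA"]
    x_nc <- x_nc[!is.na(x_nc)]; x_ca <- x_ca[!is.na(x_ca)]
    if (length(x_nc) < 2 || length(x_ca) < 2) {
      stop("variable '", v, "' needs >= 2 observed values per class")
    }
    p <- stats::t.test(x_ca, x_nc, var.equal = !welch)$p.value
    p_values[[v]] <- p
    fmt <- function(x) sprintf("%.1f (+/-%.1f) [n=%d]", mean(x),
                               stats::sd(x), length(x))
    add_row(variable = v, level = "", nc = fmt(x_nc), ca = fmt(x_ca),
            p_value = p)
  }

  for (v in intersect(categorical_vars, names(subjects))) {
    keep <- !is.na(subjects[[v]])
    tab <- table(subjects[[v]][keep],
                 factor(subjects$class_label[keep], classes))
    if (nrow(tab) < 2) next
    p <- fisher_exact(unclass(tab))$p_value
    p_values[[v]] <- p
    first <- TRUE
    for (lv in rownames(tab)) {
      add_row(variable = v, level = lv,
              nc = as.character(tab[lv, "NC"]),
              ca = as.character(tab[lv, "CA"]),
              p_value = if (first) p else NA_real_)
      first <- FALSE
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_values") <- p_values
  out
}
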