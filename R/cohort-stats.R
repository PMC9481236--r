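#' Diagnostic-yield summaries
#'
#' Computes diagnostic yields (percentage of patients with a positive
#' genetic diagnosis) over the whole cohort or by subgroup.  Stage yields
#' use the full cohort as denominator, so the exome stage's figure is the
#' incremental yield the second tier adds on top of the panel.
#' Percentages are rounded half-up to one decimal, the convention of the
#' printed clinical literature.
#'
#' @param outcomes outcome table from [triage_cohort()].
#' @param patients patient table with `patient_id`, `group`
#'   (`syndromic`/`nonsyndromic`), `suture_type`.
#' @param by grouping: `overall`, `stage`, `syndromic_status`, or
#'   `suture_type`.
#' @return data.frame with `group`, `n_total`, `n_positive`,
#'   `yield_percent`.
#' @export
summarize_yields <- function(outcomes, patients,
                             by = c("overall", "stage", "syndromic_status",
                                    "suture_type")) {
  by <- match.arg(by)
  if (!nrow(outcomes)) {
    return(data.frame(group = character(0), n_total = integer(0),
                      n_positive = integer(0), yield_percent = numeric(0)))
  }
  pos <- outcomes$status == "positive"
  n_all <- nrow(outcomes)
  mk <- function(group, n_total, n_positive) {
    data.frame(group = group, n_total = as.integer(n_total),
               n_positive = as.integer(n_positive),
               yield_percent = ifelse(n_total > 0,
                                      round_half_up(100 * n_positive / n_total,
                                                    1), NA_real_),
               stringsAsFactors = FALSE)
  }
  if (by == "overall") {
    return(mk("overall", n_all, sum(pos)))
  }
  if (by == "stage") {
    return(rbind(
      mk("panel", n_all, sum(pos & outcomes$stage == "panel")),
      mk("wes", n_all, sum(pos & outcomes$stage == "wes"))
    ))
  }
  key <- if (by == "syndromic_status") "group" else "suture_type"
  grp <- patients[[key]][match(outcomes$patient_id, patients$patient_id)]
  do.call(rbind, lapply(sort(unique(grp)), function(g) {
    mk(g, sum(grp == g), sum(pos & grp == g))
  }))
}

#' Per-gene contribution to the positive diagnoses
#'
#' @param outcomes outcome table from [triage_cohort()].
#' @return data.frame `gene`, `n_patients` (distinct positive patients
#'   whose causal variants involve the gene), sorted by contribution.
#' @export
gene_contributions <- function(outcomes) {
  pos <- outcomes[outcomes$status == "positive", , drop = FALSE]
  genes <- split_tags(pos$causal_genes)
  df <- data.frame(patient_id = rep(pos$patient_id, lengths(genes)),
                   gene = unlist(genes), stringsAsFactors = FALSE)
  df <- unique(df)
  tab <- sort(table(df$gene), decreasing = TRUE)
  data.frame(gene = names(tab), n_patients = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test given both margins, computed from the
#' hypergeometric distribution of the top-left cell.  One-tailed p-values
#' sum the tail of tables at least as extreme in the stated direction
#' (`greater`: association at least as strong towards large top-left
#' counts); the two-tailed p-value follows the point-probability method —
#' the sum of probabilities of all tables no more probable than the
#' observed one — which is the convention of mainstream statistical
#' software.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @param alternative `two_tailed`, `one_tailed_greater`, or
#'   `one_tailed_less`.
#' @return the p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2), "one_tailed_greater")  # 1/6
fisher_exact <- function(table,
                         alternative = c("two_tailed", "one_tailed_greater",
                                         "one_tailed_less")) {
  alternative <- match.arg(alternative)
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) {
    crs_abort("fisher_exact needs a 2x2 table", "crstrio_input_error")
  }
  check_counts(m)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 + r2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  switch(alternative,
    one_tailed_greater = sum(probs[support >= a]),
    one_tailed_less = sum(probs[support <= a]),
    two_tailed = {
      p_obs <- probs[match(a, support)]
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    }
  )
}

check_counts <- function(m) {
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    crs_abort("contingency counts must be non-negative integers",
              "crstrio_input_error")
  }
  invisible(TRUE)
}

# number of non-negative integer tables with the given margins, computed
# exactly by dynamic programming when one dimension is 2 (the free row is
# a bounded composition), NA otherwise (caller falls back to bounded
# enumeration)
count_margin_tables <- function(row_sums, col_sums) {
  if (length(row_sums) != 2 && length(col_sums) != 2) return(NA_real_)
  if (length(col_sums) == 2 && length(row_sums) != 2) {
    tmp <- row_sums; row_sums <- col_sums; col_sums <- tmp
  }
  target <- row_sums[1]
  dp <- c(1, rep(0, target))
  for (cs in col_sums) {
    new_dp <- numeric(target + 1)
    for (t in 0:target) {
      v <- 0:min(cs, t)
      new_dp[t + 1] <- sum(dp[t + 1 - v])
    }
    dp <- new_dp
  }
  dp[target + 1]
}

# multivariate hypergeometric log point-probability of a margin-fixed table
log_table_prob <- function(m) {
  n <- sum(m)
  sum(lfactorial(rowSums(m))) + sum(lfactorial(colSums(m))) -
    lfactorial(n) - sum(lfactorial(m))
}

# enumerate all r x c tables with the given margins, applying f to each;
# stops with a capability condition if more than `bound` tables are visited
enumerate_tables <- function(row_sums, col_sums, f, bound = Inf) {
  r <- length(row_sums); cc <- length(col_sums)
  m <- matrix(0L, r, cc)
  count <- 0L
  rec <- function(i, j, row_rem, col_rem) {
    if (i == r && j == cc) {
      if (row_rem[i] == col_rem[j]) {
        m[i, j] <<- row_rem[i]
        count <<- count + 1L
        if (count > bound) {
          crs_abort("enumeration bound exceeded", "crstrio_capability_error")
        }
        f(m)
      }
      return(invisible(NULL))
    }
    if (j == cc) {                      # last cell in the row is forced
      v <- row_rem[i]
      if (v <= col_rem[j]) {
        m[i, j] <<- v
        cr <- col_rem; cr[j] <- cr[j] - v
        rr <- row_rem; rr[i] <- 0L
        rec(i + 1L, 1L, rr, cr)
      }
      return(invisible(NULL))
    }
    if (i == r) {                       # last row: cells forced by columns
      v <- col_rem[j]
      if (v <= row_rem[i]) {
        m[i, j] <<- v
        rr <- row_rem; rr[i] <- rr[i] - v
        cr <- col_rem; cr[j] <- 0L
        rec(i, j + 1L, rr, cr)
      }
      return(invisible(NULL))
    }
    for (v in 0:min(row_rem[i], col_rem[j])) {
      m[i, j] <<- v
      rr <- row_rem; rr[i] <- rr[i] - v
      cr <- col_rem; cr[j] <- cr[j] - v
      rec(i, j + 1L, rr, cr)
    }
  }
  rec(1L, 1L, as.integer(row_sums), as.integer(col_sums))
  invisible(count)
}

#' Exact (or Monte-Carlo) test of independence for an r x c table
#'
#' Exact conditional p-value by full enumeration of all tables with the
#' observed margins, using the point-probability criterion (sum of
#' probabilities of tables no more probable than the observed one).  When
#' the enumeration would visit more than `max_tables` tables, the test
#' falls back — if `monte_carlo` draws are allowed — to Monte-Carlo
#' sampling from the conditional distribution (Patefield's algorithm via
#' `stats::r2dtable`), with the add-one p-value estimate; otherwise it
#' signals a capability error.  On 2x2 input the enumeration reproduces
#' [fisher_exact()]'s two-tailed value.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param max_tables enumeration bound.
#' @param monte_carlo number of Monte-Carlo tables to draw above the
#'   bound, or `NULL` to disallow the fallback.
#' @param seed RNG seed for the Monte-Carlo fallback.
#' @return list with `p_value` and `method` (`"enumeration"` or
#'   `"monte_carlo"`).
#' @export
fisher_rxc <- function(table, max_tables = 2e6, monte_carlo = NULL,
                       seed = 1L) {
  m <- as.matrix(table)
  check_counts(m)
  rs <- rowSums(m); cs <- colSums(m)
  if (sum(m) == 0) return(list(p_value = 1, method = "enumeration"))
  lp_obs <- log_table_prob(m)
  tol <- log(1 + 1e-7)
  n_tab <- count_margin_tables(rs, cs)
  feasible <- is.na(n_tab) || n_tab <= max_tables
  p <- 0
  res <- if (!feasible) NULL else tryCatch({
    enumerate_tables(rs, cs, function(t) {
      lp <- log_table_prob(t)
      if (lp <= lp_obs + tol) p <<- p + exp(lp)
    }, bound = max_tables)
    list(p_value = min(p, 1), method = "enumeration")
  }, crstrio_capability_error = function(e) NULL)
  if (!is.null(res)) return(res)
  if (is.null(monte_carlo)) {
    crs_abort(sprintf("table enumeration exceeds %g tables; pass monte_carlo",
                      max_tables), "crstrio_capability_error")
  }
  withr::with_seed(seed, {
    draws <- stats::r2dtable(monte_carlo, rs, cs)
    hits <- vapply(draws, function(t) log_table_prob(t) <= lp_obs + tol,
                   logical(1))
    list(p_value = (1 + sum(hits)) / (monte_carlo + 1),
         method = "monte_carlo")
  })
}
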