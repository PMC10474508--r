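#' Postpartum depression flag from EPDS responses
#'
#' A mother screens positive for postpartum depression symptoms when her
#' Edinburgh Postnatal Depression Scale total is at least 10 or her answer
#' to question 10 (self-harm) is other than 0. The flag is missing only when
#' both inputs are missing.
#'
#' @param epds_total Integer vector of EPDS totals (may contain `NA`).
#' @param epds_q10 Integer vector of question-10 answers (may contain `NA`).
#' @return Logical vector.
#' @examples
#' ppd_flag(c(9, 9, 12, NA), c(0, 1, 0, NA))
#' @export
ppd_flag <- function(epds_total, epds_q10) {
  out <- (dplyr::coalesce(epds_total, 0L) >= 10) |
    (dplyr::coalesce(epds_q10, 0L) != 0)
  out[is.na(epds_total) & is.na(epds_q10)] <- NA
  out
}

#' Prematurity category from gestational age
#'
#' Standard prematurity strata: extremely preterm below 27 weeks, very
#' preterm 27-31 weeks, late preterm 32-36 weeks, early term 37-38 weeks,
#' full term 39 weeks and above.
#'
#' @param gestational_age Numeric vector, weeks.
#' @return Factor with levels `extremely_preterm`, `very_preterm`,
#'   `late_preterm`, `early_term`, `full_term`.
#' @export
preterm_category <- function(gestational_age) {
  cut(gestational_age,
      breaks = c(-Inf, 27, 32, 37, 39, Inf),
      labels = c("extremely_preterm", "very_preterm", "late_preterm",
                 "early_term", "full_term"),
      right = FALSE)
}

#' Mann-Whitney U test with midranks
#'
#' Two-sided rank-sum comparison of two samples. `U` is computed from
#' midranks of the pooled sample. For small samples (combined n of at most
#' `exact_max`) the p-value is obtained by exact enumeration of all
#' assignments of the pooled (mid)ranks to the two groups; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used. Surveillance scores are heavily tied at 0, so
#' midranks and the tie correction matter.
#'
#' @param sample_a,sample_b Numeric vectors, both nonempty.
#' @param group_names Length-2 character labels for the report.
#' @param exact_max Combined sample size at or below which the exact
#'   enumeration path is used (default 20).
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `u_statistic` (U of sample A), `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(sample_a, sample_b, group_names = c("A", "B"),
                         exact_max = 20) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  n <- n_a + n_b
  r <- rank(c(sample_a, sample_b))           # midranks
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2

  if (n <= exact_max) {
    method <- "exact"
    combos <- utils::combn(n, n_a)
    u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    dev <- abs(u_all - mu)
    p <- mean(dev >= abs(u_a - mu) - 1e-9)
  } else {
    method <- "normal_approximation"
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_a - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  tibble::tibble(
    group_a = group_names[1], group_b = group_names[2],
    n_a = n_a, n_b = n_b,
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    u_statistic = u_a, p_value = p, method = method
  )
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that drops incomplete pairs and
#' returns `NA` (rather than erroring) when either variable has zero
#' variance.
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Stratified DSS means with pairwise rank-sum comparisons
#'
#' Computes per-stratum sample sizes and mean scores for every year-of-life
#' window and domain group of a score grid, stratifying children by one
#' covariate (categorical, or numeric with bins). Consecutive strata (or all
#' pairs) are compared with the Mann-Whitney test and annotated with
#' significance stars (`*` p<.05, `**` p<.01, `***` p<.001, two-sided,
#' unadjusted). Children missing the stratifier are excluded from this
#' stratification only. Empty strata are reported with `n = 0`, not
#' dropped.
#'
#' @param scores Output of [score_table()].
#' @param children Child covariate records.
#' @param var Name of the stratifying column in `children`.
#' @param breaks Optional numeric breaks; when given, `var` is binned with
#'   [cut()] (left-closed, lowest and highest bins closed).
#' @param levels Optional explicit ordering of the strata.
#' @param pairs `"consecutive"` (default) or `"all"`.
#' @return A list of class `devsurv_strata`: `means` (tibble `window`,
#'   `group`, `stratum`, `n`, `mean_dss`) and `comparisons` (tibble with
#'   the two strata, U, p and stars per window and group).
#' @export
stratified_means <- function(scores, children, var, breaks = NULL,
                             levels = NULL, pairs = c("consecutive", "all")) {
  pairs <- match.arg(pairs)
  if (!var %in% names(children)) {
    stop("children table has no column '", var, "'", call. = FALSE)
  }
  strat <- children[[var]]
  if (!is.null(breaks)) {
    strat <- cut(children[[var]], breaks = breaks, right = FALSE,
                 include.lowest = TRUE)
  }
  key <- tibble::tibble(child_id = children$child_id, stratum = as.character(strat))
  key <- key[!is.na(key$stratum), ]
  if (is.null(levels)) {
    levels <- if (!is.null(breaks) || is.factor(strat)) {
      lv <- levels(strat)
      lv[lv %in% key$stratum | TRUE]
    } else sort(unique(key$stratum))
  }
  df <- dplyr::inner_join(scores, key, by = "child_id")
  df <- df[!is.na(df$dss), ]

  cells <- tidyr::expand_grid(
    window = unique(scores$window), group = unique(scores$group),
    stratum = levels
  )
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$window, .data$group, .data$stratum),
    n = dplyr::n(), mean_dss = mean(.data$dss), .groups = "drop"
  )
  means <- dplyr::left_join(cells, means, by = c("window", "group", "stratum"))
  means$n[is.na(means$n)] <- 0L

  pair_idx <- if (pairs == "consecutive") {
    if (length(levels) < 2) list() else
      lapply(seq_len(length(levels) - 1), function(i) c(i, i + 1))
  } else {
    utils::combn(length(levels), 2, simplify = FALSE)
  }
  comps <- list()
  for (w in unique(scores$window)) for (g in unique(scores$group)) {
    sub <- df[df$window == w & df$group == g, ]
    for (pr in pair_idx) {
      a <- sub$dss[sub$stratum == levels[pr[1]]]
      b <- sub$dss[sub$stratum == levels[pr[2]]]
      if (length(a) == 0 || length(b) == 0) next
      cmp <- mann_whitney(a, b, group_names = levels[pr])
      cmp$window <- w
      cmp$group <- g
      comps[[length(comps) + 1]] <- cmp
    }
  }
  comparisons <- dplyr::bind_rows(comps)
  if (nrow(comparisons) > 0) {
    comparisons$stars <- significance_stars(comparisons$p_value)
    comparisons <- comparisons[c("window", "group", "group_a", "group_b",
                                 "n_a", "n_b", "mean_a", "mean_b",
                                 "u_statistic", "p_value", "stars", "method")]
  }
  structure(list(variable = var, means = means, comparisons = comparisons),
            class = "devsurv_strata")
}

#' @export
print.devsurv_strata <- function(x, ...) {
  cat("DSS stratified by", x$variable, "\n\n")
  print(as.data.frame(x$means), row.names = FALSE)
  if (nrow(x$comparisons) > 0) {
    cat("\nPairwise Mann-Whitney comparisons:\n")
    print(as.data.frame(x$comparisons[c("window", "group", "group_a", "group_b",
                                        "p_value", "stars")]), row.names = FALSE)
  }
  invisible(x)
}

#' Drop preterm-born children
#'
#' Subpopulation analyses exclude children born before 37 weeks of
#' gestation (and children with missing gestational age); the one exception
#' is the stratification by gestational age itself, which must be run on
#' the unfiltered cohort.
#'
#' @param children Child covariate records.
#' @return The on-term subset.
#' @export
exclude_preterm <- function(children) {
  keep <- !is.na(children$gestational_age) & children$gestational_age >= 37
  children[keep, ]
}
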