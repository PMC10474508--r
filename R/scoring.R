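#' Discrete Milestone Attainment Score (DMAS)
#'
#' An attained milestone scores 0 regardless of age. A failed milestone
#' scores the index of the severity bracket containing the evaluation age:
#' 1 when fewer than 75% of same-age children attain it, 2 between 75% and
#' 90%, 3 between 90% and 95%, and 4 above 95%. Ages are clamped to
#' `[t0, t100]` before lookup.
#'
#' @param milestone A single-row scale entry.
#' @param age Numeric vector of evaluation ages in months.
#' @param attained Logical vector (recycled against `age`).
#' @return Integer vector of scores in 0..4.
#' @seealso [score_lmas()] for the continuous variant.
#' @export
score_dmas <- function(milestone, age, attained) {
  n <- max(length(age), length(attained))
  age <- rep_len(age, n)
  attained <- rep_len(attained, n)
  out <- integer(n)
  failed <- !attained
  if (any(failed)) out[failed] <- bracket_of(milestone, age[failed])
  out
}

#' Linearized Milestone Attainment Score (LMAS)
#'
#' Continuous extension of the discrete score: 0 for attainment, and for a
#' failure at age `a` inside bracket `i = (a_min, a_max]`,
#' `(i - 1) + (a - a_min) / (a_max - a_min)`. The result is the unique
#' continuous piecewise-linear function of age that is 0 at `t0`, equals `i`
#' at the upper end of bracket `i`, and is linear within each bracket; it
#' coincides with the discrete score at every bracket's upper endpoint. A
#' failure exactly at `t0` therefore scores 0 even though its discrete score
#' is 1. Within a degenerate (zero-width) bracket the right-limit value `i`
#' is returned. Ages are clamped to `[t0, t100]`.
#'
#' @inheritParams score_dmas
#' @return Numeric vector of scores in `[0, 4]`.
#' @export
score_lmas <- function(milestone, age, attained) {
  n <- max(length(age), length(attained))
  age <- rep_len(age, n)
  attained <- rep_len(attained, n)
  thr <- as.numeric(milestone[c("t0", "t75", "t90", "t95", "t100")])
  out <- numeric(n)
  failed <- !attained
  if (!any(failed)) return(out)
  a <- pmin(pmax(age[failed], thr[1]), thr[5])
  i <- bracket_of(milestone, a)
  a_min <- thr[i]
  a_max <- thr[i + 1]
  width <- a_max - a_min
  val <- ifelse(width == 0, i, (i - 1) + (a - a_min) / pmax(width, .Machine$double.xmin))
  out[failed] <- val
  out
}

#' Score a table of milestone attempts
#'
#' Annotates each attempt with its discrete and linearized attainment score.
#' Every attempt is scored independently: repeated attempts of the same
#' milestone each count. Attempts documented by parent report are treated
#' identically to clinic-observed ones.
#'
#' @param attempts A data frame with columns `child_id`, `milestone_id`,
#'   `age_months`, `attained` (logical or 0/1), and optionally `source`
#'   (`observed` or `parent_report`).
#' @param scale A `devsurv_scale` resolving every `milestone_id`.
#' @return The attempts tibble with columns `domain`, `dmas`, `lmas` added.
#' @export
score_attempts <- function(attempts, scale) {
  attempts <- tibble::as_tibble(attempts)
  if (nrow(attempts) == 0) {
    return(dplyr::mutate(attempts, domain = character(0),
                         dmas = integer(0), lmas = numeric(0)))
  }
  if (any(attempts$age_months < 0)) {
    stop("attempt with negative age", call. = FALSE)
  }
  unknown <- setdiff(unique(attempts$milestone_id), scale$milestone_id)
  if (length(unknown) > 0) {
    stop("attempt references unknown milestone(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  attempts$attained <- as.logical(attempts$attained)
  scored <- dplyr::left_join(
    attempts,
    tibble::as_tibble(unclass_scale(scale)),
    by = "milestone_id"
  )
  # vectorized over all rows at once: bracket index from threshold columns
  a <- pmin(pmax(scored$age_months, scored$t0), scored$t100)
  thr <- as.matrix(scored[c("t0", "t75", "t90", "t95", "t100")])
  eq <- thr[, 2:5, drop = FALSE] == a
  has_eq <- rowSums(eq) > 0
  i <- 1L + (a > thr[, 2]) + (a > thr[, 3]) + (a > thr[, 4])
  if (any(has_eq)) {
    i[has_eq] <- max.col(eq[has_eq, , drop = FALSE], ties.method = "last")
  }
  a_min <- thr[cbind(seq_len(nrow(thr)), i)]
  a_max <- thr[cbind(seq_len(nrow(thr)), i + 1L)]
  width <- a_max - a_min
  lmas <- ifelse(width == 0, i, (i - 1) + (a - a_min) / pmax(width, .Machine$double.xmin))
  scored$dmas <- ifelse(scored$attained, 0L, as.integer(i))
  scored$lmas <- ifelse(scored$attained, 0, lmas)
  dplyr::select(scored, -dplyr::all_of(c("t0", "t75", "t90", "t95", "t100")))
}

#' Developmental Surveillance Score over a milestone set
#'
#' The DSS for a query — an age window crossed with a set of developmental
#' domains — is the arithmetic mean of the per-attempt attainment scores of
#' all matching attempts. When no attempt matches, the score is undefined
#' and `NA` is returned: an undefined score is materially different from 0,
#' which means every attempted milestone was attained.
#'
#' @param attempts Attempt records (see [score_attempts()]).
#' @param scale A `devsurv_scale`.
#' @param window Numeric length-2: window `[start, end)` in months.
#' @param domains Domain and/or group tokens (default: all four domains).
#' @param method `"lmas"` (default) or `"dmas"`.
#' @param include_end Include attempts at exactly `window[2]` (used for the
#'   final window of a schedule, e.g. 24-36 months).
#' @return A single numeric score in `[0, 4]`, or `NA` if no attempt matches.
#' @examples
#' sc <- dev_scale(data.frame(milestone_id = "m1", domain = "language",
#'                            t0 = 2, t75 = 6, t90 = 9, t95 = 12, t100 = 18))
#' at <- data.frame(child_id = "c1", milestone_id = "m1",
#'                  age_months = c(6, 10), attained = c(TRUE, FALSE))
#' dss(at, sc, window = c(0, 12), method = "dmas")   # mean(0, 3) = 1.5
#' @export
dss <- function(attempts, scale, window = c(0, 36), domains = DOMAINS,
                method = c("lmas", "dmas"), include_end = FALSE) {
  method <- match.arg(method)
  if (window[1] >= window[2]) stop("window start must be before end", call. = FALSE)
  scored <- score_attempts(attempts, scale)
  doms <- expand_domains(domains)
  keep <- scored$domain %in% doms &
    scored$age_months >= window[1] &
    (scored$age_months < window[2] |
       (include_end & scored$age_months == window[2]))
  if (!any(keep)) return(NA_real_)
  mean(scored[[method]][keep])
}

#' Per-child, per-window, per-domain-group DSS grid
#'
#' Computes the DSS of each child for each year-of-life window (0-12, 12-24,
#' 24-36 months; the last window closed at 36) crossed with each domain
#' group, as used in subpopulation comparisons. Cells with no matching
#' attempt are `NA`; nothing is imputed.
#'
#' @inheritParams dss
#' @param children Optional character vector restricting/ordering the child
#'   ids; defaults to every child present in `attempts`.
#' @param groups Character vector of domain/group tokens, each scored
#'   separately (default: the three groups of the subpopulation analyses).
#' @param windows A list of numeric length-2 windows; names label the rows.
#' @return A tibble `child_id`, `window`, `group`, `n_attempts`, `dss` (long
#'   form, one row per cell).
#' @export
score_table <- function(attempts, scale, children = NULL,
                        groups = c("gross_motor", "fine_motor", "language_social"),
                        windows = list(`0-12` = c(0, 12), `12-24` = c(12, 24),
                                       `24-36` = c(24, 36)),
                        method = c("lmas", "dmas")) {
  method <- match.arg(method)
  scored <- score_attempts(attempts, scale)
  if (is.null(children)) children <- sort(unique(scored$child_id))
  if (is.null(names(windows))) {
    names(windows) <- vapply(windows, function(w) paste(w, collapse = "-"), "")
  }
  last_end <- max(vapply(windows, `[`, numeric(1), 2))
  cells <- tidyr::expand_grid(
    child_id = children,
    window = names(windows),
    group = groups
  )
  rows <- lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    in_w <- scored$age_months >= w[1] &
      (scored$age_months < w[2] | (w[2] == last_end & scored$age_months == w[2]))
    sub <- scored[in_w, ]
    out <- lapply(groups, function(g) {
      doms <- expand_domains(g)
      gsub <- sub[sub$domain %in% doms & sub$child_id %in% children, ]
      agg <- dplyr::summarise(
        dplyr::group_by(gsub, .data$child_id),
        n_attempts = dplyr::n(),
        dss = mean(.data[[method]]),
        .groups = "drop"
      )
      agg$window <- wn
      agg$group <- g
      agg
    })
    dplyr::bind_rows(out)
  })
  grid <- dplyr::left_join(cells, dplyr::bind_rows(rows),
                           by = c("child_id", "window", "group"))
  grid$n_attempts[is.na(grid$n_attempts)] <- 0L
  grid
}
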