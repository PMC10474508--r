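# Age steps binning visits from birth to 36 months. Half-open [low, high),
# except the last step which is closed at 36; ages in [0, 1) (the
# post-discharge contact) fold into step 1.
STEP_BREAKS <- c(0, 3, 6, 9, 12, 18, 24, 36)
STEP_LABELS <- c("1-3", "3-6", "6-9", "9-12", "12-18", "18-24", "24-36")

#' Age steps of the surveillance schedule
#'
#' @return A tibble with columns `index` (1..7), `low`, `high` (months) and
#'   `label`. Intervals are `[low, high)` with the final step closed at 36.
#' @export
age_steps <- function() {
  tibble::tibble(
    index = 1:7,
    low = STEP_BREAKS[1:7],
    high = STEP_BREAKS[2:8],
    label = STEP_LABELS
  )
}

#' Age step containing an evaluation age
#'
#' Bins ages into the seven age steps 1-3, 3-6, 6-9, 9-12, 12-18, 18-24 and
#' 24-36 months under the half-open convention `[low, high)`, with 36 months
#' itself in step 7. Ages below 1 month fold into step 1; ages above 36
#' months fall outside the trajectory definition and map to `NA`.
#'
#' @param age Numeric vector of ages in months, all `>= 0`.
#' @return Integer vector of step indices in 1..7, `NA` above 36 months.
#' @examples
#' assign_step(c(0.5, 4.5, 12, 36))
#' @export
assign_step <- function(age) {
  if (any(age < 0)) stop("negative age", call. = FALSE)
  idx <- findInterval(age, STEP_BREAKS, rightmost.closed = TRUE)
  idx[age > 36] <- NA_integer_
  as.integer(idx)
}

#' Build Developmental Trajectory Vectors
#'
#' A child's developmental trajectory vector (DTV) for a domain group is the
#' series of its seven per-age-step DSS values: entry `k` is the mean
#' attainment score over the child's attempts evaluated at ages within step
#' `k`, restricted to the group's domains. Attempts are binned by the age at
#' which they were evaluated (a re-attempt of an earlier milestone at a
#' later visit lands in the later step, since scores are age-dependent by
#' construction). Steps with no attempt are `NA` and make the vector
#' incomplete.
#'
#' @inheritParams dss
#' @param domain_group `"motor"` or `"language_social"`.
#' @return A tibble with one row per child appearing in `attempts`:
#'   `child_id`, `domain_group`, `step1` .. `step7`, `complete`.
#' @seealso [filter_complete()], [cluster_dtvs()]
#' @export
build_dtvs <- function(attempts, scale,
                       domain_group = c("motor", "language_social"),
                       method = c("lmas", "dmas")) {
  domain_group <- match.arg(domain_group)
  method <- match.arg(method)
  scored <- score_attempts(attempts, scale)
  all_children <- sort(unique(scored$child_id))
  scored <- scored[scored$domain %in% DOMAIN_GROUPS[[domain_group]], ]
  scored$step <- assign_step(scored$age_months)
  scored <- scored[!is.na(scored$step), ]
  agg <- dplyr::summarise(
    dplyr::group_by(scored, .data$child_id, .data$step),
    dss = mean(.data[[method]]),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    agg,
    id_cols = "child_id",
    names_from = "step",
    names_prefix = "step",
    values_from = "dss"
  )
  # ensure all 7 step columns exist and every child is present
  for (k in 1:7) {
    col <- paste0("step", k)
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- dplyr::left_join(tibble::tibble(child_id = all_children), wide,
                           by = "child_id")
  wide <- wide[c("child_id", paste0("step", 1:7))]
  wide$domain_group <- domain_group
  wide$complete <- stats::complete.cases(wide[paste0("step", 1:7)])
  wide[c("child_id", "domain_group", paste0("step", 1:7), "complete")]
}

#' Keep only complete trajectory vectors
#'
#' Children missing data for one or more age steps are excluded from
#' trajectory clustering; the number excluded is reported via `message()`.
#'
#' @param dtvs Output of [build_dtvs()].
#' @return The complete subset of `dtvs`.
#' @export
filter_complete <- function(dtvs) {
  n_excl <- sum(!dtvs$complete)
  if (n_excl > 0) {
    message("excluding ", n_excl, " of ", nrow(dtvs),
            " children with incomplete trajectories")
    if (n_excl == nrow(dtvs)) {
      warning("no complete trajectory vectors remain", call. = FALSE)
    }
  }
  dtvs[dtvs$complete, ]
}

dtv_matrix <- function(dtvs) {
  m <- as.matrix(dtvs[paste0("step", 1:7)])
  rownames(m) <- dtvs$child_id
  m
}

#' Write / read trajectory vectors as CSV
#'
#' Plain CSV with columns `child_id,group,step1..step7,complete`; undefined
#' entries are empty cells.
#'
#' @param dtvs Output of [build_dtvs()].
#' @param path File path.
#' @return `path` (writer) or a DTV tibble (reader).
#' @export
write_dtvs <- function(dtvs, path) {
  out <- dtvs
  names(out)[names(out) == "domain_group"] <- "group"
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_dtvs
#' @export
read_dtvs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          child_id = readr::col_character(),
                          group = readr::col_character(),
                          complete = readr::col_logical(),
                          .default = readr::col_double()
                        ))
  names(df)[names(df) == "group"] <- "domain_group"
  df
}
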