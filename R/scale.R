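#' @importFrom rlang .data
#' @importFrom stats plogis qlogis rbinom rnorm runif setNames
NULL

# Canonical domain tokens and their two aggregation groups.
DOMAINS <- c("gross_motor", "fine_motor", "language", "personal_social")
DOMAIN_GROUPS <- list(
  motor           = c("gross_motor", "fine_motor"),
  language_social = c("language", "personal_social")
)

#' Expand domain or domain-group tokens to canonical domain tokens
#'
#' The four developmental domains are aggregated into two groups for
#' trajectory analysis: `motor` (gross + fine motor) and `language_social`
#' (language + personal-social). This helper accepts any mix of the four
#' domain tokens and the two group tokens and returns the corresponding set
#' of domains.
#'
#' @param domains Character vector of domain and/or group tokens.
#' @return Character vector of canonical domain tokens.
#' @examples
#' expand_domains("motor")
#' expand_domains(c("language", "fine_motor"))
#' @export
expand_domains <- function(domains) {
  out <- character(0)
  for (d in domains) {
    if (d %in% names(DOMAIN_GROUPS)) {
      out <- c(out, DOMAIN_GROUPS[[d]])
    } else if (d %in% DOMAINS) {
      out <- c(out, d)
    } else {
      stop("unknown domain or domain group: '", d, "'", call. = FALSE)
    }
  }
  unique(out)
}

#' Construct a developmental scale
#'
#' A developmental scale holds, per milestone, the developmental domain and
#' five age thresholds (in months): `t0` and `t100`, the minimal and maximal
#' ages at which the milestone is assessed, and `t75`, `t90`, `t95`, the ages
#' by which 75%, 90% and 95% of children attain it. The thresholds delimit
#' four consecutive severity brackets used for scoring failures.
#'
#' @param milestones A data frame with columns `milestone_id`, `domain`,
#'   `t0`, `t75`, `t90`, `t95`, `t100`. Ages are decimal months.
#' @return A validated `devsurv_scale` tibble.
#' @seealso [load_scale()], [milestone_brackets()], [bracket_of()]
#' @export
dev_scale <- function(milestones) {
  required <- c("milestone_id", "domain", "t0", "t75", "t90", "t95", "t100")
  missing_cols <- setdiff(required, names(milestones))
  if (length(missing_cols) > 0) {
    stop("scale is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scale <- tibble::as_tibble(milestones)[required]
  scale$milestone_id <- as.character(scale$milestone_id)
  scale$domain <- as.character(scale$domain)
  for (col in c("t0", "t75", "t90", "t95", "t100")) {
    scale[[col]] <- as.numeric(scale[[col]])
  }
  validate_scale(scale)
  class(scale) <- c("devsurv_scale", class(scale))
  scale
}

validate_scale <- function(scale) {
  if (nrow(scale) == 0) {
    warning("scale has no milestones", call. = FALSE)
    return(invisible(scale))
  }
  bad_domain <- !scale$domain %in% DOMAINS
  if (any(bad_domain)) {
    stop("unknown domain token for milestone(s): ",
         paste(scale$milestone_id[bad_domain], collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(scale$milestone_id)
  if (any(dup)) {
    stop("duplicated milestone_id: ",
         paste(unique(scale$milestone_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  thr <- as.matrix(scale[c("t0", "t75", "t90", "t95", "t100")])
  if (any(!is.finite(thr)) || any(thr < 0)) {
    bad <- scale$milestone_id[rowSums(!is.finite(thr) | thr < 0) > 0]
    stop("non-finite or negative threshold for milestone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  non_mono <- rowSums(thr[, -1, drop = FALSE] < thr[, -5, drop = FALSE]) > 0
  if (any(non_mono)) {
    stop("non-monotone thresholds (need t0 <= t75 <= t90 <= t95 <= t100) ",
         "for milestone(s): ",
         paste(scale$milestone_id[non_mono], collapse = ", "), call. = FALSE)
  }
  invisible(scale)
}

#' Read a developmental scale from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `milestone_id,domain,t0,t75,t90,t95,t100`; ages are decimal months and
#' domain tokens are one of `gross_motor`, `fine_motor`, `language`,
#' `personal_social`. Every row is validated (known domain, monotone
#' thresholds, unique ids). A header-only file yields an empty scale with a
#' warning, so scales can be built incrementally.
#'
#' @param path Path to the scale CSV.
#' @return A `devsurv_scale` tibble.
#' @export
load_scale <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dev_scale(df)
}

#' Write a developmental scale to CSV
#'
#' @param scale A `devsurv_scale`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  readr::write_csv(tibble::as_tibble(unclass_scale(scale)), path)
  invisible(path)
}

unclass_scale <- function(scale) {
  class(scale) <- setdiff(class(scale), "devsurv_scale")
  scale
}

#' Severity brackets of one milestone
#'
#' The five thresholds of a milestone define four consecutive age brackets:
#' `b1 = [t0, t75]`, `b2 = (t75, t90]`, `b3 = (t90, t95]`, `b4 = (t95, t100]`.
#' A failure in bracket `i` has discrete severity `i`. Brackets may be
#' degenerate (zero width) when consecutive thresholds coincide, e.g. for
#' step-like attainment curves; such brackets are flagged.
#'
#' @param milestone A single-row scale entry (or any list with fields
#'   `t0`, `t75`, `t90`, `t95`, `t100`).
#' @return A tibble with columns `index` (1..4), `low`, `high`, and
#'   `degenerate` (logical, `low == high`).
#' @export
milestone_brackets <- function(milestone) {
  thr <- as.numeric(milestone[c("t0", "t75", "t90", "t95", "t100")])
  out <- tibble::tibble(
    index = 1:4,
    low = thr[1:4],
    high = thr[2:5],
    degenerate = thr[1:4] == thr[2:5]
  )
  if (any(out$degenerate)) {
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Bracket index containing an evaluation age
#'
#' Maps an age to the severity bracket (1..4) of a milestone. Ages outside
#' `[t0, t100]` are clamped to the nearest endpoint first, since records can
#' fall slightly outside the assessed range. Brackets are low-open /
#' high-closed except bracket 1, which contains `t0`. When an age falls on a
#' shared boundary of degenerate brackets, the highest-index bracket whose
#' (closed) upper bound equals the age wins, which keeps the map total for
#' step-like threshold configurations.
#'
#' @param milestone A single-row scale entry.
#' @param age Numeric vector of ages in months.
#' @return Integer vector of bracket indices in 1..4.
#' @export
bracket_of <- function(milestone, age) {
  thr <- as.numeric(milestone[c("t0", "t75", "t90", "t95", "t100")])
  a <- pmin(pmax(age, thr[1]), thr[5])
  uppers <- thr[2:5]
  vapply(a, function(ai) {
    hit <- which(uppers == ai)
    if (length(hit) > 0) return(max(hit))
    1L + sum(ai > uppers[1:3])
  }, integer(1))
}

#' Derive percentile age thresholds from an attainment curve
#'
#' Given a nondecreasing curve of population attainment probability by age,
#' returns the smallest grid ages at which the curve reaches 75%, 90% and
#' 95% attainment — the thresholds an age-normed scale is built from.
#'
#' @param curve A function of age (months) returning attainment probability,
#'   nondecreasing on `grid`.
#' @param grid Numeric vector of ages (months), increasing.
#' @param milestone_id Optional id used in error messages.
#' @return Named numeric vector `c(t75 = , t90 = , t95 = )`, nondecreasing.
#' @examples
#' thresholds_from_curve(function(a) plogis(a - 9), seq(0, 20, by = 0.001))
#' @export
thresholds_from_curve <- function(curve, grid, milestone_id = NULL) {
  p <- curve(grid)
  if (any(diff(p) < -1e-9)) {
    stop("attainment curve is not nondecreasing on the grid",
         if (!is.null(milestone_id)) paste0(" for milestone '", milestone_id, "'"),
         call. = FALSE)
  }
  if (max(p) < 0.95) {
    stop("attainment curve never reaches 95%",
         if (!is.null(milestone_id)) paste0(" for milestone '", milestone_id, "'"),
         call. = FALSE)
  }
  out <- vapply(c(0.75, 0.90, 0.95), function(q) grid[min(which(p >= q))],
                numeric(1))
  setNames(out, c("t75", "t90", "t95"))
}

#' Convert day-counted ages to fractional months
#'
#' Ages are stored in fractional months using the mean Gregorian month of
#' 30.4375 days, so day-level visit records convert losslessly.
#'
#' @param days Numeric vector of ages in days.
#' @return Ages in months.
#' @export
days_to_months <- function(days) days / 30.4375
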