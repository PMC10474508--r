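#' Simulation configuration for a synthetic surveillance cohort
#'
#' Bundles the knobs of the synthetic generator. The defaults emulate the
#' structure of a national maternal-child-health-clinic (MCHC) surveillance
#' program: 59 milestones across 4 domains, visits at 1, 2, 4, 6, 9, 12,
#' 18, 24 and 36 months, covariate marginals resembling a population
#' registry, and a mixture of latent trajectory archetypes (adequate,
#' catching-up, worsening, with the remainder an unlabelled mid-trajectory
#' bump) whose proportions approximate the cluster fractions reported for
#' such cohorts.
#'
#' Each child carries a latent developmental *ability* curve, an age shift
#' in months: attainment of milestone `m` at age `a` is Bernoulli with
#' probability `curve_m(a + ability(a) * scale_m)`, where `scale_m` is the
#' milestone's sensitivity (proportional to the width of its attainment
#' curve). Negative ability makes the child behave like a younger child.
#' Covariate effects (in months of ability) add to the archetype curve.
#'
#' @param n_children Number of children.
#' @param n_milestones Number of milestones (default 59), allocated across
#'   domains and age steps; must be at least 4.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param archetype_mixture Named probabilities for `adequate`,
#'   `catching_up`, `worsening`; must sum to at most 1, the remainder is
#'   the `other` (bump) archetype.
#' @param covariate_effects Named list of effect sizes in months of latent
#'   ability (see Details); use `zero_effects()` for a null cohort.
#' @param visit_ages Scheduled visit ages in months.
#' @param retention Per-visit attendance probability in (0, 1].
#' @param visit_jitter Maximum delay (months) of an attended visit past its
#'   scheduled age, uniform at day resolution; 0 gives exact schedule ages.
#' @param ability_noise_sd SD (months) of the child-level ability noise.
#' @param prop_parent_report Fraction of attained attempts documented by
#'   parent report rather than clinic observation.
#' @return A list of class `devsurv_sim_config`.
#' @export
sim_config <- function(n_children = 1000,
                       n_milestones = 59,
                       seed = 1L,
                       archetype_mixture = c(adequate = 0.75,
                                             catching_up = 0.13,
                                             worsening = 0.04),
                       covariate_effects = default_effects(),
                       visit_ages = c(1, 2, 4, 6, 9, 12, 18, 24, 36),
                       retention = 0.95,
                       visit_jitter = 0.25,
                       ability_noise_sd = 0.08,
                       prop_parent_report = 0.1) {
  req <- c("adequate", "catching_up", "worsening")
  if (!all(req %in% names(archetype_mixture))) {
    stop("archetype_mixture needs named entries ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (sum(archetype_mixture) > 1 + 1e-12 || any(archetype_mixture < 0)) {
    stop("archetype_mixture must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  if (retention <= 0 || retention > 1) {
    stop("retention must be in (0, 1]", call. = FALSE)
  }
  if (n_milestones < 4) stop("need at least 4 milestones", call. = FALSE)
  structure(
    list(n_children = as.integer(n_children),
         n_milestones = as.integer(n_milestones),
         seed = as.integer(seed),
         archetype_mixture = archetype_mixture[req],
         covariate_effects = covariate_effects,
         visit_ages = sort(visit_ages),
         retention = retention,
         visit_jitter = visit_jitter,
         ability_noise_sd = ability_noise_sd,
         prop_parent_report = prop_parent_report),
    class = "devsurv_sim_config"
  )
}

#' Default covariate effect sizes (months of latent ability)
#'
#' Negative values delay development. The defaults produce the monotone
#' subgroup orderings reported in surveillance cohorts — boys slightly
#' behind girls, a dose-response with prematurity, a U-shaped birth-weight
#' effect, a maternal-education gradient, and small effects of maternal
#' age, postpartum depression and birth order.
#'
#' @return Named list of effects.
#' @export
default_effects <- function() {
  list(
    sex_male = -0.12,
    per_week_preterm = -0.05,     # per gestational week below 39.5
    low_birth_weight = -0.15,     # < 2.5 kg
    lownormal_birth_weight = -0.05, # 2.5-3 kg
    high_birth_weight = -0.12,    # > 4.5 kg
    education = c(academic = 0.08, tertiary = 0.02,
                  high_school = -0.06, elementary = -0.22),
    maternal_age_40 = -0.06,
    ppd = -0.08,
    per_birth_order = -0.02
  )
}

#' @rdname default_effects
#' @export
zero_effects <- function() {
  e <- default_effects()
  e[] <- lapply(e, function(v) v * 0)
  e
}

# --- scale generation ------------------------------------------------------

# How many months of ability shift correspond to one logistic width of a
# milestone's attainment curve; fixes the units of `ability`.
ABILITY_SCALE_REF <- 0.5

allocate_milestones <- function(n_milestones, steps_available) {
  n_motor <- max(2L, round(n_milestones * 30 / 59))
  n_ls <- n_milestones - n_motor
  if (n_ls < 2L) { n_ls <- 2L; n_motor <- n_milestones - 2L }
  alloc_group <- function(count, single_step) {
    counts <- integer(7)
    usable <- intersect(1:7, steps_available)
    if (length(usable) == 0) stop("no visit covers any age step", call. = FALSE)
    if (count >= length(usable)) {
      counts[usable] <- 1L
      extra <- count - length(usable)
      non_single <- setdiff(usable, single_step)
      if (length(non_single) == 0) non_single <- usable
      per <- extra %/% length(non_single)
      rem <- extra %% length(non_single)
      counts[non_single] <- counts[non_single] + per
      if (rem > 0) counts[non_single[seq_len(rem)]] <- counts[non_single[seq_len(rem)]] + 1L
    } else {
      counts[usable[seq_len(count)]] <- 1L
    }
    counts
  }
  list(motor = alloc_group(n_motor, 5L),
       language_social = alloc_group(n_ls, 3L))
}

#' Generate a synthetic age-normed developmental scale
#'
#' Builds `n_milestones` milestones with logistic attainment curves whose
#' midpoints are anchored to the visit schedule: each milestone is
#' scheduled at a visit of its age step, and its curve reaches 97-99.5%
#' attainment at that visit, so that a typical child attains the milestones
#' expected at their age. Curve width grows with age (early milestones have
#' sharp curves, later ones spread over months). The 75/90/95% age
#' thresholds are derived from the curve with [thresholds_from_curve()];
#' `t0` and `t100` are the bounds of the assessed age range. Under the
#' default allocation every age step holds several milestones per domain
#' group except one single-milestone step per group (step 5 for motor,
#' step 3 for language-social).
#'
#' @param config A [sim_config()].
#' @return A list with elements `scale` (a `devsurv_scale`) and `curves`
#'   (tibble of per-milestone curve parameters: `midpoint`, `slope`,
#'   `ability_scale`, scheduled `visit_age`, `step`, `domain_group`).
#' @export
generate_scale <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    visit_steps <- assign_step(config$visit_ages)
    if (any(is.na(visit_steps))) {
      stop("visit ages beyond 36 months are outside the trajectory schedule",
           call. = FALSE)
    }
    alloc <- allocate_milestones(config$n_milestones, unique(visit_steps))
    rows <- list()
    for (grp in names(alloc)) {
      doms <- DOMAIN_GROUPS[[grp]]
      counts <- alloc[[grp]]
      g_idx <- 0L
      for (s in which(counts > 0)) {
        step_visits <- config$visit_ages[visit_steps == s]
        for (j in seq_len(counts[s])) {
          g_idx <- g_idx + 1L
          rows[[length(rows) + 1]] <- tibble::tibble(
            domain = doms[(g_idx - 1L) %% length(doms) + 1L],
            domain_group = grp,
            step = s,
            visit_age = step_visits[(j - 1L) %% length(step_visits) + 1L]
          )
        }
      }
    }
    curves <- dplyr::bind_rows(rows)
    prefix <- c(gross_motor = "gm", fine_motor = "fm",
                language = "lg", personal_social = "ps")
    curves <- dplyr::mutate(
      dplyr::group_by(curves, .data$domain),
      milestone_id = sprintf("%s%02d", prefix[.data$domain[1]],
                             dplyr::row_number())
    )
    curves <- dplyr::ungroup(curves)
    n <- nrow(curves)
    curves$slope <- (0.12 + 0.045 * curves$visit_age) * runif(n, 0.85, 1.15)
    p_target <- runif(n, 0.993, 0.999)
    curves$midpoint <- curves$visit_age - curves$slope * qlogis(p_target)
    curves$ability_scale <- curves$slope / ABILITY_SCALE_REF

    thr <- t(mapply(function(mu, sl, id) {
      grid <- seq(max(0, mu - 6 * sl), mu + 8 * sl, by = sl / 200)
      thresholds_from_curve(function(a) plogis((a - mu) / sl), grid,
                            milestone_id = id)
    }, curves$midpoint, curves$slope, curves$milestone_id))
    scale <- dev_scale(tibble::tibble(
      milestone_id = curves$milestone_id,
      domain = curves$domain,
      t0 = pmax(0, curves$midpoint - 4 * curves$slope),
      t75 = thr[, "t75"],
      t90 = thr[, "t90"],
      t95 = thr[, "t95"],
      t100 = curves$midpoint + 8 * curves$slope
    ))
    list(scale = scale,
         curves = curves[c("milestone_id", "domain", "domain_group", "step",
                           "visit_age", "midpoint", "slope", "ability_scale")])
  })
}

# --- cohort generation -----------------------------------------------------

# Latent ability (months of age shift) at age a for each child row;
# vectorized over children x ages of equal length.
ability_at <- function(a, archetype, delta, center, width) {
  shift <- numeric(length(a))
  cu <- archetype == "catching_up"
  wo <- archetype == "worsening"
  ot <- archetype == "other"
  shift[cu] <- -delta[cu] * pmax(0, 12 - a[cu]) / 11
  shift[wo] <- -delta[wo] * pmax(0, a[wo] - 6) / 15
  shift[ot] <- -delta[ot] * exp(-((a[ot] - center[ot]) / width[ot])^2)
  shift
}

covariate_shift <- function(children, effects) {
  edu <- effects$education[children$maternal_education]
  edu[is.na(edu)] <- 0
  shift <- effects$sex_male * (children$sex == "male") +
    effects$per_week_preterm * pmax(0, 39.5 - children$gestational_age) +
    effects$low_birth_weight * (children$birth_weight < 2.5) +
    effects$lownormal_birth_weight *
      (children$birth_weight >= 2.5 & children$birth_weight < 3) +
    effects$high_birth_weight * (children$birth_weight > 4.5) +
    unname(edu) +
    effects$maternal_age_40 * (children$maternal_age >= 40) +
    effects$ppd * dplyr::coalesce(children$ppd, FALSE) +
    effects$per_birth_order * (children$birth_order - 1)
  shift
}

draw_covariates <- function(n) {
  ga_weeks <- 23:42
  ga_probs <- c(rep(0.0015 / 4, 4),            # 23-26: extremely preterm
                rep(0.0055 / 5, 5),            # 27-31: very preterm
                rep(0.062 / 5, 5),             # 32-36: late preterm
                rep(0.242 / 2, 2),             # 37-38: early term
                rep(0.689 / 4, 4))             # 39-42: full term
  ga <- sample(ga_weeks, n, replace = TRUE, prob = ga_probs)
  bw <- round(pmin(6, pmax(1, 3.3 + 0.12 * (ga - 39.5) + rnorm(n, 0, 0.42))), 2)
  edu_lv <- c("academic", "tertiary", "high_school", "elementary")
  edu <- sample(edu_lv, n, replace = TRUE, prob = c(0.438, 0.149, 0.383, 0.03))
  edu[runif(n) < 0.08] <- NA
  epds_total <- stats::rpois(n, 5)
  epds_q10 <- ifelse(runif(n) < 0.012, sample(1:3, n, replace = TRUE), 0L)
  epds_missing <- runif(n) < 0.1
  epds_total[epds_missing] <- NA
  epds_q10[epds_missing] <- NA
  tibble::tibble(
    child_id = sprintf("c%06d", seq_len(n)),
    sex = ifelse(runif(n) < 0.488, "female", "male"),
    gestational_age = ga,
    birth_weight = bw,
    birth_order = sample(1:6, n, replace = TRUE,
                         prob = c(0.36, 0.33, 0.19, 0.08, 0.03, 0.01)),
    maternal_age = pmin(50, pmax(18, round(rnorm(n, 32.5, 6.5)))),
    maternal_education = edu,
    epds_total = epds_total,
    epds_q10 = epds_q10,
    ppd = ppd_flag(epds_total, epds_q10)
  )
}

#' Generate a synthetic surveillance cohort
#'
#' Draws child covariates from marginals resembling a population registry,
#' assigns each child a latent trajectory archetype and ability curve, and
#' simulates milestone attempts over the MCHC visit schedule: each
#' milestone is attempted at its scheduled visit (when attended),
#' attainment is Bernoulli with probability
#' `curve_m(age + ability(age) * scale_m)`, and a failed milestone is
#' re-attempted once at the child's next attended visit. The planted
#' per-child truth (archetype and ability parameters) is returned for
#' recovery testing.
#'
#' @param scale_obj Output of [generate_scale()] (list with `scale` and
#'   `curves`).
#' @param config The same [sim_config()] used for the scale.
#' @return A list with `children` (covariates incl. a `dev_tracking` flag),
#'   `attempts` (attempt records), and `truth` (per-child archetype and
#'   ability parameters).
#' @export
generate_cohort <- function(scale_obj, config = sim_config()) {
  curves <- scale_obj$curves
  withr::with_seed(config$seed + 1L, {
    n <- config$n_children
    children <- draw_covariates(n)

    mix <- config$archetype_mixture
    archetype <- sample(c(names(mix), "other"), n, replace = TRUE,
                        prob = c(mix, max(0, 1 - sum(mix))))
    delta <- numeric(n)
    delta[archetype == "catching_up"] <-
      pmax(2.2, rnorm(sum(archetype == "catching_up"), 2.8, 0.3))
    delta[archetype == "worsening"] <-
      pmax(1.8, rnorm(sum(archetype == "worsening"), 2.2, 0.25))
    delta[archetype == "other"] <-
      pmax(1.8, rnorm(sum(archetype == "other"), 2.2, 0.3))
    center <- runif(n, 6, 10)
    width <- rep(3, n)
    noise <- rnorm(n, 0, config$ability_noise_sd)
    cov_shift <- covariate_shift(children, config$covariate_effects)

    track_prob <- c(adequate = 0.01, catching_up = 0.045,
                    worsening = 0.25, other = 0.06)
    children$dev_tracking <- runif(n) < track_prob[archetype]

    truth <- tibble::tibble(
      child_id = children$child_id,
      archetype = archetype,
      delta = delta,
      bump_center = ifelse(archetype == "other", center, NA_real_),
      bump_width = ifelse(archetype == "other", width, NA_real_),
      ability_noise = noise,
      covariate_shift = cov_shift
    )

    # attended visits with jittered day-level ages
    n_visits <- length(config$visit_ages)
    visits <- tidyr::expand_grid(child_id = children$child_id,
                                 visit_idx = seq_len(n_visits))
    visits$scheduled <- config$visit_ages[visits$visit_idx]
    visits <- visits[runif(nrow(visits)) < config$retention, ]
    # visits happen at or shortly after the due age (day resolution), so a
    # jittered visit stays inside its scheduled age step
    jit <- if (config$visit_jitter > 0) {
      days_to_months(floor(runif(nrow(visits)) * config$visit_jitter * 30.4375))
    } else 0
    visits$age <- visits$scheduled + jit
    visits <- dplyr::arrange(visits, .data$child_id, .data$visit_idx)
    visits <- dplyr::mutate(dplyr::group_by(visits, .data$child_id),
                            next_age = dplyr::lead(.data$age))
    visits <- dplyr::ungroup(visits)

    child_par <- tibble::tibble(
      child_id = children$child_id, archetype = archetype, delta = delta,
      center = center, width = width,
      base_shift = noise + cov_shift
    )

    sched <- dplyr::inner_join(
      visits,
      dplyr::mutate(curves,
                    visit_idx = match(.data$visit_age, config$visit_ages))[
        c("milestone_id", "visit_idx", "midpoint", "slope")],
      by = "visit_idx", relationship = "many-to-many"
    )
    sched <- dplyr::left_join(sched, child_par, by = "child_id")

    draw_attempts <- function(df, age) {
      shift <- ability_at(age, df$archetype, df$delta, df$center, df$width) +
        df$base_shift
      p <- plogis((age - df$midpoint) / df$slope + shift / ABILITY_SCALE_REF)
      tibble::tibble(
        child_id = df$child_id,
        milestone_id = df$milestone_id,
        age_months = round(age, 4),
        attained = runif(nrow(df)) < p
      )
    }

    first_try <- draw_attempts(sched, sched$age)
    retry_rows <- sched[!first_try$attained & !is.na(sched$next_age), ]
    retries <- draw_attempts(retry_rows, retry_rows$next_age)
    attempts <- dplyr::bind_rows(first_try, retries)
    attempts <- dplyr::arrange(attempts, .data$child_id, .data$age_months,
                               .data$milestone_id)
    attempts$source <- "observed"
    flip <- attempts$attained & runif(nrow(attempts)) < config$prop_parent_report
    attempts$source[flip] <- "parent_report"

    list(children = children, attempts = attempts, truth = truth)
  })
}

# --- plain-text I/O --------------------------------------------------------

#' Read and write cohort tables as CSV
#'
#' Attempts CSV: `child_id,milestone_id,age_months,attained,source` with
#' `attained` as 0/1. Children CSV carries the covariate columns. Truth CSV
#' (`child_id,archetype,delta,bump_center,bump_width,ability_noise,
#' covariate_shift`) stores the planted per-child ground truth for
#' recovery tests.
#'
#' @param attempts,children,truth Tibbles as produced by
#'   [generate_cohort()].
#' @param path File path.
#' @return The writer returns `path` invisibly; readers return a tibble.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_attempts <- function(attempts, path) {
  out <- attempts
  out$attained <- as.integer(out$attained)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_attempts <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          child_id = readr::col_character(),
                          milestone_id = readr::col_character()))
  df$attained <- as.logical(df$attained)
  df
}

#' @rdname cohort_io
#' @export
write_children <- function(children, path) {
  readr::write_csv(children, path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_children <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(child_id = readr::col_character()))
}

#' @rdname cohort_io
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(child_id = readr::col_character(),
                                          archetype = readr::col_character()))
}
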