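#' Age-group BMD and daily-activity loading catalogs
#'
#' Mean apparent BMD of proximal trabecular bone by age group (g/cm^3) and
#' mean hip contact load by activity of daily living (body-weight multiples;
#' 1 BW is taken as roughly 750 N, recorded as metadata only — all
#' computation stays in BW multiples).
#'
#' @return `age_groups()`: named numeric vector of BMD means;
#'   `activities()`: named numeric vector of BW means.
#' @examples
#' age_groups()
#' activities()
#' @export
age_groups <- function() {
  c("50-64" = 0.3375, "65-79" = 0.2875, ">=80" = 0.275)
}

#' @rdname age_groups
#' @export
activities <- function() {
  c("normal walking" = 2.38, "up stairs" = 2.51, "down stairs" = 2.60,
    "standing up" = 1.90, "sitting down" = 1.56)
}

#' Newtons per body-weight multiple (metadata only)
#' @return 750, the assumed hip contact force of one body weight in N.
#' @export
newtons_per_bw <- function() 750

#' Build a failure scenario
#'
#' Combines an age group (BMD mean from the catalog), an activity (BW mean
#' from the catalog), and coefficients of variation for both into the input
#' random variables of one reliability computation.
#'
#' @param age_group Name from [age_groups()].
#' @param activity Name from [activities()].
#' @param cov_bmd,cov_bw Coefficients of variation, in (0, 1] for the
#'   catalog sweeps.
#' @param criterion A [yield_criterion()]; defaults to 0.85% +/- 0.10%.
#' @return A `scenario`: list with `age_group`, `activity`, `bmd`, `bw`
#'   (both [random_variable()]), `cov_bmd`, `cov_bw`, `criterion`.
#' @examples
#' build_scenario("50-64", "normal walking", 0.1, 0.1)
#' @export
build_scenario <- function(age_group, activity, cov_bmd, cov_bw,
                           criterion = yield_criterion()) {
  ag <- age_groups()
  ac <- activities()
  if (!age_group %in% names(ag)) {
    stop("unknown age group '", age_group, "'; valid: ",
         paste(names(ag), collapse = ", "))
  }
  if (!activity %in% names(ac)) {
    stop("unknown activity '", activity, "'; valid: ",
         paste(names(ac), collapse = ", "))
  }
  if (cov_bmd <= 0 || cov_bw <= 0) stop("COV values must be positive")
  structure(
    list(age_group = age_group, activity = activity,
         bmd = from_mean_cov(ag[[age_group]], cov_bmd, "BMD"),
         bw = from_mean_cov(ac[[activity]], cov_bw, "BW"),
         cov_bmd = cov_bmd, cov_bw = cov_bw, criterion = criterion),
    class = "scenario")
}

#' Probability of failure for one scenario
#'
#' @param scenario A [build_scenario()] result.
#' @param model A [quadratic_response_model()]; defaults to the published
#'   surrogate.
#' @param mode Propagation mode, see [strain_moments()].
#' @return A `performance_summary`.
#' @export
scenario_pof <- function(scenario, model = published_model(),
                         mode = c("paper_termwise", "taylor_first_order",
                                  "exact_moments")) {
  stopifnot(inherits(scenario, "scenario"))
  mode <- match.arg(mode)
  pof_analytic(strain_moments(model, scenario$bmd, scenario$bw, mode),
               scenario$criterion, mode = mode)
}

#' Sweep probability of failure over scenarios
#'
#' Evaluates every combination of age group, activity and COV grid cell in
#' the requested propagation mode. Deterministic for the analytic modes.
#'
#' @param model A [quadratic_response_model()].
#' @param age_group_names Subset of [age_groups()] names.
#' @param activity_names Subset of [activities()] names.
#' @param cov_grid COV values used for both BMD and BW axes (default
#'   0.1 to 0.9 in steps of 0.1, the catalog range).
#' @param mode Propagation mode.
#' @param criterion A [yield_criterion()].
#' @return A `sweep_result` data frame with one row per grid cell: columns
#'   `age_group`, `activity`, `cov_bmd`, `cov_bw`, `mode`, `mu_S`, `sigma_S`,
#'   `mu_Z`, `sigma_Z`, `beta`, `pof`.
#' @examples
#' sw <- sweep_pof(published_model(), "50-64", "normal walking",
#'                 cov_grid = c(0.1, 0.9))
#' sw[, c("cov_bmd", "cov_bw", "pof")]
#' @export
sweep_pof <- function(model = published_model(),
                      age_group_names = names(age_groups()),
                      activity_names = names(activities()),
                      cov_grid = seq(0.1, 0.9, by = 0.1),
                      mode = c("paper_termwise", "taylor_first_order",
                               "exact_moments"),
                      criterion = yield_criterion()) {
  mode <- match.arg(mode)
  grid <- expand.grid(age_group = age_group_names,
                      activity = activity_names,
                      cov_bmd = cov_grid, cov_bw = cov_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- build_scenario(grid$age_group[i], grid$activity[i],
                         grid$cov_bmd[i], grid$cov_bw[i], criterion)
    as.data.frame(scenario_pof(sc, model, mode))
  })
  out <- cbind(grid, do.call(rbind, res))
  out$n_mc <- NULL
  out$seed <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write a sweep to CSV or JSON
#'
#' @param x A `sweep_result`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Contour plot of PoF over the COV grid
#'
#' One panel per (age group, activity): filled contours of PoF over
#' (COV_BMD, COV_BW), the layout used to report the scenario sweeps.
#'
#' @param sweep A `sweep_result` restricted to one age group and activity.
#' @param ... Passed to [graphics::filled.contour()].
#' @return Invisibly, the PoF matrix plotted.
#' @export
plot_pof_contour <- function(sweep, ...) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (length(unique(sweep$age_group)) != 1L ||
      length(unique(sweep$activity)) != 1L) {
    stop("restrict the sweep to a single age group and activity first")
  }
  xs <- sort(unique(sweep$cov_bmd))
  ys <- sort(unique(sweep$cov_bw))
  z <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_len(nrow(sweep))) {
    z[match(sweep$cov_bmd[i], xs), match(sweep$cov_bw[i], ys)] <-
      sweep$pof[i]
  }
  graphics::filled.contour(
    xs, ys, z, xlab = "COV of BMD", ylab = "COV of BW",
    main = sprintf("PoF: %s, %s", sweep$age_group[1], sweep$activity[1]),
    ...)
  invisible(z)
}

#' Headline reliability numbers
#'
#' Recomputes the reference cells of the scenario analysis with the published
#' surrogate, reporting the term-wise FOSM value (replication mode) and the
#' exact-moment value side by side, in percent. The cells are the
#' (50-64, normal walking) corners of the COV grid plus the grid-wide
#' maximum; `pof_threshold` (default 5%) flags cells in the commonly used
#' "acceptable risk" regime.
#'
#' @param model A [quadratic_response_model()].
#' @param criterion A [yield_criterion()].
#' @param pof_threshold Reporting threshold on PoF (fraction).
#' @return Data frame with columns `cell`, `age_group`, `activity`,
#'   `cov_bmd`, `cov_bw`, `pof_termwise_pct`, `pof_exact_pct`, `acceptable`.
#' @export
headline_numbers <- function(model = published_model(),
                             criterion = yield_criterion(),
                             pof_threshold = 0.05) {
  cells <- data.frame(
    cell = c("walking, low COVs", "walking, high BW COV",
             "walking, high BMD COV", "walking, both COVs high"),
    age_group = "50-64", activity = "normal walking",
    cov_bmd = c(0.1, 0.1, 0.9, 0.9), cov_bw = c(0.1, 0.9, 0.1, 0.9),
    stringsAsFactors = FALSE)
  tw <- ex <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- build_scenario(cells$age_group[i], cells$activity[i],
                         cells$cov_bmd[i], cells$cov_bw[i], criterion)
    tw[i] <- scenario_pof(sc, model, "paper_termwise")$pof
    ex[i] <- scenario_pof(sc, model, "exact_moments")$pof
  }
  sw <- sweep_pof(model, mode = "paper_termwise", criterion = criterion)
  imax <- which.max(sw$pof)
  sw_ex <- sweep_pof(model, age_group_names = sw$age_group[imax],
                     activity_names = sw$activity[imax],
                     cov_grid = unique(c(sw$cov_bmd[imax], sw$cov_bw[imax])),
                     mode = "exact_moments", criterion = criterion)
  ex_max <- sw_ex$pof[sw_ex$cov_bmd == sw$cov_bmd[imax] &
                        sw_ex$cov_bw == sw$cov_bw[imax]]
  out <- rbind(
    cbind(cells, pof_termwise_pct = 100 * tw, pof_exact_pct = 100 * ex),
    data.frame(cell = "grid maximum",
               age_group = sw$age_group[imax], activity = sw$activity[imax],
               cov_bmd = sw$cov_bmd[imax], cov_bw = sw$cov_bw[imax],
               pof_termwise_pct = 100 * sw$pof[imax],
               pof_exact_pct = 100 * ex_max))
  out$acceptable <- out$pof_termwise_pct <= 100 * pof_threshold
  out
}
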