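#' Equating bias across replications
#'
#' Mean signed deviation of replicated estimates from the true value:
#' systematic error. No absolute value or sign flip is applied.
#'
#' @param estimates Numeric vector of estimates, one per replication.
#' @param truth True value (scalar).
#' @return Scalar bias.
#' @export
eq_bias <- function(estimates, truth) {
  check_reps(estimates)
  mean(estimates - truth)
}

#' Standard error of equating across replications
#'
#' Root mean squared deviation of the estimates from their replication
#' mean (divisor R): random sampling error. Translation-invariant.
#'
#' @inheritParams eq_bias
#' @return Scalar SEE.
#' @export
eq_see <- function(estimates) {
  check_reps(estimates)
  sqrt(mean((estimates - mean(estimates))^2))
}

#' Root mean square equating error across replications
#'
#' Total error: root mean of squared deviations from truth. With the
#' divisor-R definitions, `rmse^2 = bias^2 + see^2` exactly.
#'
#' @inheritParams eq_bias
#' @return Scalar RMSE.
#' @export
eq_rmse <- function(estimates, truth) {
  check_reps(estimates)
  sqrt(mean((estimates - truth)^2))
}

check_reps <- function(estimates) {
  if (length(estimates) == 0L || any(!is.finite(estimates))) {
    stop("`estimates` must be a non-empty finite vector", call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarise replication estimates into a condition table
#'
#' Computes bias, SEE and RMSE per parameter and then aggregates to one
#' row per fitted model and parameter family, in the shape of a
#' condition-table cell. Item parameters: each statistic is computed per
#' item across replications, then averaged (unweighted, signed mean for
#' bias) over the items in scope. Abilities: statistics are pooled over
#' persons within each replication (each replication draws new
#' examinees), then averaged across replications.
#'
#' @param run A `condition_run` from [run_condition()], or a list with
#'   tibbles `item_estimates` (rep, model, item_id, form, anchor,
#'   testlet_id, param, truth, estimate) and `ability_estimates`
#'   (rep, model, group, truth, estimate).
#' @param item_scope Which items enter the item-parameter summaries:
#'   `"new_testlet"` (default; the new form's non-anchor testlet items —
#'   the equated items of interest), `"all_testlet"` (every testlet item
#'   including anchors), `"anchor_testlet"`, or `"all"`.
#' @param ability_scope `"new"` (default; new-form examinees) or `"all"`.
#' @return A tibble with columns model, param, bias, see, rmse, n_units,
#'   scope.
#' @export
summarize_condition <- function(run,
                                item_scope = c("new_testlet", "all_testlet",
                                               "anchor_testlet", "all"),
                                ability_scope = c("new", "all")) {
  item_scope <- match.arg(item_scope)
  ability_scope <- match.arg(ability_scope)
  it <- run$item_estimates
  ab <- run$ability_estimates

  keep <- switch(item_scope,
    new_testlet = !is.na(it$testlet_id) & !it$anchor & it$form != "base",
    all_testlet = !is.na(it$testlet_id),
    anchor_testlet = !is.na(it$testlet_id) & it$anchor,
    all = rep(TRUE, nrow(it))
  )
  item_tab <- NULL
  if (any(keep)) item_tab <- it[keep, ] |>
    dplyr::group_by(.data$model, .data$param, .data$item_id) |>
    dplyr::summarise(
      bias = eq_bias(.data$estimate, .data$truth[1]),
      see = eq_see(.data$estimate),
      rmse = eq_rmse(.data$estimate, .data$truth[1]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$model, .data$param) |>
    dplyr::summarise(dplyr::across(c("bias", "see", "rmse"), mean),
                     n_units = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(scope = item_scope)

  ability_tab <- NULL
  if (!is.null(ab) && nrow(ab) > 0) {
    if (ability_scope == "new") ab <- dplyr::filter(ab, .data$group == 2L)
    ability_tab <- ab |>
      dplyr::group_by(.data$model, .data$rep) |>
      dplyr::summarise(
        bias = mean(.data$estimate - .data$truth),
        rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
        see = sqrt(pmax(rmse^2 - bias^2, 0)),
        n = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(param = "theta",
                       dplyr::across(c("bias", "see", "rmse"), mean),
                       n_units = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(scope = ability_scope)
  }
  dplyr::bind_rows(item_tab, ability_tab)
}
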