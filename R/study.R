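#' Deterministic per-replication seed derivation
#'
#' Splits one master seed into independent, reproducible streams by a
#' documented linear-congruential hash of (master seed, condition index,
#' replication index). Replication `r` of condition `c` always receives
#' the same seed, so any single replication can be re-run in isolation;
#' all values stay below 2^31.
#'
#' @param master Integer master seed.
#' @param condition_index Integer condition position (0 reserved for
#'   condition-level draws such as the form pair).
#' @param rep_index Integer replication number (0 reserved likewise).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, condition_index = 0L, rep_index = 0L) {
  m <- 2147483587
  as.integer(((master %% m) * 48271 + condition_index * 7919 +
                rep_index * 104729) %% m)
}

default_families <- function(study) {
  if (study == "dichotomous") c("2PLM", "2PTM") else c("GRM", "GRTM")
}

#' Run all replications of one simulation condition
#'
#' For each replication: draw both examinee groups, generate responses
#' under the testlet model (the generating truth always carries testlet
#' effects), assemble the concurrent NEAT matrix, fit every requested
#' model family *to the same data* (a paired comparison that removes
#' Monte Carlo noise from model contrasts), EAP-score every examinee,
#' and align estimates with the generating truth. The form pair is built
#' once from the condition seed (set `resample_forms` in the condition to
#' redraw it each replication). A replication whose fit fails is
#' recorded and excluded from summaries; the run continues.
#'
#' @param condition A [simulation_condition()].
#' @param fit_families Character vector of model families to fit; default
#'   both families of the condition's study (e.g. 2PLM and 2PTM).
#' @param control A [calib_control()] passed to every fit.
#' @param condition_index Integer index used in seed derivation (see
#'   [derive_seed()]).
#' @param form_pair Optional fixed form pair (e.g. from
#'   [printed_form_pair()]) used instead of sampling one from the
#'   condition's distributions. With `resample_forms` set in the
#'   condition, the item parameters stay fixed but each replication
#'   redraws the testlet variances from the condition's effect level, so
#'   summaries average over the variance range rather than one draw.
#' @param progress Print one line per replication.
#' @return A `condition_run` list: tibbles `item_estimates`
#'   (rep, model, item_id, form, anchor, testlet_id, param, truth,
#'   estimate), `ability_estimates` (rep, model, person, group, truth,
#'   estimate), `testlet_estimates` (rep, model, testlet_id, truth,
#'   estimate), `failures`, plus `form_pair`, `condition` and the
#'   per-replication `seeds`.
#' @export
run_condition <- function(condition, fit_families = NULL,
                          control = calib_control(),
                          condition_index = 1L, form_pair = NULL,
                          progress = FALSE) {
  stopifnot(inherits(condition, "simulation_condition"))
  fit_families <- fit_families %||% default_families(condition$study)
  ok <- if (condition$study == "dichotomous") c("2PLM", "2PTM")
        else c("GRM", "GRTM")
  if (!all(fit_families %in% ok)) {
    stop("fit families must match the study's item type", call. = FALSE)
  }

  set.seed(derive_seed(condition$seed, condition_index, 0L))
  form <- form_pair %||% build_form_pair(condition)

  truth_items <- tidyr::pivot_longer(
    form$items, cols = dplyr::matches("^a$|^b[0-9]*$"),
    names_to = "param", values_to = "truth"
  )

  item_out <- list(); abil_out <- list(); tl_out <- list(); fail_out <- list()
  seeds <- integer(condition$n_replications)

  for (r in seq_len(condition$n_replications)) {
    seeds[r] <- derive_seed(condition$seed, condition_index, r)
    set.seed(seeds[r])
    if (condition$resample_forms) {
      if (is.null(form_pair)) {
        if (r > 1L) {
          form <- build_form_pair(condition)
          truth_items <- tidyr::pivot_longer(
            form$items, cols = dplyr::matches("^a$|^b[0-9]*$"),
            names_to = "param", values_to = "truth"
          )
        }
      } else {
        form$testlets$sigma2 <- draw_testlet_variances(
          condition$testlet_effect, nrow(form$testlets))
      }
    }
    base_items <- form_items(form, "base")
    new_items <- form_items(form, "new")
    tl_b <- form$testlets[form$testlets$testlet_id %in% base_items$testlet_id, ]
    tl_n <- form$testlets[form$testlets$testlet_id %in% new_items$testlet_id, ]
    p_b <- sample_persons(condition$sample_size, "base", tl_b)
    p_n <- sample_persons(condition$sample_size, "new", tl_n,
                          condition$new_form_mean_shift)
    resp <- assemble_concurrent(generate_responses(base_items, p_b),
                                generate_responses(new_items, p_n),
                                form)
    truth_theta <- c(p_b$theta, p_n$theta)

    for (fam in fit_families) {
      fit <- tryCatch(fit_concurrent(resp, form, fam, control),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        fail_out[[length(fail_out) + 1L]] <-
          tibble::tibble(rep = r, model = fam,
                         message = conditionMessage(fit))
        next
      }
      est <- tidy(fit) |>
        dplyr::select("item_id", param = "term", estimate = "estimate") |>
        dplyr::filter(!is.na(.data$estimate)) |>
        dplyr::inner_join(truth_items |>
                            dplyr::select("item_id", "form", "anchor",
                                          "testlet_id", "param", "truth"),
                          by = c("item_id", "param"))
      item_out[[length(item_out) + 1L]] <-
        dplyr::mutate(est, rep = r, model = fam)

      sc <- eap_score(resp, fit, control)
      abil_out[[length(abil_out) + 1L]] <- tibble::tibble(
        rep = r, model = fam, person = sc$person, group = sc$group,
        truth = truth_theta, estimate = sc$theta_eap
      )
      if (nrow(fit$testlets)) {
        tl_out[[length(tl_out) + 1L]] <- tibble::tibble(
          rep = r, model = fam,
          testlet_id = fit$testlets$testlet_id,
          truth = form$testlets$sigma2[
            match(fit$testlets$testlet_id, form$testlets$testlet_id)],
          estimate = fit$testlets$sigma2
        )
      }
      if (progress) {
        message(sprintf("rep %d %s: logLik %.1f, %d cycles%s", r, fam,
                        fit$logLik, fit$n_cycles,
                        if (fit$converged) "" else " (not converged)"))
      }
    }
  }

  structure(
    list(condition = condition,
         form_pair = form,
         item_estimates = dplyr::bind_rows(item_out),
         ability_estimates = dplyr::bind_rows(abil_out),
         testlet_estimates = dplyr::bind_rows(tl_out),
         failures = if (length(fail_out)) dplyr::bind_rows(fail_out)
                    else tibble::tibble(rep = integer(), model = character(),
                                        message = character()),
         seeds = seeds),
    class = "condition_run"
  )
}

#' @export
print.condition_run <- function(x, ...) {
  print(x$condition)
  cat("  replications stored:", length(x$seeds),
      "| fit failures:", nrow(x$failures), "\n")
  invisible(x)
}

#' Configure a full factorial study
#'
#' The factorial grid of one simulation study: testlet-effect levels x
#' testlet lengths x sample sizes, each cell fit with both model
#' families of the study.
#'
#' @inheritParams simulation_condition
#' @param testlet_effects,testlet_lengths,sample_sizes Factor levels
#'   (defaults are the full design grid).
#' @param master_seed Master seed split across conditions and
#'   replications via [derive_seed()].
#' @return A `study_config` list.
#' @export
study_config <- function(study = c("dichotomous", "polytomous"),
                         testlet_effects = c("low", "moderate", "high"),
                         testlet_lengths = c(5, 10),
                         sample_sizes = c(1000, 2000),
                         n_replications = 500,
                         master_seed = 1L,
                         new_form_mean_shift = 0.5,
                         n_categories = 5,
                         resample_forms = FALSE) {
  study <- match.arg(study)
  if (!length(testlet_effects) || !length(testlet_lengths) ||
      !length(sample_sizes)) {
    stop("factor grids must be non-empty", call. = FALSE)
  }
  structure(
    list(study = study, testlet_effects = testlet_effects,
         testlet_lengths = testlet_lengths, sample_sizes = sample_sizes,
         n_replications = n_replications, master_seed = as.integer(master_seed),
         new_form_mean_shift = new_form_mean_shift,
         n_categories = n_categories, resample_forms = resample_forms),
    class = "study_config"
  )
}

#' Enumerate the conditions of a study grid
#'
#' @param config A [study_config()].
#' @return Tibble of conditions with a `condition_index` column.
#' @export
study_grid <- function(config) {
  g <- tidyr::expand_grid(
    testlet_effect = config$testlet_effects,
    testlet_length = config$testlet_lengths,
    sample_size = config$sample_sizes
  )
  dplyr::mutate(g, condition_index = dplyr::row_number(),
                study = config$study)
}

#' Run a full factorial simulation study
#'
#' Iterates the study grid, runs every condition with both model
#' families, summarises each into bias/SEE/RMSE rows, and (optionally)
#' writes delimited summary tables plus a JSON manifest of seeds and
#' failures. Condition-level failures are reported and skipped; the run
#' continues.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory for `summary.tsv`, one wide table per
#'   parameter family, and `manifest.json`; NULL (default) writes nothing.
#' @param control A [calib_control()].
#' @param item_scope,ability_scope Passed to [summarize_condition()].
#' @param keep_runs Keep every `condition_run` in the result (memory!).
#' @param progress Print per-condition progress.
#' @return A `study_result` list with `summaries` (long tibble keyed by
#'   condition factors), `manifest`, and optionally `runs`.
#' @export
run_study <- function(config, out_dir = NULL, control = calib_control(),
                      item_scope = "new_testlet", ability_scope = "new",
                      keep_runs = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- study_grid(config)
  sums <- list(); runs <- list(); manifest_conditions <- list()

  for (i in seq_len(nrow(grid))) {
    cond <- simulation_condition(
      study = config$study,
      testlet_effect = grid$testlet_effect[i],
      testlet_length = grid$testlet_length[i],
      sample_size = grid$sample_size[i],
      n_replications = config$n_replications,
      seed = config$master_seed,
      new_form_mean_shift = config$new_form_mean_shift,
      n_categories = config$n_categories,
      resample_forms = config$resample_forms
    )
    if (progress) {
      message(sprintf("condition %d/%d: effect %s, length %d, n %d",
                      i, nrow(grid), cond$testlet_effect,
                      cond$testlet_length, cond$sample_size))
    }
    run <- tryCatch(
      run_condition(cond, control = control, condition_index = i,
                    progress = progress),
      error = function(e) e
    )
    if (inherits(run, "error")) {
      warning("condition ", i, " failed: ", conditionMessage(run),
              call. = FALSE)
      manifest_conditions[[i]] <- list(condition_index = i,
                                       error = conditionMessage(run))
      next
    }
    s <- summarize_condition(run, item_scope = item_scope,
                             ability_scope = ability_scope)
    sums[[i]] <- dplyr::mutate(s,
                               testlet_effect = cond$testlet_effect,
                               testlet_length = cond$testlet_length,
                               sample_size = cond$sample_size,
                               condition_index = i)
    manifest_conditions[[i]] <- list(
      condition_index = i,
      testlet_effect = cond$testlet_effect,
      testlet_length = cond$testlet_length,
      sample_size = cond$sample_size,
      seeds = run$seeds,
      n_failures = nrow(run$failures)
    )
    if (keep_runs) runs[[i]] <- run
  }

  summaries <- dplyr::bind_rows(sums)
  manifest <- list(
    study = config$study,
    master_seed = config$master_seed,
    n_replications = config$n_replications,
    new_form_mean_shift = config$new_form_mean_shift,
    package_version = as.character(utils::packageVersion("testleteq")),
    conditions = manifest_conditions
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summaries, file.path(out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (p in unique(summaries$param)) {
      wide <- format_condition_table(summaries, p)
      utils::write.table(wide,
                         file.path(out_dir, paste0("table_", p, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(summaries = summaries, manifest = manifest,
                 runs = if (keep_runs) runs),
            class = "study_result")
}

#' Pivot study summaries into the condition-table layout
#'
#' One row per model x sample size x metric, one column per testlet
#' length x testlet effect combination (the layout of the published
#' condition tables).
#'
#' @param summaries The `summaries` tibble of a [run_study()] result.
#' @param param Which parameter family to tabulate (e.g. "a", "b",
#'   "theta").
#' @return A wide tibble.
#' @export
format_condition_table <- function(summaries, param) {
  summaries |>
    dplyr::filter(.data$param == !!param) |>
    tidyr::pivot_longer(c("rmse", "bias", "see"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(cell = paste0("len", .data$testlet_length, "_",
                                .data$testlet_effect)) |>
    dplyr::select("metric", "model", "sample_size", "cell", "value") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value") |>
    dplyr::arrange(.data$metric, .data$model, .data$sample_size)
}
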