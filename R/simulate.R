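#' Sample true dichotomous item parameters
#'
#' Discriminations are lognormal, `a = exp(z)` with `z ~ N(0, 1)`, kept by
#' rejection sampling inside (0, 2.5) for non-anchor items or (1, 2) for
#' anchor items (the tighter anchor range keeps the anchor block highly
#' discriminating and representative). Difficulties are `b ~ N(0, 1)`
#' rejected outside (-3, 3). Rejection (not clipping) preserves the shape
#' of the truncated distributions.
#'
#' @param n Number of items to draw.
#' @param role `"nonanchor"` or `"anchor"`.
#' @return A tibble with columns `a` and `b`.
#' @export
sample_dichotomous_params <- function(n, role = c("nonanchor", "anchor")) {
  role <- match.arg(role)
  bounds <- if (role == "anchor") c(1, 2) else c(0, 2.5)
  tibble::tibble(
    a = rtrunc(n, function(m) exp(stats::rnorm(m)), bounds),
    b = rtrunc(n, stats::rnorm, c(-3, 3))
  )
}

#' Sample true polytomous item parameters
#'
#' Discrimination as in [sample_dichotomous_params()]. The K-1 category
#' boundaries are independent N(0, 1) draws truncated to (-3, 3), sorted
#' into increasing order; tied draws are resampled so generated
#' boundaries are strictly increasing.
#'
#' @inheritParams sample_dichotomous_params
#' @param n_categories Number of response categories K (default 5,
#'   codes 0..4).
#' @return A tibble with columns `a` and `b1`..`b{K-1}`.
#' @export
sample_polytomous_params <- function(n, role = c("nonanchor", "anchor"),
                                     n_categories = 5) {
  role <- match.arg(role)
  stopifnot(n_categories >= 2)
  k <- n_categories - 1L
  a <- sample_dichotomous_params(n, role)$a
  bmat <- vapply(seq_len(n), function(i) {
    repeat {
      b <- sort(rtrunc(k, stats::rnorm, c(-3, 3)))
      if (k == 1L || all(diff(b) > 0)) return(b)
    }
  }, numeric(k))
  bmat <- if (k == 1L) matrix(bmat, ncol = 1L) else t(bmat)
  colnames(bmat) <- paste0("b", seq_len(k))
  dplyr::bind_cols(tibble::tibble(a = a), tibble::as_tibble(bmat))
}

#' Draw testlet-effect variances for a local-dependence level
#'
#' Each testlet's random-effect variance \eqn{\sigma^2_\gamma} is drawn
#' uniformly from (0.1, 0.5), (0.6, 1.0) or (1.1, 2.0) for low, moderate
#' and high local item dependence respectively.
#'
#' @param level `"low"`, `"moderate"` or `"high"`.
#' @param n_testlets Number of variances to draw (0 gives an empty vector).
#' @return Numeric vector of variances.
#' @export
draw_testlet_variances <- function(level = c("low", "moderate", "high"),
                                   n_testlets) {
  level <- match.arg(level)
  rng <- switch(level, low = c(0.1, 0.5), moderate = c(0.6, 1.0),
                high = c(1.1, 2.0))
  stats::runif(n_testlets, rng[1], rng[2])
}

rtrunc <- function(n, sampler, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- sampler(max(n - length(out), 1L) * 2L)
    out <- c(out, x[x > bounds[1] & x < bounds[2]])
  }
  out[seq_len(n)]
}

#' Specify one cell of the simulation design
#'
#' A condition fixes the study (dichotomous 2PLM/2PTM or polytomous
#' GRM/GRTM data), the testlet-effect level, the testlet length (5 or 10
#' items), the per-group sample size, the number of Monte Carlo
#' replications, and the seed. Responses are always *generated* under the
#' testlet model (testlet effects are present in every condition); the
#' fitted model family is chosen at calibration time.
#'
#' @param study `"dichotomous"` or `"polytomous"`.
#' @param testlet_effect `"low"`, `"moderate"` or `"high"` — the uniform
#'   range the testlet variances are drawn from.
#' @param testlet_length Items per testlet, 5 or 10.
#' @param sample_size Examinees per group (the study design uses 1000
#'   and 2000).
#' @param n_replications Monte Carlo replications (design value 500).
#' @param seed Integer master seed for the condition.
#' @param new_form_mean_shift Mean of the new-form group's ability
#'   distribution; the base group is N(0, 1). Default +0.5 (the design
#'   calls only for a "slightly higher" new-group mean).
#' @param n_categories Categories per polytomous item (default 5).
#' @param resample_forms If TRUE, a fresh form pair is drawn each
#'   replication; default FALSE fixes one form pair per condition.
#' @return A `simulation_condition` list.
#' @export
simulation_condition <- function(study = c("dichotomous", "polytomous"),
                                 testlet_effect = c("low", "moderate", "high"),
                                 testlet_length = 5,
                                 sample_size = 1000,
                                 n_replications = 500,
                                 seed = 1L,
                                 new_form_mean_shift = 0.5,
                                 n_categories = 5,
                                 resample_forms = FALSE) {
  study <- match.arg(study)
  testlet_effect <- match.arg(testlet_effect)
  if (!testlet_length %in% c(5, 10)) {
    stop("`testlet_length` must be 5 or 10", call. = FALSE)
  }
  stopifnot(sample_size >= 1, n_replications >= 1)
  structure(
    list(study = study, testlet_effect = testlet_effect,
         testlet_length = as.integer(testlet_length),
         sample_size = as.integer(sample_size),
         n_replications = as.integer(n_replications),
         seed = as.integer(seed),
         new_form_mean_shift = new_form_mean_shift,
         n_categories = as.integer(n_categories),
         resample_forms = isTRUE(resample_forms)),
    class = "simulation_condition"
  )
}

#' @export
print.simulation_condition <- function(x, ...) {
  cat("Simulation condition:", x$study, "study\n")
  cat("  testlet effect:", x$testlet_effect,
      "| testlet length:", x$testlet_length,
      "| n per group:", x$sample_size, "\n")
  cat("  replications:", x$n_replications, "| seed:", x$seed,
      "| new-group shift:", x$new_form_mean_shift, "\n")
  invisible(x)
}

#' Build a NEAT form pair with shared anchors
#'
#' Constructs the base/new form layout: each form has 60 items — 20
#' locally independent non-anchor items, 20 non-anchor testlet items
#' (4 testlets of 5 or 2 of 10), and a 20-item internal anchor block
#' shared verbatim by both forms (10 testlet items in 2 testlets of 5 or
#' 1 of 10, plus 10 independent items). Anchor parameters are sampled
#' once; every testlet (base, new, and anchor) gets its own variance
#' drawn from the condition's uniform range.
#'
#' @param condition A [simulation_condition()].
#' @return A `form_pair` list with tibbles `items` (item_id, form, anchor,
#'   testlet_id and parameter columns) and `testlets` (testlet_id, sigma2).
#' @export
build_form_pair <- function(condition) {
  stopifnot(inherits(condition, "simulation_condition"))
  len <- condition$testlet_length
  n_tl_nonanchor <- 20L %/% len     # per form: 4 of 5 or 2 of 10
  n_tl_anchor <- 10L %/% len        # 2 of 5 or 1 of 10
  poly <- condition$study == "polytomous"

  sample_params <- function(n, role) {
    if (poly) sample_polytomous_params(n, role, condition$n_categories)
    else sample_dichotomous_params(n, role)
  }

  make_form <- function(tag) {
    ind <- sample_params(20L, "nonanchor")
    tst <- sample_params(20L, "nonanchor")
    tibble::tibble(
      item_id = sprintf("%s_%02d", tag, 1:40),
      form = tag,
      anchor = FALSE,
      testlet_id = c(rep(NA_character_, 20L),
                     rep(sprintf("%s_t%d", tag, seq_len(n_tl_nonanchor)),
                         each = len))
    ) |> dplyr::bind_cols(dplyr::bind_rows(ind, tst))
  }

  anch_tst <- sample_params(10L, "anchor")
  anch_ind <- sample_params(10L, "anchor")
  anchor <- tibble::tibble(
    item_id = sprintf("anch_%02d", 1:20),
    form = "both",
    anchor = TRUE,
    testlet_id = c(rep(sprintf("anch_t%d", seq_len(n_tl_anchor)), each = len),
                   rep(NA_character_, 10L))
  ) |> dplyr::bind_cols(dplyr::bind_rows(anch_tst, anch_ind))

  items <- dplyr::bind_rows(make_form("base"), make_form("new"), anchor)
  tl_ids <- unique(stats::na.omit(items$testlet_id))
  testlets <- tibble::tibble(
    testlet_id = tl_ids,
    anchor = grepl("^anch", tl_ids),
    sigma2 = draw_testlet_variances(condition$testlet_effect, length(tl_ids))
  )
  new_form_pair(items, testlets, condition)
}

new_form_pair <- function(items, testlets, condition) {
  structure(
    list(items = items, testlets = testlets,
         study = condition$study, n_categories = condition$n_categories,
         testlet_length = condition$testlet_length),
    class = "form_pair"
  )
}

#' @export
print.form_pair <- function(x, ...) {
  cat("NEAT form pair (", x$study, " study)\n", sep = "")
  cat(" ", nrow(x$items), "distinct items;",
      sum(x$items$anchor), "anchor items;",
      nrow(x$testlets), "testlets of length", x$testlet_length, "\n")
  invisible(x)
}

#' Items administered on one side of a form pair
#'
#' @param form_pair A `form_pair`.
#' @param side `"base"` or `"new"`.
#' @return Tibble of the 60 items that side's examinees answer (its own
#'   non-anchor items followed by the shared anchor block).
#' @export
form_items <- function(form_pair, side = c("base", "new")) {
  side <- match.arg(side)
  dplyr::filter(form_pair$items, .data$form %in% c(side, "both"))
}

#' Sample one examinee group
#'
#' Base-group abilities are N(0, 1) — matching the difficulty scale — and
#' the new group is N(shift, 1). Each person gets an independent
#' mean-zero normal testlet effect per testlet on their form, with the
#' testlet's variance.
#'
#' @param n Number of examinees.
#' @param group `"base"` or `"new"`.
#' @param testlets Tibble with `testlet_id` and `sigma2` for the testlets
#'   on this group's form.
#' @param new_form_mean_shift Mean of the new group's ability
#'   distribution (ignored for the base group).
#' @return A `person_sample` list with `theta` (length n) and `gamma`
#'   (n x n_testlets matrix, columns named by testlet id).
#' @export
sample_persons <- function(n, group = c("base", "new"), testlets,
                           new_form_mean_shift = 0.5) {
  group <- match.arg(group)
  stopifnot(n >= 1)
  mu <- if (group == "new") new_form_mean_shift else 0
  gamma <- matrix(stats::rnorm(n * nrow(testlets)), nrow = n) %*%
    diag(sqrt(testlets$sigma2), nrow(testlets))
  colnames(gamma) <- testlets$testlet_id
  structure(list(group = group, theta = stats::rnorm(n, mu, 1), gamma = gamma),
            class = "person_sample")
}

#' Generate item responses for one form
#'
#' Responses are always generated under the testlet model (testlet
#' effects are present in all generating conditions): the linear
#' predictor of a testlet item includes the person's effect for that
#' testlet. Each response compares the model probability against one
#' U(0, 1) draw — a dichotomous item is coded 1 when the probability
#' exceeds the draw, and a polytomous item is coded by locating the draw
#' within the cumulative boundary partition (codes 0..K-1).
#'
#' @param items Tibble of item parameters for the administered form
#'   (columns `item_id`, `a`, `b` or `b1`.., `testlet_id`).
#' @param persons A [sample_persons()] result whose `gamma` covers every
#'   testlet appearing in `items`.
#' @return Integer matrix (persons x items) with `item_id` column names.
#' @export
generate_responses <- function(items, persons) {
  n <- length(persons$theta)
  poly <- any(grepl("^b[0-9]+$", names(items)))
  tl <- as.character(items$testlet_id)
  need <- unique(stats::na.omit(tl))
  if (!all(need %in% colnames(persons$gamma))) {
    stop("persons lack a testlet effect for a testlet on this form",
         call. = FALSE)
  }
  out <- matrix(NA_integer_, n, nrow(items),
                dimnames = list(NULL, items$item_id))
  for (j in seq_len(nrow(items))) {
    gam <- if (is.na(tl[j])) 0 else persons$gamma[, tl[j]]
    u <- stats::runif(n)
    if (poly) {
      bnd <- item_boundaries(items, j)
      ps <- grm_boundary_probs(persons$theta, items$a[j], bnd, gam)
      # code = number of boundary probabilities still >= u
      inner <- ps[, 2:(length(bnd) + 1L), drop = FALSE]
      out[, j] <- as.integer(rowSums(inner >= u))
    } else {
      p <- prob_dichotomous(persons$theta, items$a[j], items$b[j], gam)
      out[, j] <- as.integer(p > u)
    }
  }
  out
}

#' Stack two group blocks into a concurrent-calibration matrix
#'
#' Base rows come first, then new rows. Anchor columns are observed for
#' all rows; each group's unique items are structurally missing (NA) in
#' the other group's rows. Structural missingness is never imputed.
#'
#' @param base_block,new_block Response matrices from
#'   [generate_responses()] for the two sides of `form_pair`.
#' @param form_pair The [build_form_pair()] structure the blocks came from.
#' @return A `response_matrix` list: integer matrix `codes` (with item_id
#'   column names), integer `group` vector (1 = base, 2 = new).
#' @export
assemble_concurrent <- function(base_block, new_block, form_pair) {
  ids <- form_pair$items$item_id
  shared <- intersect(colnames(base_block), colnames(new_block))
  if (!setequal(shared, form_pair$items$item_id[form_pair$items$anchor])) {
    stop("anchor columns of the two blocks do not match the form pair",
         call. = FALSE)
  }
  n_b <- nrow(base_block); n_n <- nrow(new_block)
  codes <- matrix(NA_integer_, n_b + n_n, length(ids),
                  dimnames = list(NULL, ids))
  codes[seq_len(n_b), colnames(base_block)] <- base_block
  codes[n_b + seq_len(n_n), colnames(new_block)] <- new_block
  response_matrix(codes, rep(1:2, c(n_b, n_n)))
}

#' Construct a response matrix object
#'
#' @param codes Integer matrix, persons x items, NA for not-administered
#'   cells; column names are item ids.
#' @param group Integer vector (1 = base group, 2 = new group), one per row.
#' @return A `response_matrix` list.
#' @export
response_matrix <- function(codes, group = rep(1L, nrow(codes))) {
  stopifnot(is.matrix(codes), length(group) == nrow(codes),
            !is.null(colnames(codes)), all(group %in% 1:2))
  structure(list(codes = codes, group = as.integer(group)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$codes), "persons x", ncol(x$codes),
      "items;", sum(x$group == 1L), "base /", sum(x$group == 2L),
      "new;", sum(is.na(x$codes)), "structurally missing cells\n")
  invisible(x)
}

#' Load the printed item-parameter tables
#'
#' Returns the packaged reference/new form parameter tables for the
#' dichotomous or polytomous study exactly as printed (120 items per
#' study), including testlet assignments and anchor flags. Note the
#' printed tables are stored verbatim: the two printed forms use
#' different testlet lengths and their anchor blocks are *not* numerically
#' identical, so for simulation use [printed_form()] to extract one
#' coherent form.
#'
#' @param study `"dichotomous"` or `"polytomous"`.
#' @return A tibble with columns `form` ("reference"/"new"), `item`,
#'   `testlet`, `anchor`, and parameter columns.
#' @export
load_printed_forms <- function(study = c("dichotomous", "polytomous")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0(study, "_forms.tsv"),
                      package = "testleteq", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(x) != 120L) stop("packaged form table is corrupt", call. = FALSE)
  tibble::as_tibble(x) |>
    dplyr::mutate(anchor = .data$anchor == 1L)
}

#' Reconstruct a coherent NEAT form pair from the printed tables
#'
#' The published parameter tables are the study's actual item pools, but
#' as printed they are not directly usable as a NEAT pair: the two forms
#' are laid out with different testlet lengths, and the reference form's
#' anchor rows duplicate the new form's first non-anchor rows instead of
#' matching the new form's anchor block. This constructor repairs both:
#' the base form takes the reference form's 40 non-anchor items, the new
#' form its own 40, and both share the *new* form's printed anchor block
#' (the one consistent with the anchor discrimination range). Within
#' each form, the 20 non-anchor testlet items (printed rows 21-40) and
#' the 10 anchor testlet items (rows 41-50) are grouped in printed order
#' into testlets of the requested length; rows 51-60 stay independent.
#' For the reference form at length 5 and the new form at length 10 this
#' reproduces the printed testlet columns exactly. Testlet variances are
#' drawn fresh from the requested effect level.
#'
#' @inheritParams load_printed_forms
#' @param testlet_length Items per testlet, 5 or 10.
#' @param testlet_effect Level passed to [draw_testlet_variances()].
#' @return A `form_pair`, as from [build_form_pair()].
#' @export
printed_form_pair <- function(study = c("dichotomous", "polytomous"),
                              testlet_length = 5,
                              testlet_effect = "low") {
  study <- match.arg(study)
  if (!testlet_length %in% c(5, 10)) {
    stop("`testlet_length` must be 5 or 10", call. = FALSE)
  }
  len <- as.integer(testlet_length)
  x <- load_printed_forms(study)
  pcols <- grep("^a$|^b[0-9]*$", names(x), value = TRUE)
  take <- function(frm, rows) {
    x[x$form == frm & x$item %in% rows, pcols]
  }
  n_tl <- 20L %/% len
  side <- function(frm, tag) {
    dplyr::bind_cols(
      tibble::tibble(
        item_id = sprintf("%s_%02d", tag, 1:40),
        form = tag,
        anchor = FALSE,
        testlet_id = c(rep(NA_character_, 20L),
                       rep(sprintf("%s_t%d", tag, seq_len(n_tl)), each = len))
      ),
      take(frm, 1:40)
    )
  }
  anchor <- dplyr::bind_cols(
    tibble::tibble(
      item_id = sprintf("anch_%02d", 1:20),
      form = "both",
      anchor = TRUE,
      testlet_id = c(rep(sprintf("anch_t%d", seq_len(10L %/% len)), each = len),
                     rep(NA_character_, 10L))
    ),
    take("new", 41:60)
  )
  items <- dplyr::bind_rows(side("reference", "base"), side("new", "new"),
                            anchor)
  tl_ids <- unique(stats::na.omit(items$testlet_id))
  testlets <- tibble::tibble(
    testlet_id = tl_ids,
    anchor = grepl("^anch", tl_ids),
    sigma2 = draw_testlet_variances(testlet_effect, length(tl_ids))
  )
  structure(list(items = items, testlets = testlets, study = study,
                 n_categories = if (study == "polytomous") 5L else 2L,
                 testlet_length = len),
            class = "form_pair")
}

#' Extract one printed form as a simulatable structure
#'
#' Converts one side of [load_printed_forms()] into the `form_pair`-style
#' item/testlet tables used by [generate_responses()] and
#' [fit_concurrent()], drawing each testlet's variance from the requested
#' effect level.
#'
#' @inheritParams load_printed_forms
#' @param form `"reference"` or `"new"`.
#' @param testlet_effect Level passed to [draw_testlet_variances()].
#' @return A list with `items` and `testlets` tibbles (a single-form
#'   structure; `form` is labelled "base").
#' @export
printed_form <- function(study = c("dichotomous", "polytomous"),
                         form = c("reference", "new"),
                         testlet_effect = "moderate") {
  study <- match.arg(study)
  form <- match.arg(form)
  x <- dplyr::filter(load_printed_forms(study), .data$form == !!form)
  items <- x |>
    dplyr::transmute(
      item_id = sprintf("%s_%02d", substr(form, 1, 3), .data$item),
      form = "base",
      anchor = .data$anchor,
      testlet_id = ifelse(is.na(.data$testlet), NA_character_,
                          paste0("t", .data$testlet)),
      dplyr::across(dplyr::matches("^a$|^b[0-9]*$"))
    )
  tl_ids <- unique(stats::na.omit(items$testlet_id))
  testlets <- tibble::tibble(
    testlet_id = tl_ids,
    anchor = FALSE,
    sigma2 = draw_testlet_variances(testlet_effect, length(tl_ids))
  )
  structure(list(items = items, testlets = testlets, study = study,
                 n_categories = if (study == "polytomous") 5L else 2L,
                 testlet_length = NA_integer_),
            class = "form_pair")
}
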