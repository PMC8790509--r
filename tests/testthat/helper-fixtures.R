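# Small structures used across tests. Everything is generated in code;
# sizes are kept small so single fits run in seconds.

# A miniature dichotomous two-group design: per form `n_ind` independent
# items plus `n_tl` testlets of `len` items, sharing `n_anchor_ind`
# independent anchors and one anchor testlet.
tiny_form_pair <- function(n_ind = 4, n_tl = 1, len = 3, n_anchor_ind = 4,
                           sigma2 = 0.6, poly = FALSE) {
  mk_params <- function(n) {
    if (poly) {
      tibble::tibble(a = runif(n, 0.8, 2),
                     b1 = runif(n, -2, -1), b2 = runif(n, -0.9, -0.2),
                     b3 = runif(n, -0.1, 0.6), b4 = runif(n, 0.7, 1.8))
    } else {
      tibble::tibble(a = runif(n, 0.8, 2), b = runif(n, -1.5, 1.5))
    }
  }
  side <- function(tag) {
    n_items <- n_ind + n_tl * len
    tibble::tibble(
      item_id = sprintf("%s_%02d", tag, seq_len(n_items)),
      form = tag, anchor = FALSE,
      testlet_id = c(rep(NA_character_, n_ind),
                     rep(sprintf("%s_t%d", tag, seq_len(n_tl)), each = len))
    ) |> dplyr::bind_cols(mk_params(n_items))
  }
  anchor <- tibble::tibble(
    item_id = sprintf("anch_%02d", seq_len(n_anchor_ind + len)),
    form = "both", anchor = TRUE,
    testlet_id = c(rep("anch_t1", len), rep(NA_character_, n_anchor_ind))
  ) |> dplyr::bind_cols(mk_params(n_anchor_ind + len))
  items <- dplyr::bind_rows(side("base"), side("new"), anchor)
  tl <- unique(stats::na.omit(items$testlet_id))
  structure(list(
    items = items,
    testlets = tibble::tibble(testlet_id = tl, anchor = grepl("^anch", tl),
                              sigma2 = rep_len(sigma2, length(tl))),
    study = if (poly) "polytomous" else "dichotomous",
    n_categories = if (poly) 5L else 2L, testlet_length = len
  ), class = "form_pair")
}

# Generate a stacked two-group response matrix from a form pair.
tiny_concurrent <- function(fp, n = 300, shift = 0.5) {
  bi <- form_items(fp, "base"); ni <- form_items(fp, "new")
  tl_b <- fp$testlets[fp$testlets$testlet_id %in% bi$testlet_id, ]
  tl_n <- fp$testlets[fp$testlets$testlet_id %in% ni$testlet_id, ]
  pb <- sample_persons(n, "base", tl_b)
  pn <- sample_persons(n, "new", tl_n, shift)
  list(resp = assemble_concurrent(generate_responses(bi, pb),
                                  generate_responses(ni, pn), fp),
       persons_base = pb, persons_new = pn)
}

expect_no_descent <- function(trace, tol = 1e-6) {
  expect_true(all(diff(trace) > -tol))
}
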