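#' Write / read a response matrix as delimited text
#'
#' Tab-separated layout: a `group` column (1 base, 2 new) followed by one
#' integer column per item (header = item id), `NA` marking structurally
#' missing cells.
#'
#' @param resp A [response_matrix()].
#' @param path Output file path.
#' @return `write_response_matrix` returns `path` invisibly;
#'   `read_response_matrix` returns a [response_matrix()].
#' @export
write_response_matrix <- function(resp, path) {
  stopifnot(inherits(resp, "response_matrix"))
  out <- data.frame(group = resp$group, resp$codes, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  codes <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  response_matrix(codes, as.integer(x$group))
}

#' Write / read a form pair as delimited text
#'
#' Two tab-separated files: an item table (item_id, form, anchor,
#' testlet_id, and the parameter columns `a`, `b` or `b1`..) and a
#' testlet map (testlet_id, anchor, sigma2).
#'
#' @param form_pair A `form_pair`.
#' @param items_path,testlets_path Output file paths.
#' @return `write_form_pair` returns the paths invisibly;
#'   `read_form_pair` returns a `form_pair`.
#' @export
write_form_pair <- function(form_pair, items_path, testlets_path) {
  utils::write.table(form_pair$items, items_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(form_pair$testlets, testlets_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(items_path, testlets_path))
}

#' @rdname write_form_pair
#' @export
read_form_pair <- function(items_path, testlets_path) {
  items <- tibble::as_tibble(utils::read.delim(items_path))
  items$testlet_id <- as.character(items$testlet_id)
  items$anchor <- as.logical(items$anchor)
  testlets <- tibble::as_tibble(utils::read.delim(testlets_path))
  testlets$testlet_id <- as.character(testlets$testlet_id)
  poly <- any(grepl("^b[0-9]+$", names(items)))
  structure(list(items = items, testlets = testlets,
                 study = if (poly) "polytomous" else "dichotomous",
                 n_categories = if (poly)
                   sum(grepl("^b[0-9]+$", names(items))) + 1L else 2L,
                 testlet_length = NA_integer_),
            class = "form_pair")
}

#' Export a calibration result as JSON
#'
#' Schema: `model`, `items` (one record per item with estimates),
#' `testlets` (estimated variances), `groups`, and fit diagnostics
#' (`logLik`, `n_cycles`, `converged`, `excluded_items`).
#'
#' @param fit A `trt_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model,
         items = fit$items,
         testlets = fit$testlets,
         groups = fit$groups,
         logLik = fit$logLik,
         n_cycles = fit$n_cycles,
         converged = fit$converged,
         excluded_items = fit$excluded_items),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null",
    pretty = TRUE
  )
  invisible(path)
}
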