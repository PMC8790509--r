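#' Item response probability under the 2PLM / 2PTM
#'
#' Probability of a correct (code 1) response to a dichotomous item under the
#' two-parameter logistic model (2PLM) or, when a testlet random effect
#' `gamma` is supplied, its testlet extension (2PTM):
#' \deqn{P(y = 1) = \mathrm{logistic}\{a(\theta - b - \gamma)\}.}
#' Setting `gamma = 0` recovers the 2PLM exactly. The testlet model
#' constrains the slope on \eqn{\gamma} to equal the item discrimination
#' `a`; no scaling constant (D = 1.7) is applied.
#'
#' @param theta Latent trait value(s), standard-normal scale.
#' @param a Item discrimination, must be positive.
#' @param b Item difficulty on the latent-trait scale.
#' @param gamma Person-by-testlet random effect; 0 (default) for a locally
#'   independent item or an IRT (non-testlet) model.
#' @return Numeric vector of probabilities in (0, 1); inputs are recycled.
#' @examples
#' prob_dichotomous(theta = 0, a = 1, b = 0)
#' prob_dichotomous(theta = 1, a = 2, b = 0, gamma = 1)
#' @export
prob_dichotomous <- function(theta, a, b, gamma = 0) {
  check_item_params(a, b)
  stats::plogis(a * (theta - b - gamma))
}

#' Cumulative boundary probabilities under the GRM / GRTM
#'
#' For an ordered polytomous item with K response categories (codes
#' 0..K-1) and K-1 ordered category boundaries, returns the cumulative
#' probabilities \eqn{P^*_x} of responding in category x *or higher*,
#' for x = 0..K. By construction \eqn{P^*_0 = 1} and \eqn{P^*_K = 0};
#' intermediate boundaries follow the graded response model
#' \deqn{P^*_x = \mathrm{logistic}\{a(\theta - b_x - \gamma)\},}
#' with `gamma = 0` giving the GRM and a testlet effect giving the GRTM.
#'
#' @inheritParams prob_dichotomous
#' @param boundaries Numeric vector of K-1 category boundaries,
#'   non-decreasing. Ties are tolerated (they yield a zero-probability
#'   category); decreasing boundaries are an error.
#' @return If `theta` has length 1, a numeric vector of length K+1;
#'   otherwise a matrix with `length(theta)` rows and K+1 columns.
#' @examples
#' grm_boundary_probs(theta = 0, a = 1.21, boundaries = c(-1.40, -1.17, -0.24, 0.80))
#' @export
grm_boundary_probs <- function(theta, a, boundaries, gamma = 0) {
  check_item_params(a, boundaries)
  if (any(diff(boundaries) < 0)) {
    stop("`boundaries` must be non-decreasing", call. = FALSE)
  }
  eff <- theta - gamma
  p <- stats::plogis(outer(a * eff, a * boundaries, `-`))
  out <- cbind(1, p, 0, deparse.level = 0)
  colnames(out) <- paste0("P", 0:(length(boundaries) + 1L))
  if (length(eff) == 1L) out[1L, ] else out
}

#' Category response probabilities under the GRM / GRTM
#'
#' Adjacent differences of the cumulative boundary probabilities:
#' \eqn{P_x = P^*_x - P^*_{x+1}} for categories x = 0..K-1. The returned
#' probabilities are non-negative and sum to 1. With K = 2 this reduces
#' exactly to `(1 - p, p)` where p is the 2PL probability.
#'
#' @inheritParams grm_boundary_probs
#' @return If `theta` has length 1, a numeric vector of length K;
#'   otherwise a matrix with K columns (categories 0..K-1).
#' @examples
#' grm_category_probs(theta = 0, a = 1.21, boundaries = c(-1.40, -1.17, -0.24, 0.80))
#' @export
grm_category_probs <- function(theta, a, boundaries, gamma = 0) {
  ps <- grm_boundary_probs(theta, a, boundaries, gamma)
  if (is.matrix(ps)) {
    k <- ncol(ps) - 1L
    out <- ps[, seq_len(k), drop = FALSE] - ps[, seq_len(k) + 1L, drop = FALSE]
    out[out < 0] <- 0
    colnames(out) <- paste0("cat", 0:(k - 1L))
    out
  } else {
    k <- length(ps) - 1L
    out <- pmax(ps[seq_len(k)] - ps[seq_len(k) + 1L], 0)
    names(out) <- paste0("cat", 0:(k - 1L))
    out
  }
}

#' Log-likelihood of a response vector for one person
#'
#' Sums log category probabilities over the non-missing entries of a
#' response vector, given item parameters and the person's latent state.
#' Missing responses (NA) contribute zero. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` inside the log only, for numerical stability.
#'
#' @param responses Integer vector of response codes (0-based), one per row
#'   of `items`; NA marks a missing (not administered) response.
#' @param items A data frame of item parameters with columns `a` plus
#'   either `b` (dichotomous) or `b1`..`b{K-1}` (polytomous), and
#'   optionally `testlet_id` (NA for locally independent items).
#' @param theta The person's latent trait value (scalar).
#' @param gamma Named numeric vector of testlet effects (names are testlet
#'   ids); required for testlet models when `items` contains testlet items.
#' @param model One of "2PLM", "2PTM", "GRM", "GRTM". Testlet models use
#'   `gamma` for items with a testlet id; IRT models ignore `gamma`.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(responses, items, theta,
                            gamma = NULL,
                            model = c("2PLM", "2PTM", "GRM", "GRTM")) {
  model <- match.arg(model)
  items <- tibble::as_tibble(items)
  stopifnot(length(responses) == nrow(items), length(theta) == 1L)
  use_testlet <- model %in% c("2PTM", "GRTM")
  dich <- model %in% c("2PLM", "2PTM")

  tl <- if ("testlet_id" %in% names(items)) as.character(items$testlet_id) else rep(NA_character_, nrow(items))
  gam <- rep(0, nrow(items))
  if (use_testlet) {
    need <- !is.na(tl) & !is.na(responses)
    if (any(need)) {
      if (is.null(gamma) || !all(tl[need] %in% names(gamma))) {
        stop("missing `gamma` value for a testlet item under a testlet model",
             call. = FALSE)
      }
      gam[need] <- gamma[tl[need]]
    }
  }

  ll <- 0
  for (j in seq_len(nrow(items))) {
    y <- responses[j]
    if (is.na(y)) next
    if (dich) {
      if (!y %in% c(0L, 1L)) stop("response code out of range for item ", j, call. = FALSE)
      p <- prob_dichotomous(theta, items$a[j], items$b[j], gam[j])
      ll <- ll + log(clamp_prob(if (y == 1L) p else 1 - p))
    } else {
      bnd <- item_boundaries(items, j)
      k <- length(bnd) + 1L
      if (y < 0L || y >= k) stop("response code out of range for item ", j, call. = FALSE)
      p <- grm_category_probs(theta, items$a[j], bnd, gam[j])[y + 1L]
      ll <- ll + log(clamp_prob(p))
    }
  }
  ll
}

# boundary columns b1..b{K-1} of row j, dropping trailing NAs
item_boundaries <- function(items, j) {
  cols <- grep("^b[0-9]+$", names(items), value = TRUE)
  cols <- cols[order(as.integer(sub("^b", "", cols)))]
  bnd <- as.numeric(items[j, cols])
  bnd[!is.na(bnd)]
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

check_item_params <- function(a, b) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("discrimination `a` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(b))) {
    stop("difficulty parameters must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
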