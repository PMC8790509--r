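#' Control settings for the MML-EM calibration engine
#'
#' @param quad_theta Number of rectangular quadrature points for the
#'   general trait theta.
#' @param theta_range Range of the theta grid.
#' @param quad_testlet Number of Gauss-Hermite quadrature points for
#'   each standardized testlet effect.
#' @param conv_tol Convergence tolerance: maximum absolute change in any
#'   parameter between EM cycles.
#' @param max_cycles Maximum EM cycles.
#' @param estimate_new_group Estimate the new group's ability mean and
#'   variance (the base group is fixed at N(0, 1) for identification).
#' @param accelerate Extrapolate along the EM path (Ramsay-style) every
#'   third cycle, falling back to the plain EM iterate whenever the
#'   extrapolation fails to increase the marginal likelihood; the
#'   monotone-ascent property is preserved.
#' @param newton_steps Safeguarded Fisher-scoring steps per item per cycle.
#' @param s_max Upper bound for the testlet-effect standard deviation.
#' @return A list of class `calib_control`.
#' @export
calib_control <- function(quad_theta = 21, theta_range = c(-5, 5),
                          quad_testlet = 11,
                          conv_tol = 1e-4, max_cycles = 500L,
                          estimate_new_group = TRUE, accelerate = TRUE,
                          newton_steps = 3L, s_max = 3) {
  stopifnot(quad_theta >= 5, quad_testlet >= 5, conv_tol > 0, max_cycles >= 1)
  structure(list(quad_theta = as.integer(quad_theta),
                 theta_range = theta_range,
                 quad_testlet = as.integer(quad_testlet),
                 conv_tol = conv_tol, max_cycles = as.integer(max_cycles),
                 estimate_new_group = isTRUE(estimate_new_group),
                 accelerate = isTRUE(accelerate),
                 newton_steps = as.integer(newton_steps), s_max = s_max),
            class = "calib_control")
}

# ---- internal setup ---------------------------------------------------------

# Precompute indicator matrices, grids and testlet bookkeeping for one
# response matrix + structure. `structure` is a form_pair or any list with
# an `items` tibble (item_id, testlet_id) or such a tibble directly.
calib_setup <- function(resp, structure, model, control,
                        exclude_degenerate = TRUE) {
  stopifnot(inherits(resp, "response_matrix"))
  items <- if (is.data.frame(structure)) structure else structure$items
  items <- tibble::as_tibble(items)
  ids <- colnames(resp$codes)
  if (!all(ids %in% items$item_id)) {
    stop("response columns missing from the item structure", call. = FALSE)
  }
  items <- items[match(ids, items$item_id), ]
  Y <- resp$codes
  dich <- model %in% c("2PLM", "2PTM")
  use_testlet <- model %in% c("2PTM", "GRTM")
  # category count from the item structure (boundary columns) when
  # available, so unobserved top/bottom categories keep their slot
  n_bnd <- sum(grepl("^b[0-9]+$", names(items)))
  K <- if (dich) 2L else if (n_bnd > 0L) n_bnd + 1L
       else max(Y, na.rm = TRUE) + 1L
  if (any(Y > K - 1L, na.rm = TRUE)) {
    stop("response codes exceed the model's category range", call. = FALSE)
  }

  # zero-variance items cannot be calibrated: flag and exclude
  obs_var <- apply(Y, 2, function(y) length(unique(y[!is.na(y)])))
  excluded <- if (exclude_degenerate) ids[obs_var < 2L] else character(0)
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " item(s) with zero observed variance: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    keep <- !(ids %in% excluded)
    Y <- Y[, keep, drop = FALSE]
    items <- items[keep, ]
    ids <- ids[keep]
  }

  N <- nrow(Y); J <- ncol(Y)
  storage.mode(Y) <- "integer"
  Mobs <- (!is.na(Y)) * 1
  Mx <- lapply(0:(K - 1L), function(x) (!is.na(Y) & Y == x) * 1)

  tl <- if ("testlet_id" %in% names(items)) as.character(items$testlet_id)
        else rep(NA_character_, J)
  if (!use_testlet) tl <- rep(NA_character_, J)
  # a testlet effect is not identified from a single administered item
  # (its SD trades off freely against the item's discrimination): treat
  # singleton testlets as locally independent and report sigma2 = 0
  singleton <- names(which(table(tl) == 1L))
  tl[tl %in% singleton] <- NA_character_
  tl_ids <- unique(tl[!is.na(tl)])
  tl_items <- lapply(tl_ids, function(d) which(tl == d))
  names(tl_items) <- tl_ids

  Q <- control$quad_theta
  theta_q <- seq(control$theta_range[1], control$theta_range[2], length.out = Q)
  # testlet effects use Gauss-Hermite nodes for the inner normal
  # integral: the standard choice, exact for polynomial integrands up
  # to degree 2V - 1
  V <- control$quad_testlet
  gh <- pracma::gaussHermite(V)
  z_v <- sqrt(2) * gh$x
  wv <- gh$w / sqrt(pi)
  # node k = (q-1)*V + v over the (theta, z) product grid
  qidx <- rep(seq_len(Q), each = V)
  vidx <- rep(seq_len(V), times = Q)
  Sagg <- matrix(0, Q * V, Q); Sagg[cbind(seq_len(Q * V), qidx)] <- 1

  groups <- sort(unique(resp$group))
  list(Y = Y, N = N, J = J, ids = ids, items = items, K = K, dich = dich,
       use_testlet = use_testlet, Mobs = Mobs, Mx = Mx,
       tl = tl, tl_ids = tl_ids, tl_items = tl_items,
       # per testlet: the persons actually administered it, and their codes
       tl_rows = lapply(tl_items, function(jd) {
         which(rowSums(!is.na(Y[, jd, drop = FALSE])) > 0L)
       }),
       Ytl = lapply(tl_items, function(jd) {
         rows <- which(rowSums(!is.na(Y[, jd, drop = FALSE])) > 0L)
         Y[rows, jd, drop = FALSE]
       }),
       indep = which(is.na(tl)),
       theta_q = theta_q, z_v = z_v, wv = wv, lwv = log(wv),
       qidx = qidx, vidx = vidx, Sagg = Sagg,
       gvec = resp$group, groups = groups, excluded = excluded,
       singleton = singleton, control = control)
}

# Starting values from observed category proportions (a = 1, s = sqrt(.5)).
# Group-aware: the new-group mean starts at a moment estimate from the
# score difference on shared (anchor) items, and each item's boundary
# start is offset by the mean ability of its takers under that estimate.
# Naive pooled-frequency starts put the start deep in a basin where the
# group shift is absorbed into the new form's item parameters; the
# concurrent graded likelihood is multimodal enough for EM to stay there.
calib_start <- function(st) {
  J <- st$J; K <- st$K
  nobs <- colSums(st$Mobs)

  mu0 <- 0
  g2 <- st$gvec == 2L
  if (any(g2) && any(!g2)) {
    shared <- colSums(st$Mobs[!g2, , drop = FALSE]) > 0 &
      colSums(st$Mobs[g2, , drop = FALSE]) > 0
    if (any(shared)) {
      sc <- st$Y[, shared, drop = FALSE]
      pm <- rowMeans(sc, na.rm = TRUE)   # per-person mean shared-item score
      sd1 <- stats::sd(pm[!g2])
      if (is.finite(sd1) && sd1 > 0) {
        mu0 <- (mean(pm[g2]) - mean(pm[!g2])) / sd1
        mu0 <- min(max(mu0, -2), 2)
      }
    }
  }
  # mean ability of each item's takers under the start estimate
  frac2 <- colSums(st$Mobs[g2, , drop = FALSE]) / pmax(nobs, 1)
  offset <- mu0 * frac2

  if (st$dich) {
    p <- colSums(st$Mx[[2]]) / nobs
    b <- offset - stats::qlogis(pmin(pmax(p, 0.02), 0.98))
  } else {
    b <- matrix(0, J, K - 1L)
    for (x in seq_len(K - 1L)) {
      pge <- colSums(Reduce(`+`, st$Mx[(x + 1L):K])) / nobs
      b[, x] <- offset - stats::qlogis(pmin(pmax(pge, 0.02), 0.98))
    }
    # enforce strictly increasing starts
    for (x in 2:(K - 1L)) b[, x] <- pmax(b[, x], b[, x - 1L] + 0.05)
  }
  s <- rep(sqrt(0.5), length(st$tl_ids)); names(s) <- st$tl_ids
  list(a = rep(1, J), b = b, s = s, mu2 = mu0, var2 = 1)
}

# log category probabilities for a block of items at a vector of effective
# trait nodes u; returns list over categories of J_blk x length(u) matrices
block_logprobs <- function(a, b, u, dich) {
  if (dich) {
    eta <- a %o% u - a * if (is.matrix(b)) b[, 1] else b
    list(stats::plogis(-eta, log.p = TRUE), stats::plogis(eta, log.p = TRUE))
  } else {
    K <- ncol(b) + 1L
    pstar <- lapply(seq_len(K - 1L), function(x) {
      stats::plogis(a %o% u - a * b[, x])
    })
    out <- vector("list", K)
    for (x in seq_len(K)) {
      hi <- if (x == 1L) 1 else pstar[[x - 1L]]
      lo <- if (x == K) 0 else pstar[[x]]
      out[[x]] <- log(clamp_prob(hi - lo))
    }
    out
  }
}

# E-step: person marginal log-likelihoods, theta posterior, per-testlet
# joint posterior machinery. Parameters in `par` (a, b, s, mu2, var2).
calib_estep <- function(st, par, keep_testlet = FALSE) {
  N <- st$N; Q <- length(st$theta_q); V <- length(st$z_v)
  LL <- matrix(0, N, Q)

  if (length(st$indep)) {
    j0 <- st$indep
    lp <- block_logprobs(par$a[j0],
                         if (st$dich) par$b[j0] else par$b[j0, , drop = FALSE],
                         st$theta_q, st$dich)
    for (x in seq_len(st$K)) LL <- LL + st$Mx[[x]][, j0, drop = FALSE] %*% lp[[x]]
  }

  store <- if (keep_testlet) vector("list", length(st$tl_ids)) else NULL
  if (length(st$tl_ids)) {
    lwv_k <- st$lwv[st$vidx]
    for (di in seq_along(st$tl_ids)) {
      jd <- st$tl_items[[di]]
      u <- st$theta_q[st$qidx] - par$s[di] * st$z_v[st$vidx]
      lp <- block_logprobs(par$a[jd],
                           if (st$dich) par$b[jd] else par$b[jd, , drop = FALSE],
                           u, st$dich)
      rows <- st$tl_rows[[di]]
      cc <- testlet_collapse(st$Ytl[[di]], lp, lwv_k, Q, V)
      LL[rows, ] <- LL[rows, , drop = FALSE] + log(cc$Ad)
      if (keep_testlet) store[[di]] <- cc
    }
  }

  lw1 <- stats::dnorm(st$theta_q, 0, 1); lw1 <- log(lw1 / sum(lw1))
  lw2 <- stats::dnorm(st$theta_q, par$mu2, sqrt(par$var2))
  lw2 <- log(lw2 / sum(lw2))
  lwmat <- rbind(lw1, lw2)
  LLp <- LL + lwmat[st$gvec, , drop = FALSE]
  mx <- LLp[cbind(seq_len(N), max.col(LLp, "first"))]
  li <- mx + log(rowSums(exp(LLp - mx)))
  Ptheta <- exp(LLp - li)
  list(loglik = sum(li), li = li, Ptheta = Ptheta, store = store)
}




# expected complete-data log-likelihood of testlet d as a function of the
# testlet-effect SD s, holding item parameters fixed
testlet_s_q <- function(s, st, par, jd, Rx) {
  u <- st$theta_q[st$qidx] - s * st$z_v[st$vidx]
  lp <- block_logprobs(par$a[jd],
                       if (st$dich) par$b[jd] else par$b[jd, , drop = FALSE],
                       u, st$dich)
  val <- 0
  for (x in seq_len(st$K)) val <- val + sum(Rx[[x]] * lp[[x]])
  val
}

#' Concurrent calibration by multiple-group marginal maximum likelihood
#'
#' Fits the 2PLM, 2PTM, GRM or GRTM to a stacked two-group response
#' matrix by EM, maximizing the marginal likelihood over item parameters,
#' testlet-effect variances (testlet families), and the new group's
#' ability mean and variance. The base group is fixed at N(0, 1) for
#' identification; anchor items carry a single parameter set across
#' groups, which places both forms on one scale without a post-hoc
#' transformation (concurrent calibration under the NEAT design).
#'
#' Integration uses a fixed rectangular grid over theta. For testlet
#' models, each item loads on theta plus at most one testlet effect with
#' the slope on the effect constrained equal to the item discrimination,
#' so the conditional likelihood factors over testlets given theta
#' (the bifactor dimension-reduction identity): the cost is
#' `quad_theta * quad_testlet` per testlet, never exponential in the
#' number of testlets. Testlet effects are integrated on a standardized
#' grid, with the effect SD entering the item predictor, and pure-ML
#' updates throughout (no priors). The M-step uses damped Newton updates
#' per dichotomous item, BFGS refinements per graded item, and Brent
#' search for each testlet SD; every update is ascent-guarded, so the
#' marginal log-likelihood is non-decreasing across cycles up to
#' quadrature arithmetic.
#'
#' @param resp A [response_matrix()] (typically from
#'   [assemble_concurrent()]).
#' @param structure A `form_pair` (or any list with an `items` tibble, or
#'   the tibble itself) giving each item's `item_id` and `testlet_id`.
#' @param model `"2PLM"`, `"2PTM"`, `"GRM"` or `"GRTM"`.
#' @param control A [calib_control()].
#' @param start Optional named list overriding entries of the default
#'   starting values (`a`, `b`, `s`, `mu2`, `var2`) — e.g. a warm start
#'   from a previous fit.
#' @return A `trt_fit` object: tibbles `items` (estimates), `testlets`
#'   (estimated sigma2), `groups`; the final marginal `logLik`, its
#'   per-cycle `trace`, `n_cycles`, `converged`, and any
#'   `excluded_items`. A testlet SD estimated at the zero boundary is
#'   reported as 0 (a legitimate boundary ML estimate).
#' @export
fit_concurrent <- function(resp, structure,
                           model = c("2PLM", "2PTM", "GRM", "GRTM"),
                           control = calib_control(), start = NULL) {
  model <- match.arg(model)
  st <- calib_setup(resp, structure, model, control)
  par <- calib_start(st)
  for (nm in names(start)) par[[nm]] <- start[[nm]]
  Q <- length(st$theta_q); V <- length(st$z_v)
  trace <- numeric(0)
  converged <- FALSE
  cyc <- 0L

  # pack/unpack for Ramsay-style extrapolation of the EM path
  pack <- function(p) c(p$a, as.numeric(p$b), p$s, p$mu2, p$var2)
  unpack <- function(v, tpl) {
    nb <- length(tpl$a) * (if (is.matrix(tpl$b)) ncol(tpl$b) else 1L)
    i <- length(tpl$a)
    out <- tpl
    out$a <- pmin(pmax(v[seq_len(i)], 0.02), 15)
    bv <- pmin(pmax(v[i + seq_len(nb)], -8), 8)
    out$b <- if (is.matrix(tpl$b)) {
      m <- matrix(bv, nrow(tpl$b), ncol(tpl$b))
      # keep boundaries ordered after extrapolation
      t(apply(m, 1, cummax))
    } else bv
    i <- i + nb
    if (length(tpl$s)) {
      out$s[] <- pmin(pmax(v[i + seq_along(tpl$s)], 0), control$s_max)
      i <- i + length(tpl$s)
    }
    out$mu2 <- v[i + 1L]
    out$var2 <- max(v[i + 2L], 1e-3)
    out
  }

  p_hist <- list()       # packed EM-map iterates for extrapolation
  em_par <- par          # last plain EM-map parameters (fallback)
  accelerated <- FALSE
  last_loglik <- -Inf

  for (cyc in seq_len(control$max_cycles)) {
    es <- calib_estep(st, par, keep_testlet = TRUE)
    if (accelerated && es$loglik < last_loglik) {
      # extrapolation overshot: fall back to the plain EM iterate
      par <- em_par
      es <- calib_estep(st, par, keep_testlet = TRUE)
      p_hist <- list()
    }
    accelerated <- FALSE
    trace <- c(trace, es$loglik)
    last_loglik <- es$loglik
    old <- par

    # --- independent items -------------------------------------------------
    if (length(st$indep)) {
      j0 <- st$indep
      Rx <- lapply(st$Mx, function(m) {
        crossprod(m[, j0, drop = FALSE], es$Ptheta)
      })
      Bmat <- if (st$dich) matrix(par$b[j0], ncol = 1L)
              else par$b[j0, , drop = FALSE]
      up <- grm_fisher_block(par$a[j0], Bmat, st$theta_q, Rx,
                             control$newton_steps, 0.02, 15, 8)
      par$a[j0] <- up$a
      if (st$dich) par$b[j0] <- up$B[, 1L] else par$b[j0, ] <- up$B
    }

    # --- testlet blocks ----------------------------------------------------
    if (length(st$tl_ids)) {
      for (di in seq_along(st$tl_ids)) {
        jd <- st$tl_items[[di]]
        sd_old <- par$s[di]
        cnt <- testlet_counts(st$Ytl[[di]], es$store[[di]]$Bd,
                              es$store[[di]]$Ad,
                              es$Ptheta[st$tl_rows[[di]], , drop = FALSE],
                              V, st$K)
        Rx <- cnt$Rx
        u <- st$theta_q[st$qidx] - sd_old * st$z_v[st$vidx]
        Bmat <- if (st$dich) matrix(par$b[jd], ncol = 1L)
                else par$b[jd, , drop = FALSE]
        up <- grm_fisher_block(par$a[jd], Bmat, u, Rx,
                               control$newton_steps, 0.02, 15, 8)
        par$a[jd] <- up$a
        if (st$dich) par$b[jd] <- up$B[, 1L] else par$b[jd, ] <- up$B
        # testlet SD: Brent on [0, s_max], ascent-guarded
        opt <- stats::optimize(function(s) testlet_s_q(s, st, par, jd, Rx),
                               c(0, control$s_max), maximum = TRUE,
                               tol = 1e-4)
        cand <- c(opt$maximum, sd_old, 0)
        qs <- vapply(cand, function(s) testlet_s_q(s, st, par, jd, Rx),
                     numeric(1))
        s_new <- cand[which.max(qs)]
        if (s_new < 1e-3) s_new <- 0
        par$s[di] <- s_new
      }
    }

    # --- new-group density -------------------------------------------------
    if (control$estimate_new_group && any(st$gvec == 2L)) {
      g2 <- st$gvec == 2L
      Eth <- es$Ptheta[g2, , drop = FALSE] %*% st$theta_q
      Eth2 <- es$Ptheta[g2, , drop = FALSE] %*% st$theta_q^2
      par$mu2 <- mean(Eth)
      par$var2 <- max(mean(Eth2) - par$mu2^2, 1e-3)
    }

    delta <- max(abs(par$a - old$a), abs(par$b - old$b),
                 if (length(par$s)) abs(par$s - old$s) else 0,
                 abs(par$mu2 - old$mu2), abs(par$var2 - old$var2))
    if (delta < control$conv_tol) { converged <- TRUE; break }

    # --- Ramsay-style acceleration every third cycle, ascent-guarded -------
    em_par <- par
    p_hist <- c(p_hist, list(pack(par)))
    if (length(p_hist) > 3L) p_hist <- p_hist[-1L]
    if (control$accelerate && cyc >= 6L && length(p_hist) == 3L) {
      d1 <- p_hist[[3L]] - p_hist[[2L]]
      d0 <- p_hist[[2L]] - p_hist[[1L]]
      den <- sum(d0 * d0)
      r <- if (den > 0) sum(d1 * d0) / den else 0
      r <- min(max(r, 0), 0.95)
      if (r > 0.5) {
        par <- unpack(p_hist[[3L]] + (r / (1 - r)) * d1, par)
        accelerated <- TRUE
      }
    }
  }

  final <- calib_estep(st, par)
  trace <- c(trace, final$loglik)
  if (!converged) {
    warning("EM did not converge within ", control$max_cycles, " cycles",
            call. = FALSE)
  }

  items <- tibble::tibble(item_id = st$ids,
                          testlet_id = st$tl,
                          a = par$a)
  if (st$dich) {
    items$b <- par$b
  } else {
    bm <- par$b; colnames(bm) <- paste0("b", seq_len(st$K - 1L))
    items <- dplyr::bind_cols(items, tibble::as_tibble(bm))
  }
  if (length(st$excluded)) {
    items <- dplyr::bind_rows(
      items,
      tibble::tibble(item_id = st$excluded, testlet_id = NA_character_)
    )
  }
  groups <- tibble::tibble(
    group = c("base", "new")[st$groups],
    mean = c(0, par$mu2)[st$groups],
    var = c(1, par$var2)[st$groups]
  )
  structure(
    list(model = model,
         items = items,
         testlets = tibble::tibble(
           testlet_id = c(st$tl_ids, st$singleton),
           sigma2 = c(unname(par$s)^2, rep(0, length(st$singleton)))),
         groups = groups,
         logLik = final$loglik,
         trace = trace,
         n_cycles = cyc,
         converged = converged,
         excluded_items = st$excluded,
         n_persons = st$N,
         control = control),
    class = "trt_fit"
  )
}

#' @export
print.trt_fit <- function(x, ...) {
  cat("Concurrent", x$model, "calibration:",
      nrow(x$items), "items,", x$n_persons, "persons\n")
  cat("  logLik:", format(x$logLik, digits = 8),
      "| cycles:", x$n_cycles,
      "|", if (x$converged) "converged" else "NOT converged", "\n")
  if (nrow(x$testlets)) {
    cat("  testlet variances:",
        paste(sprintf("%s=%.3f", x$testlets$testlet_id, x$testlets$sigma2),
              collapse = ", "), "\n")
  }
  ng <- x$groups[x$groups$group == "new", ]
  if (nrow(ng)) {
    cat(sprintf("  new group: mean %.3f, var %.3f\n", ng$mean, ng$var))
  }
  invisible(x)
}

# rebuild an internal parameter list from a trt_fit (or fit-like list)
fit_params <- function(fit, st) {
  items <- fit$items[match(st$ids, fit$items$item_id), ]
  b <- if (st$dich) items$b
       else as.matrix(items[, paste0("b", seq_len(st$K - 1L))])
  s <- sqrt(fit$testlets$sigma2[match(st$tl_ids, fit$testlets$testlet_id)])
  names(s) <- st$tl_ids
  ng <- fit$groups[fit$groups$group == "new", ]
  list(a = items$a, b = b, s = s,
       mu2 = if (nrow(ng)) ng$mean else 0,
       var2 = if (nrow(ng)) ng$var else 1)
}

#' Marginal log-likelihood of a response matrix under a fitted model
#'
#' Sum over persons of the log of the quadrature-approximated marginal
#' probability of their response pattern under their group's ability
#' density. An all-missing person contributes exactly 0.
#'
#' @param resp A [response_matrix()].
#' @param fit A `trt_fit` (or a list with compatible `items`, `testlets`,
#'   `groups` tibbles and `model`).
#' @param control Optional [calib_control()]; defaults to the fit's.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(resp, fit, control = NULL) {
  control <- control %||% fit$control %||% calib_control()
  st <- calib_setup(resp, fit, fit$model, control, exclude_degenerate = FALSE)
  calib_estep(st, fit_params(fit, st))$loglik
}

#' EAP ability scores
#'
#' Expected a posteriori trait estimates: the posterior mean of theta for
#' each person under their group's fitted ability density, with testlet
#' effects integrated out for testlet models. Missing responses are
#' skipped; a person with no observed responses is scored at the group
#' prior mean and flagged.
#'
#' @inheritParams marginal_loglik
#' @return A tibble with `person` (row index), `group` (1 base / 2 new),
#'   `theta_eap`, and `all_missing`.
#' @export
eap_score <- function(resp, fit, control = NULL) {
  control <- control %||% fit$control %||% calib_control()
  st <- calib_setup(resp, fit, fit$model, control, exclude_degenerate = FALSE)
  es <- calib_estep(st, fit_params(fit, st))
  tibble::tibble(
    person = seq_len(st$N),
    group = st$gvec,
    theta_eap = as.numeric(es$Ptheta %*% st$theta_q),
    all_missing = rowSums(st$Mobs) == 0
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy item estimates from a calibration
#'
#' @param x A `trt_fit`.
#' @param ... Unused.
#' @return One row per item and parameter: `item_id`, `testlet_id`,
#'   `term`, `estimate`.
#' @method tidy trt_fit
#' @export
tidy.trt_fit <- function(x, ...) {
  tidyr::pivot_longer(x$items, cols = -c("item_id", "testlet_id"),
                      names_to = "term", values_to = "estimate")
}

#' One-row fit summary
#'
#' @param x A `trt_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model, log-likelihood, cycle count,
#'   convergence flag, dimensions and new-group density estimates.
#' @method glance trt_fit
#' @export
glance.trt_fit <- function(x, ...) {
  ng <- x$groups[x$groups$group == "new", ]
  tibble::tibble(
    model = x$model,
    logLik = x$logLik,
    n_cycles = x$n_cycles,
    converged = x$converged,
    n_items = nrow(x$items),
    n_persons = x$n_persons,
    n_testlets = nrow(x$testlets),
    new_group_mean = if (nrow(ng)) ng$mean else NA_real_,
    new_group_var = if (nrow(ng)) ng$var else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
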