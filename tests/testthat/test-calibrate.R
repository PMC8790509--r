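# MML-EM concurrent calibration, marginal likelihood and EAP scoring.
# Fits here use miniature designs so each runs in seconds.

test_that("marginal_loglik matches a hand-computed quadrature sum", {
  # one person, one item: L = sum_q w_q * P(y=1 | theta_q)
  resp <- response_matrix(matrix(1L, 1, 1, dimnames = list(NULL, "i1")))
  fit <- list(model = "2PLM",
              items = tibble::tibble(item_id = "i1", testlet_id = NA_character_,
                                     a = 1.4, b = 0.3),
              testlets = tibble::tibble(testlet_id = character(),
                                        sigma2 = numeric()),
              groups = tibble::tibble(group = "base", mean = 0, var = 1))
  ctl <- calib_control(quad_theta = 5, theta_range = c(-2, 2))
  nodes <- seq(-2, 2, length.out = 5)
  w <- dnorm(nodes); w <- w / sum(w)
  oracle <- log(sum(w * plogis(1.4 * (nodes - 0.3))))
  expect_equal(marginal_loglik(resp, fit, ctl), oracle, tolerance = 1e-12)

  # an all-missing person changes the value by exactly zero
  resp2 <- response_matrix(matrix(c(1L, NA), 2, 1,
                                  dimnames = list(NULL, "i1")))
  expect_equal(marginal_loglik(resp2, fit, ctl), oracle, tolerance = 1e-12)
})

test_that("marginal_loglik integrates the testlet effect for TRT models", {
  # one person answering two items of one testlet: the bifactor collapse
  # must equal the brute-force double quadrature
  resp <- response_matrix(matrix(c(1L, 0L), 1, 2,
                                 dimnames = list(NULL, c("i1", "i2"))))
  s2 <- 0.8
  fit <- list(model = "2PTM",
              items = tibble::tibble(item_id = c("i1", "i2"),
                                     testlet_id = "t1",
                                     a = c(1.2, 0.7), b = c(-0.2, 0.5)),
              testlets = tibble::tibble(testlet_id = "t1", sigma2 = s2),
              groups = tibble::tibble(group = "base", mean = 0, var = 1))
  ctl <- calib_control(quad_theta = 21, quad_testlet = 11)
  thq <- seq(-5, 5, length.out = 21); wq <- dnorm(thq); wq <- wq / sum(wq)
  gh <- pracma::gaussHermite(11)
  zv <- sqrt(2) * gh$x; wv <- gh$w / sqrt(pi)
  lik <- 0
  for (q in 1:21) for (v in 1:11) {
    g <- sqrt(s2) * zv[v]
    lik <- lik + wq[q] * wv[v] *
      plogis(1.2 * (thq[q] + 0.2 - g)) *
      (1 - plogis(0.7 * (thq[q] - 0.5 - g)))
  }
  expect_equal(marginal_loglik(resp, fit, ctl), log(lik), tolerance = 1e-10)
})

test_that("EAP matches a dense-grid posterior oracle on a single-item test", {
  resp <- response_matrix(matrix(c(1L, 0L), 2, 1,
                                 dimnames = list(NULL, "i1")))
  fit <- list(model = "2PLM",
              items = tibble::tibble(item_id = "i1",
                                     testlet_id = NA_character_,
                                     a = 1.6, b = -0.4),
              testlets = tibble::tibble(testlet_id = character(),
                                        sigma2 = numeric()),
              groups = tibble::tibble(group = "base", mean = 0, var = 1))
  sc <- eap_score(resp, fit, calib_control(quad_theta = 2001,
                                           theta_range = c(-8, 8)))
  # brute-force 10,000-point trapezoid integration of the posterior mean
  grid <- seq(-8, 8, length.out = 10000)
  for (i in 1:2) {
    y <- resp$codes[i, 1]
    lik <- dnorm(grid) * (if (y == 1) plogis(1.6 * (grid + 0.4))
                          else 1 - plogis(1.6 * (grid + 0.4)))
    oracle <- sum(grid * lik) / sum(lik)
    expect_equal(sc$theta_eap[i], oracle, tolerance = 1e-4)
  }
})

test_that("an all-missing person is scored at the group prior mean and flagged", {
  codes <- matrix(c(1L, NA, 0L, NA), 2, 2, dimnames = list(NULL, c("i1", "i2")))
  codes[2, ] <- NA
  resp <- response_matrix(codes, group = c(1L, 2L))
  fit <- list(model = "2PLM",
              items = tibble::tibble(item_id = c("i1", "i2"),
                                     testlet_id = NA_character_,
                                     a = c(1, 1), b = c(0, 0)),
              testlets = tibble::tibble(testlet_id = character(),
                                        sigma2 = numeric()),
              groups = tibble::tibble(group = c("base", "new"),
                                      mean = c(0, 0.37), var = c(1, 1)))
  sc <- eap_score(resp, fit, calib_control(quad_theta = 201,
                                           theta_range = c(-6, 6)))
  expect_true(sc$all_missing[2])
  expect_false(sc$all_missing[1])
  expect_equal(sc$theta_eap[2], 0.37, tolerance = 1e-3)
})

test_that("adding a correct response never decreases the EAP score", {
  set.seed(31)
  items <- tibble::tibble(item_id = sprintf("i%d", 1:6),
                          testlet_id = NA_character_,
                          a = runif(6, 0.8, 2), b = runif(6, -1.5, 1.5))
  fit <- list(model = "2PLM", items = items,
              testlets = tibble::tibble(testlet_id = character(),
                                        sigma2 = numeric()),
              groups = tibble::tibble(group = "base", mean = 0, var = 1))
  base_pattern <- c(1L, 0L, 1L, 0L, 0L, NA)
  with_extra <- base_pattern; with_extra[6] <- 1L
  codes <- rbind(base_pattern, with_extra)
  dimnames(codes) <- list(NULL, items$item_id)
  sc <- eap_score(response_matrix(codes), fit)
  expect_gt(sc$theta_eap[2], sc$theta_eap[1])
})

test_that("concurrent 2PTM fit recovers parameters and ascends monotonically", {
  set.seed(32)
  fp <- tiny_form_pair(n_ind = 6, n_tl = 2, len = 4, n_anchor_ind = 4,
                       sigma2 = 0.8)
  out <- tiny_concurrent(fp, n = 400)
  fit <- fit_concurrent(out$resp, fp, "2PTM")
  expect_s3_class(fit, "trt_fit")
  expect_true(fit$converged)
  expect_no_descent(fit$trace)
  merged <- dplyr::inner_join(fit$items, fp$items, by = "item_id",
                              suffix = c(".est", ".true"))
  expect_gt(cor(merged$a.est, merged$a.true), 0.7)
  expect_gt(cor(merged$b.est, merged$b.true), 0.9)
  # the new group's mean shift is recovered with reasonable accuracy
  ng <- fit$groups[fit$groups$group == "new", ]
  expect_lt(abs(ng$mean - 0.5), 0.3)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("a", "b"))
  gl <- glance(fit)
  expect_equal(gl$model, "2PTM")
  expect_true(gl$converged)
})

test_that("EM ascends for the graded testlet model too", {
  set.seed(33)
  fp <- tiny_form_pair(n_ind = 4, n_tl = 1, len = 4, n_anchor_ind = 3,
                       sigma2 = 0.9, poly = TRUE)
  out <- tiny_concurrent(fp, n = 300)
  fit <- fit_concurrent(out$resp, fp, "GRTM",
                        calib_control(max_cycles = 120))
  expect_no_descent(fit$trace)
  expect_true(all(fit$testlets$sigma2 >= 0))
  bm <- as.matrix(fit$items[, paste0("b", 1:4)])
  expect_true(all(diff(t(bm)) >= 0))  # ordered boundaries per item
})

test_that("permuting item columns leaves estimates invariant up to relabeling", {
  set.seed(34)
  fp <- tiny_form_pair(n_ind = 5, n_tl = 1, len = 3, n_anchor_ind = 3,
                       sigma2 = 0.5)
  out <- tiny_concurrent(fp, n = 300)
  fit1 <- fit_concurrent(out$resp, fp, "2PTM")
  perm <- sample(ncol(out$resp$codes))
  resp2 <- response_matrix(out$resp$codes[, perm], out$resp$group)
  fit2 <- fit_concurrent(resp2, fp, "2PTM")
  m <- dplyr::inner_join(fit1$items, fit2$items, by = "item_id",
                         suffix = c(".1", ".2"))
  expect_equal(m$a.1, m$a.2, tolerance = 1e-3)
  expect_equal(m$b.1, m$b.2, tolerance = 1e-3)
})

test_that("singleton testlets degenerate the 2PTM to the 2PLM", {
  set.seed(35)
  # every item its own testlet, all true variances zero
  items <- tibble::tibble(item_id = sprintf("i%d", 1:10),
                          form = "base", anchor = FALSE,
                          testlet_id = sprintf("t%d", 1:10),
                          a = runif(10, 0.8, 1.8), b = runif(10, -1, 1))
  fp <- structure(list(
    items = items,
    testlets = tibble::tibble(testlet_id = items$testlet_id, anchor = FALSE,
                              sigma2 = 0),
    study = "dichotomous", n_categories = 2L, testlet_length = 1L
  ), class = "form_pair")
  ps <- sample_persons(700, "base", fp$testlets)
  resp <- response_matrix(generate_responses(items, ps))
  f_irt <- fit_concurrent(resp, fp, "2PLM")
  f_trt <- fit_concurrent(resp, fp, "2PTM")
  m <- dplyr::inner_join(f_irt$items, f_trt$items, by = "item_id",
                         suffix = c(".irt", ".trt"))
  expect_equal(m$a.irt, m$a.trt, tolerance = 0.02)
  expect_equal(m$b.irt, m$b.trt, tolerance = 0.02)
})

test_that("zero-variance items are flagged and excluded, fit continues", {
  set.seed(36)
  fp <- tiny_form_pair(n_ind = 5, n_tl = 1, len = 3, n_anchor_ind = 3)
  out <- tiny_concurrent(fp, n = 200)
  codes <- out$resp$codes
  codes[!is.na(codes[, "base_01"]), "base_01"] <- 1L  # constant item
  resp <- response_matrix(codes, out$resp$group)
  expect_warning(fit <- fit_concurrent(resp, fp, "2PLM"), "zero observed variance")
  expect_equal(fit$excluded_items, "base_01")
  expect_true(is.na(fit$items$a[fit$items$item_id == "base_01"]))
  expect_true(fit$converged)
})

test_that("base group stays fixed at N(0,1) and anchors are structurally shared", {
  set.seed(37)
  fp <- tiny_form_pair()
  out <- tiny_concurrent(fp, n = 250)
  fit <- fit_concurrent(out$resp, fp, "2PLM")
  bg <- fit$groups[fit$groups$group == "base", ]
  expect_equal(bg$mean, 0)
  expect_equal(bg$var, 1)
  # one estimate per anchor item, used by both groups' likelihoods
  expect_equal(sum(grepl("^anch", fit$items$item_id)), 7L)
  expect_equal(anyDuplicated(fit$items$item_id), 0L)
})

test_that("non-convergence is reported, not silently swallowed", {
  set.seed(38)
  fp <- tiny_form_pair(n_ind = 4, n_tl = 1, len = 3, n_anchor_ind = 2)
  out <- tiny_concurrent(fp, n = 150)
  expect_warning(
    fit <- fit_concurrent(out$resp, fp, "2PTM",
                          calib_control(max_cycles = 3)),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_equal(fit$n_cycles, 3L)
})
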