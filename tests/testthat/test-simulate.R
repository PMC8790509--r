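# NEAT form construction, parameter sampling, person sampling and
# response generation.

test_that("sampled dichotomous parameters respect their truncation bounds", {
  set.seed(1)
  na <- sample_dichotomous_params(10000, "nonanchor")
  expect_true(all(na$a > 0 & na$a < 2.5))
  expect_true(all(na$b > -3 & na$b < 3))
  an <- sample_dichotomous_params(10000, "anchor")
  expect_true(all(an$a > 1 & an$a < 2))
  # anchor support is contained in (1, 2): the anchor minimum dominates
  expect_gte(min(an$a), 1)
  expect_gt(min(an$a), min(na$a))
})

test_that("anchor discriminations match a brute-force rejection oracle", {
  set.seed(2)
  draws <- sample_dichotomous_params(10000, "anchor")$a
  # independent oracle: raw lognormal draws filtered to the interval
  z <- exp(rnorm(2e5))
  oracle <- z[z > 1 & z < 2]
  se <- sd(oracle) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean(oracle)), 3 * se + 3 * sd(oracle) / sqrt(length(oracle)))
  expect_lt(abs(sd(draws) - sd(oracle)), 0.02)
})

test_that("polytomous boundaries are strictly increasing and match the order-statistic oracle", {
  set.seed(3)
  pp <- sample_polytomous_params(10000, "nonanchor")
  bm <- as.matrix(pp[, paste0("b", 1:4)])
  expect_true(all(bm[, 2] > bm[, 1] & bm[, 3] > bm[, 2] & bm[, 4] > bm[, 3]))
  expect_true(all(bm > -3 & bm < 3))
  # Monte-Carlo oracle: sorted truncated-normal 4-tuples
  z <- matrix(rnorm(4 * 4e4), ncol = 4)
  z <- z[apply(abs(z) < 3, 1, all), , drop = FALSE]
  oracle <- t(apply(z, 1, sort))
  for (k in 1:4) {
    se <- sd(oracle[, k]) / sqrt(nrow(bm))
    expect_lt(abs(mean(bm[, k]) - mean(oracle[, k])),
              3 * se + 3 * sd(oracle[, k]) / sqrt(nrow(oracle)))
  }
  # two categories behave as a single difficulty
  p2 <- sample_polytomous_params(50, "nonanchor", n_categories = 2)
  expect_named(p2, c("a", "b1"))
  expect_true(all(p2$b1 > -3 & p2$b1 < 3))
})

test_that("testlet variances come from the level's uniform range", {
  set.seed(4)
  expect_true(all(dplyr::between(draw_testlet_variances("low", 5000), 0.1, 0.5)))
  expect_true(all(dplyr::between(draw_testlet_variances("moderate", 5000), 0.6, 1.0)))
  hi <- draw_testlet_variances("high", 10000)
  expect_true(all(dplyr::between(hi, 1.1, 2.0)))
  # mean of U(1.1, 2.0) is 1.55; SD is 0.9/sqrt(12)
  expect_lt(abs(mean(hi) - 1.55), 3 * (0.9 / sqrt(12)) / sqrt(10000))
  expect_length(draw_testlet_variances("low", 0), 0)
  expect_error(draw_testlet_variances("extreme", 2))
})

test_that("form pairs have the NEAT layout for both testlet lengths", {
  set.seed(5)
  for (len in c(5L, 10L)) {
    cond <- simulation_condition("dichotomous", "moderate", len, 500, 1, 1)
    fp <- build_form_pair(cond)
    expect_equal(nrow(fp$items), 100L)             # 60 + 60 - 20 shared
    for (side in c("base", "new")) {
      it <- form_items(fp, side)
      expect_equal(nrow(it), 60L)
      expect_equal(sum(it$anchor), 20L)
      non_anchor_tl <- it$testlet_id[!it$anchor & !is.na(it$testlet_id)]
      expect_equal(length(non_anchor_tl), 20L)
      expect_equal(unname(table(non_anchor_tl)),
                   rep(len, 20L / len), ignore_attr = TRUE)
      anchor_tl <- it$testlet_id[it$anchor & !is.na(it$testlet_id)]
      expect_equal(length(anchor_tl), 10L)
    }
    # every testlet has exactly the condition's length
    cnt <- table(fp$items$testlet_id)
    expect_true(all(cnt == len))
    # anchor rows appear once, shared verbatim by construction
    expect_equal(sum(fp$items$form == "both"), 20L)
  }
  expect_error(simulation_condition("dichotomous", "low", 7, 500, 1, 1),
               "testlet_length")
})

test_that("regenerating with the same seed is bit-identical", {
  cond <- simulation_condition("polytomous", "high", 5, 50, 1, seed = 99)
  set.seed(cond$seed); fp1 <- build_form_pair(cond)
  set.seed(cond$seed); fp2 <- build_form_pair(cond)
  expect_identical(fp1$items, fp2$items)
  expect_identical(fp1$testlets, fp2$testlets)
  tl <- fp1$testlets[fp1$testlets$testlet_id %in%
                       form_items(fp1, "base")$testlet_id, ]
  set.seed(7); p1 <- sample_persons(50, "base", tl)
  set.seed(7); p2 <- sample_persons(50, "base", tl)
  expect_identical(p1, p2)
  set.seed(8); r1 <- generate_responses(form_items(fp1, "base"), p1)
  set.seed(8); r2 <- generate_responses(form_items(fp1, "base"), p1)
  expect_identical(r1, r2)
})

test_that("person samples have the specified group means and testlet variances", {
  set.seed(6)
  tl <- tibble::tibble(testlet_id = c("t1", "t2"), sigma2 = c(0.4, 1.5))
  ps <- sample_persons(100000, "new", tl, new_form_mean_shift = 0.5)
  expect_lt(abs(mean(ps$theta) - 0.5), 3 / sqrt(1e5))
  # chi-square sampling error of a variance: SE = sigma2 * sqrt(2/n)
  for (d in 1:2) {
    expect_lt(abs(var(ps$gamma[, d]) - tl$sigma2[d]),
              3 * tl$sigma2[d] * sqrt(2 / 1e5))
    expect_lt(abs(mean(ps$gamma[, d])), 3 * sqrt(tl$sigma2[d] / 1e5))
  }
  # zero shift makes the groups distributionally identical
  set.seed(7); a <- sample_persons(2000, "base", tl)
  set.seed(7); b <- sample_persons(2000, "new", tl, new_form_mean_shift = 0)
  expect_identical(a$theta, b$theta)
})

test_that("response generation matches model probabilities (binomial oracle)", {
  set.seed(8)
  items <- tibble::tibble(item_id = c("i1", "i2"), a = c(1.3, 0.9),
                          b = c(-0.4, 0.8),
                          testlet_id = c(NA_character_, "t1"))
  n <- 50000
  persons <- list(theta = rep(0.3, n),
                  gamma = matrix(0.6, n, 1, dimnames = list(NULL, "t1")))
  resp <- generate_responses(items, persons)
  p1 <- prob_dichotomous(0.3, 1.3, -0.4)
  p2 <- prob_dichotomous(0.3, 0.9, 0.8, gamma = 0.6)
  expect_lt(abs(mean(resp[, 1]) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  expect_lt(abs(mean(resp[, 2]) - p2), 3 * sqrt(p2 * (1 - p2) / n))
  # degenerate probability forces a constant column
  items$b <- c(-30, 30)
  resp <- generate_responses(items, persons)
  expect_true(all(resp[, 1] == 1L))
  expect_true(all(resp[, 2] == 0L))
})

test_that("polytomous category frequencies match grm_category_probs (multinomial oracle)", {
  set.seed(9)
  items <- tibble::tibble(item_id = "p1", a = 1.21, b1 = -1.40, b2 = -1.17,
                          b3 = -0.24, b4 = 0.80, testlet_id = "t1")
  n <- 50000
  persons <- list(theta = rep(0.2, n),
                  gamma = matrix(-0.4, n, 1, dimnames = list(NULL, "t1")))
  resp <- generate_responses(items, persons)
  expect_true(all(resp %in% 0:4))
  pc <- grm_category_probs(0.2, 1.21, c(-1.40, -1.17, -0.24, 0.80), -0.4)
  freq <- tabulate(resp[, 1] + 1L, 5) / n
  for (k in 1:5) {
    expect_lt(abs(freq[k] - pc[k]), 3 * sqrt(pc[k] * (1 - pc[k]) / n))
  }
})

test_that("generation requires a testlet effect for every testlet on the form", {
  items <- tibble::tibble(item_id = "i1", a = 1, b = 0, testlet_id = "t9")
  persons <- list(theta = rnorm(5), gamma = matrix(0, 5, 0))
  expect_error(generate_responses(items, persons), "testlet effect")
})

test_that("concurrent assembly has the NEAT missingness pattern", {
  set.seed(10)
  cond <- simulation_condition("dichotomous", "low", 5, 40, 1, 3)
  fp <- build_form_pair(cond)
  out <- tiny_concurrent(fp, n = 40)
  codes <- out$resp$codes
  expect_equal(ncol(codes), 100L)     # 60 + 60 - 20 shared columns
  base_rows <- out$resp$group == 1L
  expect_true(all(rowSums(is.na(codes[base_rows, ])) == 40L))
  expect_true(all(rowSums(is.na(codes[!base_rows, ])) == 40L))
  anchor_cols <- fp$items$item_id[fp$items$anchor]
  expect_true(all(!is.na(codes[, anchor_cols])))
  # anchor parameters are a single shared block
  expect_equal(sum(duplicated(fp$items$item_id)), 0L)
})

test_that("items within a testlet correlate more than across testlets under high LID", {
  set.seed(12)
  fp <- tiny_form_pair(n_ind = 2, n_tl = 2, len = 5, sigma2 = 1.6)
  bi <- form_items(fp, "base")
  tl <- fp$testlets[fp$testlets$testlet_id %in% bi$testlet_id, ]
  ps <- sample_persons(2000, "base", tl)
  resp <- generate_responses(bi, ps)
  cm <- cor(resp)
  same <- outer(bi$testlet_id, bi$testlet_id, `==`)
  same[is.na(same)] <- FALSE
  off <- upper.tri(cm)
  expect_gt(mean(cm[off & same]), mean(cm[off & !same]))
})

test_that("printed tables load verbatim with the published summary values", {
  d <- load_printed_forms("dichotomous")
  expect_equal(nrow(d), 120L)
  ref <- d[d$form == "reference", ]
  expect_equal(ref$a[ref$item == 2], 2.32)
  expect_equal(ref$b[ref$item == 2], -1.49)
  expect_equal(round(mean(ref$a), 2), 1.51)
  expect_equal(round(sd(ref$a), 2), 0.36)
  p <- load_printed_forms("polytomous")
  prf <- p[p$form == "reference", ]
  expect_equal(round(mean(prf$a), 2), 1.10)
  i41 <- prf[prf$item == 41, ]
  expect_equal(i41$a, 1.21)
  expect_equal(c(i41$b1, i41$b2, i41$b3, i41$b4),
               c(-1.40, -1.17, -0.24, 0.80))
  expect_equal(i41$testlet, 5)
  expect_true(i41$anchor)
})

test_that("printed form pair reconstruction shares one anchor block and groups testlets by length", {
  set.seed(13)
  for (len in c(5L, 10L)) {
    fp <- printed_form_pair("dichotomous", len, "low")
    expect_equal(nrow(fp$items), 100L)
    expect_true(all(table(fp$items$testlet_id) == len))
    expect_equal(sum(fp$items$anchor), 20L)
    # base non-anchor parameters come from the printed reference form
    ref <- load_printed_forms("dichotomous")
    ref <- ref[ref$form == "reference" & ref$item <= 40, ]
    expect_equal(fp$items$a[fp$items$form == "base"], ref$a)
    # anchors are the new form's printed anchor block
    nf <- load_printed_forms("dichotomous")
    nf <- nf[nf$form == "new" & nf$item >= 41, ]
    expect_equal(fp$items$a[fp$items$anchor], nf$a)
    expect_true(all(dplyr::between(fp$testlets$sigma2, 0.1, 0.5)))
  }
})
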