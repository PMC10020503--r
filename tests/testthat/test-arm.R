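test_that("rule statistics reproduce the printed co-prescription table", {
  # (freq_x, freq_y, freq_xy) rows with n_total = 7376, against the
  # printed 2-decimal support/confidence/lift values
  rows <- list(
    list(399, 557, 145, c(1.97, 36.34, 4.81)),
    list(280, 324, 96,  c(1.30, 34.29, 7.81)),
    list(540, 557, 91,  c(1.23, 16.85, 2.23)),
    list(466, 540, 91,  c(1.23, 19.53, 2.67)),
    list(280, 399, 88,  c(1.19, 31.43, 5.81)))
  for (r in rows) {
    s <- rule_stats(r[[1]], r[[2]], r[[3]], 7376)
    got <- round_half_up(c(s$support_pct, s$confidence_pct, s$lift), 2)
    expect_equal(got, r[[4]], info = paste(r[[1]], r[[2]], r[[3]]))
  }
  # degenerate singleton catalog: perfect co-occurrence
  s1 <- rule_stats(10, 10, 10, 10)
  expect_equal(c(s1$support_pct, s1$confidence_pct, s1$lift),
               c(100, 100, 1))
  expect_error(rule_stats(0, 10, 0, 100), class = "herbsurv_data_error")
  expect_error(rule_stats(10, 10, 11, 100), class = "herbsurv_data_error")
})

test_that("rule orientation puts the rarer product on the left", {
  expect_identical(orient_rule("HL", "HQ", 399, 557), c("HL", "HQ"))
  expect_identical(orient_rule("HQ", "HL", 557, 399), c("HL", "HQ"))
  expect_identical(orient_rule("GC", "HQ", 540, 557), c("GC", "HQ"))
  expect_identical(orient_rule("B", "A", 5, 5), c("A", "B"))  # tie: lexical
  # all five printed orientations from the marginals alone
  pr <- printed_rules()
  for (i in seq_len(nrow(pr))) {
    expect_identical(
      orient_rule(pr$y[i], pr$x[i], pr$freq_y[i], pr$freq_x[i]),
      c(pr$x[i], pr$y[i]))
  }
})

test_that("transactions are patient-days with deduplicated products", {
  rx <- chm_rows("P1", rep("2014-01-05", 3), c("A", "B", "A"))
  ts <- build_transactions(rx)
  expect_equal(ts$n_total, 1L)
  expect_equal(sort(ts$items$product_code), c("A", "B"))
  # same product twice on one day counts once
  r <- top_rules(ts, k = Inf)
  expect_equal(r$freq_xy, 1L)
  expect_equal(r$freq_x, 1L)
  # two days for one patient are two transactions
  rx2 <- chm_rows("P1", c("2014-01-05", "2014-01-09"), c("A", "A"))
  expect_equal(build_transactions(rx2)$n_total, 2L)
  expect_equal(build_transactions(rx2[0, ])$n_total, 0L)
})

test_that("pair tallies equal brute-force enumeration", {
  set.seed(44)
  n_tx <- 400
  prods <- LETTERS[1:8]
  rx <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
    k <- sample(1:4, 1)
    chm_rows(sprintf("P%03d", i %% 60), as.Date("2014-01-01") + i,
             sample(prods, k))
  }))
  ts <- build_transactions(rx)
  rules <- top_rules(ts, k = Inf, min_freq_xy = 1)
  brute <- brute_pair_counts(ts)
  expect_equal(nrow(rules), nrow(brute))
  key_rules <- apply(cbind(rules$x, rules$y), 1,
                     function(r) paste(sort(r), collapse = "|"))
  key_brute <- paste(brute$a, brute$b, sep = "|")
  m <- match(key_brute, key_rules)
  expect_false(anyNA(m))
  expect_equal(rules$freq_xy[m], brute$freq_xy)
  # ranking: descending joint frequency
  expect_true(all(diff(rules$freq_xy) <= 0))
  # k larger than the pair count returns everything
  expect_equal(nrow(top_rules(ts, k = 10000)), nrow(rules))
})

test_that("rule invariants hold on random transaction sets", {
  set.seed(55)
  for (rep in 1:5) {
    rx <- do.call(rbind, lapply(1:150, function(i) {
      chm_rows(sprintf("P%02d", i %% 25), as.Date("2015-01-01") + i,
               sample(LETTERS[1:6], sample(1:3, 1)))
    }))
    ts <- build_transactions(rx)
    rules <- top_rules(ts, k = Inf)
    n <- ts$n_total
    marg <- table(ts$items$product_code)
    # conservation: product marginals sum to at least n_total
    expect_gte(sum(marg), n)
    for (i in seq_len(nrow(rules))) {
      r <- rules[i, ]
      expect_lte(r$freq_xy, min(r$freq_x, r$freq_y))
      expect_lte(max(r$freq_x, r$freq_y), n)
      expect_gte(r$confidence_pct, r$support_pct)
      # lift symmetry: direction does not change the lift
      s_fwd <- rule_stats(r$freq_x, r$freq_y, r$freq_xy, n)
      s_rev <- rule_stats(r$freq_y, r$freq_x, r$freq_xy, n)
      expect_equal(s_fwd$lift, s_rev$lift, tolerance = 1e-12)
      # lift > 1 iff positive dependence
      expect_identical(s_fwd$lift > 1, r$freq_xy * n > r$freq_x * r$freq_y)
    }
  }
})

test_that("dosage is mean dose x mean duration x prescription count", {
  rx <- chm_rows("P1", c("2014-01-01", "2014-02-01"), c("A", "A"),
                 days = c(7, 7), daily_dose_g = c(3, 5))
  expect_equal(dosage("A", rx), 4 * 7 * 2)
  one <- chm_rows("P1", "2014-01-01", "B", days = 10, daily_dose_g = 2)
  expect_equal(dosage("B", one), 20)
  expect_error(dosage("C", rx), class = "herbsurv_data_error")
  # a stream engineered to the printed marginal-dosage convention:
  # mean dose x mean days x 399 rows = 2575
  n <- 399
  target_per_rx <- 2575 / n  # = mean_dose * mean_days
  rx_hl <- chm_rows("P1", as.Date("2014-01-01") + seq_len(n), rep("HL", n),
                    days = 7, daily_dose_g = target_per_rx / 7)
  expect_equal(round_half_up(dosage("HL", rx_hl), 0), 2575)
})

test_that("network clusters are connected components with attributes", {
  g <- build_graph(printed_rules())
  cl <- graph_clusters(g)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], c("HQ", "GC", "HL", "JG", "HB"))
  expect_setequal(cl[[2]], c("SZRT", "YJT"))
  # single pair: one 2-node component
  g1 <- build_graph(printed_rules()[2, ])
  expect_length(graph_clusters(g1), 1)
  expect_setequal(graph_clusters(g1)[[1]], c("SZRT", "YJT"))
  # component labels agree with a union-find oracle on a random graph
  set.seed(66)
  nodes <- sprintf("N%02d", 1:30)
  e <- data.frame(a = sample(nodes, 50, TRUE), b = sample(nodes, 50, TRUE))
  e <- e[e$a != e$b, ]
  rules <- tibble::tibble(x = e$a, y = e$b, freq_x = 10L, freq_y = 10L,
                          freq_xy = 5L, support_pct = 1,
                          confidence_pct = 50, lift = 2)
  gg <- build_graph(rules)
  oracle <- uf_components(unique(c(e$a, e$b)), as.matrix(e))
  got <- split(gg$nodes$code, gg$nodes$cluster_id)
  key <- function(part) sort(unname(vapply(part, function(s)
    paste(sort(s), collapse = ","), character(1))))
  expect_identical(key(got), key(oracle))
  # thresholds excluding all nodes yield an empty graph with a warning
  expect_warning(g0 <- build_graph(printed_rules(), node_min_freq = 1e6))
  expect_equal(nrow(g0$nodes), 0)
})

test_that("two-decimal rendering round-trips the printed fixture", {
  out <- render_rules(printed_rules())
  expect_equal(out$support_pct, c(1.97, 1.30, 1.23, 1.23, 1.19))
  expect_equal(out$confidence_pct, c(36.34, 34.29, 16.85, 19.53, 31.43))
  expect_equal(out$lift, c(4.81, 7.81, 2.23, 2.67, 5.81))
})
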