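test_that("episode categories convert to interval midpoints", {
  expect_identical(code_count_category("2-3"), 2.5)
  expect_identical(code_count_category("once"), 1)
  expect_identical(code_count_category(c("4-9", "10-15")), c(6.5, 12.5))
  expect_identical(code_count_category("more", 60), 60)
  expect_error(code_count_category("more"),
               class = "cannadid_incomplete_record_error")
  expect_error(code_count_category("more", 12),
               class = "cannadid_incomplete_record_error")
  expect_error(code_count_category("lots"), class = "cannadid_config_error")
})

test_that("episode allocation follows the scheme proportionally", {
  sc <- allocation_scheme()
  expect_identical(unname(unclass(sc)), c(1, 0.75, 0.25, 0))
  a <- allocate_episodes(7, "cannabis_only", sc)
  expect_identical(c(a$minus, a$plus), c(7, 0))
  b <- allocate_episodes(2.5, "occasionally", sc)
  expect_identical(c(b$minus, b$plus), c(1.875, 0.625))
  d <- allocate_episodes(4, "always", sc)
  expect_identical(c(d$minus, d$plus), c(0, 4))
  expect_error(allocate_episodes(-1, "always", sc),
               class = "cannadid_config_error")
})

test_that("decomposition shares match the hand-computed fixture", {
  fx <- burden_fixture()
  bt <- burden_decomposition(fx$sample3, fx$users)
  # per-respondent episode counts: 12.5, 6.5, 2.5, 20, 1, 1
  # minus: 12.5, 4.875, 0.625, 0, 1, 0.75 ; plus: 0, 1.625, 1.875, 20, 0, .25
  tt <- burden_totals(bt)
  expect_equal(tt$total, 43.5)
  expect_equal(tt$minus, 19.75)
  expect_equal(tt$plus, 23.75)
  expect_equal(tt$plus_proportion, 100 * 23.75 / 43.5, tolerance = 1e-12)
  expect_equal(bt$minus_share,
               100 * c(0.75, 1, 0.625, 12.5 + 4.875) / 19.75,
               tolerance = 1e-12)
  expect_equal(bt$plus_share,
               100 * c(0.25, 0, 1.875 + 20, 1.625) / 23.75,
               tolerance = 1e-12)
  expect_equal(bt$pop_share, 100 * c(40, 25, 20, 15) / 100,
               tolerance = 1e-12)
})

test_that("degenerate cases behave as specified", {
  fx <- burden_fixture()
  one <- fx$sample3
  one$cannabis_freq <- "weekly"
  bt <- burden_decomposition(one, data.frame(cannabis_freq =
                                               rep("weekly", 10)))
  expect_equal(bt$minus_share[bt$freq_group == "weekly"], 100)
  expect_equal(bt$plus_share[bt$freq_group == "weekly"], 100)
  # all-minus scheme: plus total 0, minus shares equal all-episode shares
  sc1 <- allocation_scheme(1, 1, 1, 1)
  b1 <- burden_decomposition(fx$sample3, fx$users, sc1)
  expect_equal(burden_totals(b1)$plus, 0)
  al <- allocate_episodes(code_count_category(fx$sample3$duic_count_category,
                                              fx$sample3$duic_count_exact),
                          fx$sample3$couse_category, sc1)
  shares <- tapply(al$total, factor(fx$sample3$cannabis_freq,
                                    c("less_than_monthly", "monthly",
                                      "weekly", "daily")),
                   sum, default = 0)
  expect_equal(b1$minus_share, as.vector(100 * shares / sum(shares)),
               tolerance = 1e-12)
  # zero episodes are an error
  empty <- fx$sample3[0, ]
  expect_error(burden_decomposition(empty, fx$users),
               class = "cannadid_degenerate_share_error")
})

test_that("conservation and normalisation hold over random fixtures", {
  set.seed(19)
  for (i in 1:30) {
    fx <- random_burden_fixture()
    sc <- allocation_scheme(runif(1), runif(1), runif(1), runif(1))
    bt <- burden_decomposition(fx$sample3, fx$users, sc)
    tt <- burden_totals(bt)
    expect_equal(tt$minus + tt$plus, tt$total, tolerance = 1e-9)
    expect_equal(sum(bt$pop_share), 100, tolerance = 1e-6)
    if (tt$minus > 0) expect_equal(sum(bt$minus_share), 100,
                                   tolerance = 1e-6)
    if (tt$plus > 0) expect_equal(sum(bt$plus_share), 100, tolerance = 1e-6)
  }
})

test_that("raising the occasionally fraction never lowers the minus total", {
  fx <- burden_fixture()
  fracs <- seq(0, 1, by = 0.25)
  tots <- vapply(fracs, function(f)
    burden_totals(burden_decomposition(
      fx$sample3, fx$users, allocation_scheme(1, f, 0.25, 0)))$minus,
    numeric(1))
  expect_true(all(diff(tots) >= 0))
})

test_that("bootstrap burden intervals are seeded and contain the point estimate", {
  fx <- burden_fixture()
  b1 <- bootstrap_burden(fx$sample3, fx$users, B = 1, seed = 3)
  expect_equal(b1$minus_share_lo, b1$minus_share_hi, tolerance = 1e-12)
  a <- bootstrap_burden(fx$sample3, fx$users, B = 300, seed = 11)
  b <- bootstrap_burden(fx$sample3, fx$users, B = 300, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (col in c("pop_share", "minus_share", "plus_share")) {
    expect_true(all(a[[col]] >= a[[paste0(col, "_lo")]] - 1e-9),
                label = col)
    expect_true(all(a[[col]] <= a[[paste0(col, "_hi")]] + 1e-9),
                label = col)
  }
})

test_that("scheme sensitivity keeps the dominant group stable on a loaded fixture", {
  # weekly users hold the bulk of polysubstance co-use episodes
  s3 <- data.frame(
    cannabis_freq = c(rep("weekly", 6), rep("daily", 4), "monthly"),
    duic_count_category = c(rep("10-15", 6), rep("2-3", 4), "once"),
    duic_count_exact = NA,
    couse_category = c(rep("mostly", 6), rep("cannabis_only", 4),
                       "occasionally"))
  users <- data.frame(cannabis_freq = rep(c("less_than_monthly", "monthly",
                                            "weekly", "daily"), 10))
  out <- sensitivity_schemes(s3, users, list(
    a = allocation_scheme(1, 0.9, 0.1, 0),
    b = allocation_scheme(1, 0.6, 0.4, 0)))
  for (tb in out)
    expect_identical(as.character(attr(tb, "plus_rank"))[1], "weekly")
  one <- sensitivity_schemes(s3, users, list(allocation_scheme()))
  ref <- burden_decomposition(s3, users)
  for (col in c("pop_share", "minus_share", "plus_share"))
    expect_equal(one[[1]][[col]], ref[[col]], tolerance = 1e-12)
  expect_error(sensitivity_schemes(s3, users, list()),
               class = "cannadid_config_error")
})
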