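test_that("resolve_line handles pack units, the 1 ml = 1 g rule, and generic fallback", {
  cat <- tiny_catalogue(); gen <- tiny_generics()
  # 2 units of a 500 ml drink at 42 kcal/100 ml -> 420 kcal
  r <- resolve_line(tx_line("t1", "2021-01-05", "A", 2), cat, gen)
  expect_equal(unname(r$nutrients["energy_kcal"]), 2 * 500 / 100 * 42)
  expect_equal(r$provenance, "retailer")
  # absent per-100 profile, category 7 -> category-7 generic applied
  r2 <- resolve_line(tx_line("t2", "2021-01-05", "B", 1), cat, gen)
  expect_equal(unname(r2$nutrients["energy_kcal"]), 400 / 100 * (100 + 70))
  expect_equal(r2$provenance, "generic")
  # loose item: 0.35 of a 1000 g pack -> 3.5 x per100
  r3 <- resolve_line(tx_line("t3", "2021-01-05", "C", 0.35), cat, gen)
  expect_equal(unname(r3$nutrients), 3.5 * c(80, 1, 2, 0.1, 0.02, 10))
  # per-unit pack: 2 pies of 150 g
  r4 <- resolve_line(tx_line("t4", "2021-01-05", "D", 2), cat, gen)
  expect_equal(unname(r4$nutrients["energy_kcal"]), 2 * 150 / 100 * 300)
  expect_error(resolve_line(tx_line("t5", "2021-01-05", "ZZ", 1), cat, gen),
               class = "basketdiet_error_lookup")
  expect_error(resolve_line(tx_line("t6", "2021-01-05", "A", 0), cat, gen),
               class = "basketdiet_error_data")
})

test_that("match rate counts distinct products pre-imputation and is 1 after", {
  cat <- tiny_catalogue(); gen <- tiny_generics()
  lines <- dplyr::bind_rows(
    tx_line("t1", "2021-01-05", "A", 1), tx_line("t1", "2021-01-05", "A", 2),
    tx_line("t2", "2021-01-06", "B", 1), tx_line("t2", "2021-01-06", "C", 1),
    tx_line("t3", "2021-01-07", "D", 1)
  )
  mr <- match_rate(lines, cat, gen)
  expect_equal(mr$pre_imputation_rate, 0.75)  # 3 of 4 distinct products
  expect_equal(mr$post_imputation_rate, 1.0)
  mr2 <- match_rate(lines[lines$product_id != "B", ], cat, gen)
  expect_equal(mr2$pre_imputation_rate, 1.0)
  expect_error(match_rate(lines[0, ], cat, gen),
               class = "basketdiet_error_insufficient_data")
})

test_that("daily household estimate divides in-period totals by inclusive day count", {
  cat <- tiny_catalogue(); gen <- tiny_generics()
  period <- comparison_period("2021-01-01", 10)
  expect_equal(period$end, as.Date("2021-01-10"))
  # two lines of 500 kcal each inside a 10-day period -> 100 kcal/d
  lines <- dplyr::bind_rows(
    tx_line("t1", "2021-01-01", "C", 500 / 800),   # 500 kcal of product C
    tx_line("t2", "2021-01-10", "C", 500 / 800),   # boundary day included
    tx_line("t3", "2021-01-11", "C", 99)           # outside, ignored
  )
  res <- resolve_lines(lines, cat, gen)
  est <- daily_household_estimate(res, period)
  expect_equal(unname(est["energy_kcal"]), 100)
  expect_false(attr(est, "no_purchases"))
  # 182000 kcal over a 91-day period -> 2000 kcal/d
  p91 <- comparison_period("2021-01-01", 91)
  l2 <- resolve_lines(tx_line("t1", "2021-02-01", "C", 182000 / 800), cat, gen)
  expect_equal(unname(daily_household_estimate(l2, p91)["energy_kcal"]), 2000)
  # no in-period purchases -> zero vector, flagged
  l3 <- resolve_lines(tx_line("t1", "2022-06-01", "A", 1), cat, gen)
  est3 <- daily_household_estimate(l3, p91)
  expect_equal(as.numeric(est3), rep(0, 6))
  expect_true(attr(est3, "no_purchases"))
})

test_that("estimates are additive over period partitions and scale equivariant", {
  cat <- tiny_catalogue(); gen <- tiny_generics()
  set.seed(3)
  lines <- tibble::tibble(
    customer_id = "ID1",
    transaction_id = paste0("t", 1:40),
    date = as.Date("2021-01-01") + sample(0:59, 40, replace = TRUE),
    product_id = sample(c("A", "B", "C", "D"), 40, replace = TRUE),
    quantity = stats::runif(40, 0.1, 3), cost = 1
  )
  res <- resolve_lines(lines, cat, gen)
  whole <- daily_household_estimate(res, comparison_period("2021-01-01", 60))
  part1 <- daily_household_estimate(res, comparison_period("2021-01-01", 25))
  part2 <- daily_household_estimate(res, comparison_period("2021-01-26", 35))
  expect_equal((25 * unclass(part1) + 35 * unclass(part2)) / 60,
               unclass(whole), tolerance = 1e-12, ignore_attr = TRUE)
  # doubling quantities doubles every component exactly
  lines2 <- dplyr::mutate(lines, quantity = 2 * quantity)
  whole2 <- daily_household_estimate(resolve_lines(lines2, cat, gen),
                                     comparison_period("2021-01-01", 60))
  expect_equal(unclass(whole2), 2 * unclass(whole), ignore_attr = TRUE)
  # provenance partitions the lines
  expect_equal(sum(res$provenance == "retailer") + sum(res$provenance == "generic"),
               nrow(lines))
  expect_setequal(res$provenance[res$product_id == "B"], "generic")
})
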