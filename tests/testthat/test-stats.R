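make_results <- function(a, b, forms = c("oil_solution", "nanoemulsion")) {
  data.frame(animal = rep(sprintf("pig%d", seq_along(a)), 2),
             formulation = rep(forms, each = length(a)),
             f_al = c(b, a))  # second level alphabetically first after sort
}

test_that("paired comparison handles identical and degenerate inputs explicitly", {
  res <- make_results(a = c(1, 2, 3), b = c(1, 2, 3))
  cmp <- paired_formulation_comparison(res, "f_al")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)

  shifted <- make_results(a = c(1, 2, 3), b = c(2, 3, 4))
  cmp <- paired_formulation_comparison(shifted, "f_al")
  expect_true(is.na(cmp$p))
  expect_match(cmp$note, "degenerate")

  expect_error(paired_formulation_comparison(res[c(1, 4), ], "f_al"),
               "fewer than 2")
})

test_that("paired t equals the one-sample t of the differences", {
  set.seed(21)
  a <- rnorm(6, 5); b <- rnorm(6, 4)
  res <- make_results(a, b)
  cmp <- paired_formulation_comparison(res, "f_al")
  ref <- stats::t.test(b - a)  # differences in the group order of the table
  expect_equal(abs(cmp$t), abs(unname(ref$statistic)), tolerance = 1e-12)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-12)
})

test_that("unpaired comparison: identical groups, unequal sizes, strong separation", {
  cmp <- unpaired_species_comparison(c(1, 2, 3), c(1, 2, 3), "f_rl",
                                     labels = c("pigs", "rats"))
  expect_equal(cmp$p, 1, tolerance = 1e-12)

  cmp <- unpaired_species_comparison(c(3.4, 3.8, 3.6),
                                     c(3, 5, 4, 6, 3.5, 2.5), "f",
                                     labels = c("pigs", "rats"))
  expect_equal(cmp$n, c(3, 6))

  set.seed(8)
  hits <- 0L
  for (i in 1:100) {
    g1 <- rnorm(6, 0); g2 <- rnorm(6, 5)
    if (unpaired_species_comparison(g1, g2, "x")$p < 0.001) hits <- hits + 1L
  }
  expect_equal(hits, 100L)
})

test_that("summary tables report sample SD and mark significance", {
  res <- data.frame(animal = rep(c("p1", "p2", "p3"), 2),
                    formulation = rep(c("a_form", "b_form"), each = 3),
                    f = c(2.8, 3.6, 4.4, 7, 8, 9))
  s <- summarize_parameters(res, "formulation", parameters = "f")
  a_row <- s[s$formulation == "a_form", ]
  expect_equal(a_row$mean, 3.6)
  expect_equal(a_row$sd, 0.8)

  single <- summarize_parameters(res[1, ], "formulation", parameters = "f")
  expect_true(is.na(single$sd))

  cmp <- paired_formulation_comparison(
    data.frame(animal = rep(c("p1", "p2", "p3"), 2),
               formulation = rep(c("a_form", "b_form"), each = 3),
               f = c(2.8, 3.6, 4.4, 7, 8, 9)), "f")
  s2 <- summarize_parameters(res, "formulation", parameters = "f",
                             comparisons = list(cmp))
  expect_true(cmp$significant)
  expect_match(s2$label[s2$formulation == "b_form"], "\\*")
  expect_false(grepl("\\*", s2$label[s2$formulation == "a_form"]))
})

test_that("recovery report computes bias and RMSE as defined", {
  truth <- data.frame(animal = c("p1", "p2", "p3"), period = 1,
                      f_al_true = 10, f_ap_true = 5, f_true = 15,
                      f_rl_true = 100 * 10 / 15)
  est <- data.frame(animal = c("p1", "p2", "p3"), period = 1,
                    f_al = c(9, 10, 11), f_ap = 5, f = c(14, 15, 16),
                    f_rl = 100 * c(9, 10, 11) / c(14, 15, 16))
  rep <- recovery_report(truth, est)
  fal <- rep[rep$parameter == "f_al", ]
  expect_equal(fal$bias, 0)
  expect_equal(fal$rmse, sqrt(2 / 3), tolerance = 1e-9)

  exact <- recovery_report(truth,
                           data.frame(animal = truth$animal, period = 1,
                                      f_al = 10, f_ap = 5, f = 15,
                                      f_rl = 100 * 10 / 15))
  expect_true(all(exact$bias == 0) && all(exact$rmse == 0))

  expect_error(recovery_report(truth, est[1:2, ]), "one-to-one")
})

test_that("both tests hold their nominal size under a simulated null", {
  set.seed(99)
  n_rep <- 400
  hits_p <- 0L; hits_u <- 0L
  for (i in seq_len(n_rep)) {
    res <- make_results(rnorm(6), rnorm(6))
    if (paired_formulation_comparison(res, "f_al")$p < 0.05)
      hits_p <- hits_p + 1L
    if (unpaired_species_comparison(rnorm(6), rnorm(6), "x")$p < 0.05)
      hits_u <- hits_u + 1L
  }
  bound <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(hits_p / n_rep - 0.05), bound)
  expect_lt(abs(hits_u / n_rep - 0.05), bound)
})
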