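test_that("classify_neuron applies the subtype rule table", {
  expect_equal(classify_neuron(40, 1, 60, responsive_nondom = FALSE),
               "gate_facilitatory")
  expect_equal(classify_neuron(40, 25, 55, responsive_nondom = TRUE),
               "true_facilitatory")
  expect_equal(classify_neuron(40, 25, 33, responsive_nondom = TRUE),
               "suppressive_between")
  # exact tie with the dominant rate: between (closed interval)
  expect_equal(classify_neuron(40, 25, 40, responsive_nondom = TRUE),
               "suppressive_between")
  expect_equal(classify_neuron(40, 25, 20, responsive_nondom = TRUE),
               "suppressive_other")
  # monocular neuron without binocular modulation
  expect_equal(classify_neuron(40, 0.5, 41, responsive_nondom = FALSE),
               "non_interacting")
  expect_error(classify_neuron(-1, 0, 5), "non-negative")
})

test_that("classification partitions any population", {
  recs <- classify_neurons(rule_table_neurons())
  expect_false(anyNA(recs$class))
  expect_equal(as.character(recs$class),
               c("gate_facilitatory", "true_facilitatory",
                 "suppressive_between", "suppressive_between",
                 "suppressive_other", "non_interacting"))
  set.seed(11)
  pop <- tibble::tibble(
    rate_dom = runif(300, 1, 300),
    rate_nondom = runif(300, 0, 1) * runif(300, 1, 300)
  )
  pop$rate_nondom <- pmin(pop$rate_nondom, pop$rate_dom)
  pop$rate_binoc <- runif(300, 0, 1.5) * pop$rate_dom
  cls <- classify_neurons(pop)
  expect_false(anyNA(cls$class))
  expect_equal(sum(table(cls$class)), nrow(pop))
})

test_that("the reliability rule needs both a relative and an absolute
           criterion to call an eye silent", {
  expect_false(nondom_responsive(100, 3))
  expect_true(nondom_responsive(100, 20))   # above 10% of dominant
  expect_true(nondom_responsive(30, 4.5))   # above 10% though below 5 sp/s
  expect_true(nondom_responsive(100, 8))    # above 5 sp/s floor fails rule 2
})

test_that("macleod_between_filter returns exactly the between subset,
           preserving order", {
  recs <- classify_neurons(rule_table_neurons())
  out <- macleod_between_filter(recs)
  expect_equal(out$id, c("r03", "r04"))
  expect_equal(nrow(macleod_between_filter(recs[0, ])), 0)
  facil <- recs[recs$class == "true_facilitatory", ]
  expect_equal(nrow(macleod_between_filter(facil)), 0)
})

test_that("subject screen requires enhancement at a strict majority of
           frequencies", {
  inc <- subject_enhancement_screen(
    one_subject_csf(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_true(inc$include)
  exc <- subject_enhancement_screen(
    one_subject_csf(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_false(exc$include)   # 3 of 6 is not a majority
  none <- subject_enhancement_screen(one_subject_csf(rep(FALSE, 6)))
  expect_false(none$include)
  expect_equal(none$n_enhancing, 0L)
})

test_that("adding an enhancing frequency never flips an included subject to
           excluded", {
  for (k in 0:5) {
    flags <- rep(c(TRUE, FALSE), c(k, 5 - k))
    before <- subject_enhancement_screen(one_subject_csf(flags))$include
    after <- subject_enhancement_screen(
      one_subject_csf(c(flags, TRUE)))$include
    expect_true(!before || after)
  }
})

test_that("best_worst_split is a row-wise, order-invariant max/min", {
  rec <- tibble::tibble(sens_left = c(30, 30, 10), sens_right = c(45, 30, 80))
  out <- best_worst_split(rec)
  expect_equal(out$sens_best, c(45, 30, 80))
  expect_equal(out$sens_worst, c(30, 30, 10))
  swapped <- best_worst_split(
    tibble::tibble(sens_left = rec$sens_right, sens_right = rec$sens_left))
  expect_equal(out$sens_best, swapped$sens_best)
  expect_equal(out$sens_worst, swapped$sens_worst)
  # the winning eye may switch across frequencies within a subject
  sub <- tibble::tibble(sens_left = c(50, 20), sens_right = c(40, 30))
  expect_equal(best_worst_split(sub)$sens_best, c(50, 30))
})
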