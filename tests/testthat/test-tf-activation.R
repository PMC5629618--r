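make_expr <- function(case, control) {
  # case/control: named lists gene -> numeric vector of sample values
  rows <- list()
  for (g in names(case)) {
    v <- case[[g]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = g, sample = paste0("s", seq_along(v)), group = "case", value = v)
  }
  for (g in names(control)) {
    v <- control[[g]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = g, sample = paste0("c", seq_along(v)), group = "control", value = v)
  }
  dplyr::bind_rows(rows)
}

test_that("fold change is the ratio of group means, zero-control genes dropped", {
  expr <- make_expr(case = list(g1 = c(4, 6), g2 = 3, g3 = c(1, 1)),
                    control = list(g1 = c(2, 3), g2 = 3, g3 = c(0, 0)))
  fc <- compute_fold_change(expr)
  expect_equal(fc$value[fc$gene == "g1"], 2.0)
  expect_equal(fc$value[fc$gene == "g2"], 1.0)
  expect_false("g3" %in% fc$gene)
  expect_equal(attr(fc, "n_dropped"), 1L)
  expect_equal(fc_mode(fc), "ratio")
  expect_error(compute_fold_change(dplyr::filter(expr, group == "case")), "control")
})

test_that("activation score follows the top-3 / all-targets rule", {
  tfmap <- tibble::tibble(tf = c(rep("T1", 4), rep("T2", 2), rep("T3", 3), "T4"),
                          target = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "zz"))
  profile <- fc_profile(c(a = 5, b = 3, c = 1, d = 0.5, e = 1.5, f = 2.5,
                          g = 4, h = 4, i = 4))
  expect_equal(activation_score("T1", profile, tfmap), 3.0)   # mean of 5, 3, 1
  expect_equal(activation_score("T2", profile, tfmap), 2.0)   # two-target branch
  expect_equal(activation_score("T3", profile, tfmap), 4.0)
  expect_true(is.na(activation_score("T4", profile, tfmap)))  # no measured target
  expect_error(activation_score("T9", profile, tfmap), "T9")

  # adding a target below the current 3rd-largest leaves the score unchanged
  tfmap2 <- dplyr::bind_rows(tfmap, tibble::tibble(tf = "T3", target = "j"))
  profile2 <- fc_profile(c(a = 5, b = 3, c = 1, d = 0.5, e = 1.5, f = 2.5,
                           g = 4, h = 4, i = 4, j = 0.1))
  expect_equal(activation_score("T3", profile2, tfmap2), 4.0)
})

test_that("activation score is permutation-invariant and monotone", {
  withr::local_seed(7)
  tfmap <- tibble::tibble(tf = "T1", target = sprintf("t%02d", 1:6))
  for (rep in 1:20) {
    vals <- round(stats::runif(6, 0, 5), 3)
    profile <- fc_profile(stats::setNames(vals, tfmap$target))
    s0 <- activation_score("T1", profile, tfmap)
    perm <- sample(6)
    s1 <- activation_score("T1", fc_profile(stats::setNames(vals[perm], tfmap$target[perm])),
                           tfmap)
    expect_equal(s0, s1)
    # raising any single target never decreases the score
    i <- sample(6, 1)
    vals2 <- vals; vals2[i] <- vals2[i] + stats::runif(1, 0, 2)
    s2 <- activation_score("T1", fc_profile(stats::setNames(vals2, tfmap$target)), tfmap)
    expect_gte(s2, s0)
  }
})

test_that("TF activation threshold is inclusive and recovers planted sets", {
  tfmap <- tibble::tibble(tf = rep(c("T1", "T2"), each = 3),
                          target = c("a", "b", "c", "d", "e", "f"))
  profile <- fc_profile(c(a = 2, b = 2, c = 2, d = 1, e = 1, f = 1))
  act <- identify_activated_tfs(profile, tfmap, threshold = 2.0)
  expect_true(act$activated[act$tf == "T1"])   # score exactly 2.0 counts
  expect_false(act$activated[act$tf == "T2"])
  expect_error(identify_activated_tfs(profile, tfmap[0, ]), "empty")

  # a flat all-1 profile activates nothing
  flat <- fc_profile(stats::setNames(rep(1, 6), c("a", "b", "c", "d", "e", "f")))
  expect_equal(sum(identify_activated_tfs(flat, tfmap)$activated), 0L)

  # planted recovery: 5 of 20 TFs pushed over the threshold
  withr::local_seed(11)
  tfs <- sprintf("TF%02d", 1:20)
  big_map <- tibble::tibble(tf = rep(tfs, each = 4),
                            target = sprintf("g%03d", 1:80))
  planted <- sample(tfs, 5)
  vals <- stats::setNames(rep(1, 80), big_map$target)
  vals[big_map$target[big_map$tf %in% planted]] <- 3.5
  act2 <- identify_activated_tfs(fc_profile(vals), big_map)
  expect_setequal(act2$tf[act2$activated], planted)
})

test_that("case identical to control yields no activation anywhere", {
  genes <- sprintf("g%02d", 1:12)
  expr <- tibble::tibble(gene = rep(genes, 2),
                         sample = rep(c("s1", "c1"), each = 12),
                         group = rep(c("case", "control"), each = 12),
                         value = rep(stats::runif(12, 1, 10), 2))
  fc <- compute_fold_change(expr)
  expect_true(all(fc$value == 1))
  tfmap <- tibble::tibble(tf = rep(c("A", "B"), each = 6), target = genes)
  expect_equal(sum(identify_activated_tfs(fc, tfmap)$activated), 0L)
})

test_that("up-regulated target collection is an inclusive-threshold union", {
  tfmap <- tibble::tibble(tf = c("T1", "T1", "T2"), target = c("g1", "g2", "g1"))
  profile <- fc_profile(c(g1 = 3, g2 = 1))
  expect_equal(upregulated_targets("T1", profile, tfmap), "g1")
  expect_equal(upregulated_targets(character(), profile, tfmap), character())
  # shared boundary-value target counted once across two activated TFs
  profile2 <- fc_profile(c(g1 = 2.0, g2 = 1))
  expect_equal(upregulated_targets(c("T1", "T2"), profile2, tfmap), "g1")
  # data-frame form of `activated` is accepted
  act <- tibble::tibble(tf = c("T1", "T2"), activated = c(TRUE, FALSE))
  expect_equal(upregulated_targets(act, profile, tfmap), "g1")
})
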