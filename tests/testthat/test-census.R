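test_that("single TTT particle gives unit frequencies at both levels", {
  cen <- aggregate_census(labels_from_comps("TTT"))
  expect_equal(cen$n_particles_complete, 1)
  expect_equal(unname(cen$trimer_freqs["TTT"]), 1)
  expect_equal(unname(cen$monomer_freqs["T"]), 1)
  expect_equal(sum(cen$monomer_freqs), 1, tolerance = 1e-12)
})

test_that("the printed composition counts reproduce the printed T-monomer percentage", {
  ## 549 TTO + 318 TTT + 128 TOO + 5 OOO particles -> 72.7 % T monomers
  comps <- rep(c("TTO", "TTT", "TOO", "OOO"), c(549, 318, 128, 5))
  cen <- aggregate_census(labels_from_comps(comps))
  expect_equal(unname(cen$monomer_freqs["T"]), 2180 / 3000, tolerance = 1e-12)
  expect_equal(round(100 * unname(cen$monomer_freqs["T"]), 1), 72.7)
  expect_equal(unname(cen$monomer_freqs["L"]), 0)
  expect_equal(sum(cen$trimer_freqs), 1, tolerance = 1e-12)
})

test_that("particles with unassigned monomers are dropped and reported", {
  tab <- labels_from_comps(c("TTO", "TTT"))
  tab$state_label[3] <- "UNASSIGNED"    # first particle now incomplete
  cen <- aggregate_census(tab)
  expect_equal(cen$n_particles_complete, 1)
  expect_equal(cen$n_particles_dropped, 1)
  expect_equal(unname(cen$trimer_freqs["TTT"]), 1)
  expect_false("TTO" %in% names(cen$trimer_counts))
  ## all-unassigned input has no complete particles
  allu <- labels_from_comps("TTT")
  allu$state_label <- "UNASSIGNED"
  expect_error(aggregate_census(allu), class = "rnd_empty_census")
})

test_that("census equals the exhaustive enumeration oracle on small inputs", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    comps <- sample(c("LTO", "TTO", "TTT", "TOO", "OOO", "LLL"), n,
                    replace = TRUE)
    tab <- labels_from_comps(comps)
    drop_one <- sample(c(TRUE, FALSE), 1) && n > 1
    if (drop_one) tab$state_label[1] <- "UNASSIGNED"
    cen <- aggregate_census(tab)
    ora <- census_oracle(tab)
    expect_equal(cen$n_particles_dropped, ora$dropped)
    expect_equal(cen$trimer_counts[sort(names(cen$trimer_counts))],
                 setNames(as.integer(ora$trimer), names(ora$trimer))[
                   sort(names(ora$trimer))])
    expect_equal(unname(cen$monomer_counts),
                 unname(as.integer(ora$monomer)))
  }
})

test_that("the census is invariant under copy-index permutation within particles", {
  comps <- rep(c("LTO", "TTO", "OOO"), c(5, 3, 2))
  tab <- labels_from_comps(comps)
  set.seed(23)
  shuffled <- dplyr::mutate(dplyr::group_by(tab, particle_id),
                            copy_index = sample(copy_index))
  a <- aggregate_census(tab)
  b <- aggregate_census(dplyr::ungroup(shuffled))
  expect_equal(a$trimer_counts, b$trimer_counts)
  expect_equal(a$monomer_counts, b$monomer_counts)
})

test_that("implied monomer frequencies reproduce the printed arithmetic", {
  f <- implied_monomer_frequencies(c(TTO = 0.549, TTT = 0.318,
                                     OOT = 0.128, OOO = 0.005))
  expect_equal(unname(f["T"]), 0.549 * 2 / 3 + 0.318 + 0.128 / 3,
               tolerance = 1e-12)
  expect_equal(round(100 * unname(f["T"]), 1), 72.7)
  expect_equal(unname(f["L"]), 0)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  f2 <- implied_monomer_frequencies(c(LTO = 1))
  expect_equal(unname(f2[c("L", "T", "O")]), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(implied_monomer_frequencies(c(TTT = 0.5)),
               class = "rnd_census_error")
})

test_that("composition aliases canonicalise and merge ('OTT' is 'TTO')", {
  expect_equal(canonical_composition(c("T", "O", "T")), "TTO")
  expect_equal(canonical_composition("OTT"), "TTO")
  expect_equal(canonical_composition("OO*O*"), "OO*O*")
  expect_equal(canonical_composition(c("O*", "O", "O*")), "OO*O*")
  f <- implied_monomer_frequencies(c(OTT = 0.25, TTO = 0.25, TTT = 0.5))
  expect_equal(unname(f["T"]), 0.5 * 2 / 3 + 0.5, tolerance = 1e-12)
})

test_that("census monomer frequencies equal the implied identity on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    comps <- sample(c("LTO", "TTO", "TTT", "TOO", "OOO", "LLT", "LLL",
                      "OO*O*", "O*O*O*"),
                    sample(5:40, 1), replace = TRUE)
    cen <- aggregate_census(labels_from_comps(comps))
    expect_equal(cen$monomer_freqs,
                 implied_monomer_frequencies(cen$trimer_freqs),
                 tolerance = 1e-12)
  }
})

test_that("recovered frequencies from a large known draw stay within 3 SE", {
  set.seed(47)
  p <- c(TTO = 0.549, TTT = 0.318, TOO = 0.128, OOO = 0.005)
  n <- 10000
  comps <- sample(names(p), n, replace = TRUE, prob = p)
  cen <- aggregate_census(labels_from_comps(comps))
  emp <- table(factor(comps, levels = names(p))) / n
  for (cm in names(p)) {
    got <- if (cm %in% names(cen$trimer_freqs)) cen$trimer_freqs[[cm]] else 0
    expect_equal(got, unname(emp[cm]), tolerance = 1e-12)  # census is exact
    se <- sqrt(p[[cm]] * (1 - p[[cm]]) / n)
    expect_lt(abs(got - p[[cm]]), 3 * se + 1e-12)
  }
})

test_that("bootstrap is seed-reproducible and intervals cover the point estimates", {
  comps <- rep(c("TTO", "TTT", "TOO"), c(60, 30, 10))
  tab <- labels_from_comps(comps)
  b1 <- bootstrap_census(tab, B = 200, seed = 5)
  b2 <- bootstrap_census(tab, B = 200, seed = 5)
  expect_equal(b1$ci, b2$ci)
  tri <- tidy(b1, "trimer")
  expect_true(all(tri$conf.low <= tri$freq + 1e-12 &
                    tri$freq <= tri$conf.high + 1e-12))
  mono <- tidy(b1, "monomer")
  got <- mono[mono$count > 0, ]
  expect_true(all(got$conf.low <= got$freq + 1e-12 &
                    got$freq <= got$conf.high + 1e-12))
})

test_that("bootstrap intervals achieve near-nominal coverage for the modal composition", {
  p <- c(TTO = 0.549, TTT = 0.318, TOO = 0.128, OOO = 0.005)
  n <- 200; B <- 200; reps <- 500
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(8000 + r)
    comps <- sample(names(p), n, replace = TRUE, prob = p)
    cen <- bootstrap_census(labels_from_comps(comps), B = B, seed = 8000 + r)
    ci <- cen$ci$trimer
    row <- ci[ci$composition == "TTO", ]
    covered[r] <- nrow(row) == 1 && row$lo <= p[["TTO"]] && p[["TTO"]] <= row$hi
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("independence test is degenerate for a single state", {
  g <- independence_test(aggregate_census(labels_from_comps(rep("TTT", 10))))
  expect_equal(g$g_statistic, 0)
  expect_equal(g$p_value, 1)
})

test_that("all-LTO particles are wildly inconsistent with independence", {
  cen <- aggregate_census(labels_from_comps(rep("LTO", 300)))
  g <- independence_test(cen)
  ## direct evaluation of the stated formula: f = (1/3,1/3,1/3),
  ## P(LTO) = 3!/(1!1!1!) * (1/3)^3 = 6/27, G = 2 * 300 * log(1/(6/27))
  expect_equal(g$g_statistic, 2 * 300 * log(27 / 6), tolerance = 1e-9)
  expect_equal(g$dof, 10 - 3)   # 10 multisets of 3 states, 3 states
  expect_lt(g$p_value, 1e-6)
})

test_that("independence-test null p-values are super-uniform at the 1% level", {
  p_ok <- logical(100)
  states <- c("L", "T", "O")
  probs <- c(0.4, 0.35, 0.25)
  n <- 5000
  for (r in 1:100) {
    set.seed(9000 + r)
    tab <- tibble::tibble(
      particle_id = rep(sprintf("p%05d", 1:n), each = 3),
      copy_index = rep(0:2, n),
      state_label = sample(states, 3 * n, replace = TRUE, prob = probs))
    g <- independence_test(aggregate_census(tab))
    p_ok[r] <- g$p_value > 0.01
  }
  expect_gte(sum(p_ok), 98)
})

test_that("tidy and glance summarise the census in broom style", {
  cen <- aggregate_census(labels_from_comps(rep(c("TTO", "TTT"), c(6, 4))))
  mono <- tidy(cen, "monomer")
  expect_named(mono, c("state", "count", "freq"))
  expect_equal(sum(mono$freq), 1, tolerance = 1e-12)
  g <- glance(cen)
  expect_equal(g$n_particles_complete, 10)
  expect_equal(g$n_compositions, 2)
  gt <- glance(independence_test(cen))
  expect_named(gt, c("statistic", "df", "p.value"))
})
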