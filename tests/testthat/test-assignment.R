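lib <- make_reference_library()
cfg <- run_config()

test_that("each reference classifies as itself with zero RMSD", {
  for (st in c("L", "T", "O")) {
    a <- assign_state(lib$states[[st]], lib, cfg)
    expect_equal(a$state_label, st)
    expect_equal(a[[paste0("rmsd_", st)]], 0, tolerance = 1e-9)
    expect_gt(a$margin, 1)
    expect_false(a$tie)
  }
})

test_that("synthetic references are mutually separated in porter RMSD", {
  pr <- attr(lib, "porter_rmsd")
  expect_true(all(pr[upper.tri(pr)] >= 2))
})

test_that("noisy copies of the T reference are always labelled T", {
  base <- lib$states$T
  for (i in 1:50) {
    set.seed(4000 + i)
    noisy <- set_coords(base, coords(base) +
                          matrix(stats::rnorm(3 * nrow(base), sd = 0.2),
                                 ncol = 3))
    a <- assign_state(noisy, lib, cfg)
    expect_equal(a$state_label, "T")
  }
})

test_that("assignment is invariant under rigid transformation of the monomer", {
  noisy <- set_coords(lib$states$O, coords(lib$states$O) +
                        matrix(stats::rnorm(3 * nrow(lib$states$O), sd = 0.3),
                               ncol = 3))
  a0 <- assign_state(noisy, lib, cfg)
  for (sd in c(51, 52, 53)) {
    a1 <- assign_state(apply_transform(noisy, random_rigid(sd)), lib, cfg)
    expect_equal(a1$state_label, a0$state_label)
    for (st in c("L", "T", "O"))
      expect_equal(a1[[paste0("rmsd_", st)]], a0[[paste0("rmsd_", st)]],
                   tolerance = 1e-6)
  }
})

test_that("exact ties go to the first state in precedence order with the tie flag", {
  ## halfway monomer: L with PN2/PC2 shifted by half the T-state shifts
  ## (all coordinates exactly representable, so the tie is exact)
  mid <- lib$states$L
  xyz <- coords(mid)
  xyz[mid$resno %in% lib$scheme$PN2, 1] <-
    xyz[mid$resno %in% lib$scheme$PN2, 1] + 2
  xyz[mid$resno %in% lib$scheme$PC2, 2] <-
    xyz[mid$resno %in% lib$scheme$PC2, 2] + 2
  mid <- set_coords(mid, xyz)
  a <- assign_state(mid, lib, cfg)
  expect_equal(a$rmsd_L, a$rmsd_T, tolerance = 1e-12)
  expect_equal(a$state_label, "L")
  expect_true(a$tie)
})

test_that("low-coverage monomers come back UNASSIGNED with a reason", {
  frag <- lib$states$T[lib$states$T$resno <= 20, ]
  a <- assign_state(as_structure(frag, "frag"), lib, cfg)
  expect_equal(a$state_label, "UNASSIGNED")
  expect_match(a$reason, "coverage")
})

test_that("subdomain displacements vanish for a self comparison", {
  d <- subdomain_displacements(lib$states$T, lib$states$T, lib$scheme)
  expect_true(all(!d$missing))
  expect_equal(d$translation, rep(0, nrow(d)), tolerance = 1e-9)
  expect_equal(d$rotation_angle, rep(0, nrow(d)), tolerance = 1e-6)
})

test_that("a pure PN1 translation is reported on PN1 only", {
  ref <- lib$states$L
  moved <- ref
  sel <- moved$resno %in% lib$scheme$PN1
  xyz <- coords(moved)
  xyz[sel, 3] <- xyz[sel, 3] + 2.0
  moved <- set_coords(moved, xyz)
  d <- subdomain_displacements(moved, ref, lib$scheme)
  expect_equal(d$translation[d$subdomain == "PN1"], 2.0, tolerance = 1e-6)
  expect_equal(d$translation[d$subdomain != "PN1"], rep(0, 3), tolerance = 1e-6)
})

test_that("a pure PN2 rotation about its centroid is recovered as 10 degrees", {
  ref <- lib$states$L
  moved <- ref
  sel <- moved$resno %in% lib$scheme$PN2
  xyz <- coords(moved)
  cen <- colMeans(xyz[sel, , drop = FALSE])
  R <- rotation_about_axis(c(0, 1, 0), 10)
  xyz[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2, cen) %*% t(R), 2, cen, "+")
  moved <- set_coords(moved, xyz)
  d <- subdomain_displacements(moved, ref, lib$scheme)
  expect_equal(d$rotation_angle[d$subdomain == "PN2"], 10, tolerance = 1e-6)
  expect_equal(d$translation[d$subdomain == "PN2"], 0, tolerance = 1e-6)
})

test_that("missing subdomains are flagged while others are still reported", {
  ref <- lib$states$L
  chopped <- as_structure(ref[!ref$resno %in% lib$scheme$PC2, ], "chopped")
  d <- subdomain_displacements(chopped, ref, lib$scheme)
  expect_true(d$missing[d$subdomain == "PC2"])
  expect_false(any(d$missing[d$subdomain != "PC2"]))
})

o_lib <- make_reference_library(template_geometry(with_exit_pore = TRUE),
                                states = c("L", "T", "O", "O*"))

test_that("open and constricted exit pores are separated by the O* detector", {
  det_open <- detect_O_star(o_lib$states$O, o_lib$scheme, cfg)
  expect_false(det_open$is_o_star)
  expect_equal(det_open$bottleneck, 2.5, tolerance = cfg$spacing)
  det_closed <- detect_O_star(o_lib$states[["O*"]], o_lib$scheme, cfg)
  expect_true(det_closed$is_o_star)
  expect_lt(det_closed$bottleneck, 1.5)
})

test_that("O and O* templates share porter architecture; assignment relabels via the channel", {
  sch <- o_lib$scheme
  a <- ca_by_resno(o_lib$states$O, porter_residues(sch))$xyz
  b <- ca_by_resno(o_lib$states[["O*"]], porter_residues(sch))$xyz
  expect_equal(a, b, tolerance = 1e-12)   # identical porter: RMSD(O, O*) = 0
  cfg_o <- run_config(check_o_star = TRUE)
  a_star <- assign_state(o_lib$states[["O*"]], o_lib, cfg_o)
  expect_equal(a_star$state_label, "O*")
  expect_true(a_star$o_star_checked)
  expect_lt(a_star$bottleneck, 1.5)
  a_open <- assign_state(o_lib$states$O, o_lib, cfg_o)
  expect_equal(a_open$state_label, "O")
  ## L/T winners are never O*-checked
  a_t <- assign_state(o_lib$states$T, o_lib, cfg_o)
  expect_false(a_t$o_star_checked)
})

test_that("missing exit-seed residues raise a precondition error naming them", {
  s <- o_lib$states$O
  stripped <- as_structure(s[!s$resno %in% o_lib$scheme$exit_seed, ], "x")
  err <- expect_error(detect_O_star(stripped, o_lib$scheme, cfg),
                      class = "rnd_precondition_error")
  expect_match(conditionMessage(err), as.character(o_lib$scheme$exit_seed[1]))
})

test_that("side-chain orientation feature follows the constructed distances", {
  triad <- as_structure(tibble::tibble(
    chain = "A",
    resno = c(946L, 947L, 410L, 411L),
    resname = c("LYS", "ASN", "ASP", "ASP"),
    atom = c("NZ", "OD1", "OD1", "OD2"),
    element = c("N", "O", "O", "O"),
    x = c(0, 3, 6, 6), y = 0, z = c(0, 0, 0, 1), occ = 1, b = 0),
    model_id = "triad")
  f <- sidechain_orientation_feature(triad, lys = 946, asn = 947,
                                     asp = c(410, 411))
  expect_false(f$missing)
  expect_equal(f$d_to_asn, 3.0)
  expect_equal(f$d_to_asp_min, 6.0)
  expect_true(f$flipped)

  ## strict inequality: equidistant is not flipped
  sym <- triad
  sym$x[2] <- 6
  f2 <- sidechain_orientation_feature(sym, 946, 947, c(410, 411))
  expect_false(f2$flipped)

  ## truncated lysine side chain: missing feature, no error
  trunc <- as_structure(triad[triad$atom != "NZ", ], "trunc")
  f3 <- sidechain_orientation_feature(trunc, 946, 947, c(410, 411))
  expect_true(f3$missing)
  expect_true(is.na(f3$d_to_asn))
})

test_that("assignment error stays below 1 percent when states are separable", {
  ## sigma * sqrt(6) = 0.49 against minimum porter separation 2.83 (> 4x)
  sigma <- 0.2
  wrong <- 0L; total <- 0L
  for (i in 1:40) {
    set.seed(6000 + i)
    st <- sample(c("L", "T", "O"), 1)
    noisy <- set_coords(lib$states[[st]], coords(lib$states[[st]]) +
                          matrix(stats::rnorm(3 * nrow(lib$states[[st]]),
                                              sd = sigma), ncol = 3))
    a <- assign_state(noisy, lib, cfg)
    wrong <- wrong + (a$state_label != st)
    total <- total + 1L
  }
  expect_lt(wrong / total, 0.01 + 1e-9)
})
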