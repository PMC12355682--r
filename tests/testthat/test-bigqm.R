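test_that("radius limits: tiny r keeps the base residues, huge r takes all", {
  fx <- generate_fixture(fixture_spec(9, "ALA", seed = 4),
                         with_terms = FALSE)
  at <- fx$system$atoms
  base <- at$index[at$residue_id == 5L]

  tiny <- select_bigqm(fx$system, bigqm_spec(1e-6, base))
  # relocation still pushes peptide cuts two residues out; the *distance*
  # rule alone selects exactly the base residue
  expect_true(all(at$index[at$residue_id == 5L] %in% tiny$atoms))
  expect_setequal(tiny$residues, 3:7)

  big <- select_bigqm(fx$system, bigqm_spec(1e4, base))
  expect_identical(big$atoms, sort(at$index))
  expect_equal(nrow(big$junctions), 0L)
})

test_that("nine-residue chain, base residue 5, small r: relocation yields 3..7", {
  fx <- generate_fixture(fixture_spec(9, "ALA", seed = 1),
                         with_terms = FALSE)
  at <- fx$system$atoms
  base <- at$index[at$residue_id == 5L]
  reg <- select_bigqm(fx$system, bigqm_spec(2, base))
  expect_setequal(reg$residues, 3:7)
  expect_setequal(reg$atoms, at$index[at$residue_id %in% 3:7])
  # both remaining cuts are peptide bonds two residues from the base
  expect_equal(nrow(reg$junctions), 2L)
})

test_that("selection is monotone in r and matches the brute-force scan", {
  fx <- generate_fixture(fixture_spec(9, c("ALA", "ALA", "ALA", "HOH",
                                           "ALA", "ALA", "HOH", "ALA",
                                           "ALA"), seed = 6),
                         with_terms = FALSE)
  at <- fx$system$atoms
  base <- at$index[at$residue_id == 5L]
  radii <- c(3, 6, 10, 14, 20)
  prev <- integer(0)
  for (r in radii) {
    reg <- select_bigqm(fx$system, bigqm_spec(r, base))
    expect_true(all(prev %in% reg$atoms))
    prev <- reg$atoms
  }
  # rule-(i) oracle at a radius with no relocation pressure: residues with
  # any atom within r of any base atom, by an independent all-pairs scan
  r <- 14
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bpos <- match(base, at$index)
  oracle_res <- sort(unique(at$residue_id[vapply(seq_len(nrow(at)),
    function(p) {
      any(sqrt(colSums((t(xyz[bpos, , drop = FALSE]) - xyz[p, ])^2)) <= r)
    }, TRUE)]))
  reg <- select_bigqm(fx$system, bigqm_spec(r, base))
  expect_setequal(reg$residues, oracle_res)
  # atom mode reproduces the raw distance hits exactly
  raw <- select_bigqm(fx$system, bigqm_spec(r, base, completion = "atom"))
  oracle_atoms <- at$index[vapply(seq_len(nrow(at)), function(p) {
    any(sqrt(colSums((t(xyz[bpos, , drop = FALSE]) - xyz[p, ])^2)) <= r)
  }, TRUE)]
  expect_setequal(raw$atoms, sort(unique(c(oracle_atoms, base))))
})

test_that("backbone spans contribute backbone atoms; buried charges come in whole", {
  fx <- generate_fixture(fixture_spec(9, "ALA", seed = 2),
                         with_terms = FALSE)
  at <- fx$system$atoms
  base <- at$index[at$residue_id == 5L]
  reg <- select_bigqm(fx$system, bigqm_spec(2, base, backbone_spans = 1L))
  bb1 <- at$index[at$residue_id == 1L &
                    at$name %in% c("N", "H", "CA", "HA", "C", "O")]
  expect_true(all(bb1 %in% reg$atoms))
  expect_false(any(at$index[at$residue_id == 1L & at$name == "CB"] %in%
                     reg$atoms))
  expect_error(select_bigqm(fx$system,
                            bigqm_spec(2, base, backbone_spans = 99L)),
               "unknown residue")
})

test_that("Shrake-Rupley exposure: isolated, occluded, convergent, invariant", {
  fx <- generate_fixture(fixture_spec(1, "ALA", seed = 1),
                         with_terms = FALSE)
  iso <- classify_exposure(fx$system)
  expect_equal(iso$rel_sasa, 1, tolerance = 0.05)

  # residue enclosed in a shell of dummy atoms is buried
  shell_pts <- 4 * qmmmtools:::.fibonacci_sphere(60)
  enclosed <- build_system(tibble::tibble(
    index = 0:60,
    name = c("O", paste0("X", 1:60)),
    element = c("O", rep("C", 60)),
    residue_id = c(1L, rep(2L, 60)),
    residue_name = c("HOH", rep("SHL", 60)),
    x = c(0, shell_pts[, 1]), y = c(0, shell_pts[, 2]),
    z = c(0, shell_pts[, 3]), charge = 0
  ))
  occ <- classify_exposure(enclosed)
  expect_lt(occ$rel_sasa[occ$residue_id == 1L], 0.05)

  # doubling the sphere sampling moves no fraction by more than 0.02
  fx3 <- generate_fixture(fixture_spec(3, c("ALA", "ARG", "ALA"),
                                       seed = 3), with_terms = FALSE)
  e1 <- classify_exposure(fx3$system, n_sphere_points = 480)
  e2 <- classify_exposure(fx3$system, n_sphere_points = 960)
  expect_lt(max(abs(e1$rel_sasa - e2$rel_sasa)), 0.02)

  # rotation + translation changes fractions only within sampling noise
  moved <- rotate_system(fx3$system, random_rotation(7), shift = c(5, 1, -3))
  e3 <- classify_exposure(moved, n_sphere_points = 960)
  expect_lt(max(abs(e3$rel_sasa - e2$rel_sasa)), 0.02)
})

test_that("neutralization edits: ARG/LYS lose a proton, ASP/GLU gain one", {
  fx <- generate_fixture(fixture_spec(7, c("ALA", "ARG", "ALA", "ASP",
                                           "GLU", "ALA", "LYS"), seed = 5),
                         with_terms = FALSE)
  res <- neutralize_exposed_charges(fx$system, c(2L, 4L, 5L, 7L),
                                    pairing_rule = FALSE)
  expect_equal(nrow(res$edits), 4L)
  expect_equal(sum(res$system$residues$formal_charge), 0L)
  at <- res$system$atoms

  expect_false(any(at$residue_id == 2L & at$name == "HH22"))
  expect_false(any(at$residue_id == 7L & at$name == "HZ3"))
  expect_equal(res$edits$action[match(c(2L, 7L), res$edits$residue_id)],
               c("delete_atom", "delete_atom"))

  for (spec in list(list(res_id = 4L, o = "OD1", h = "HD1"),
                    list(res_id = 5L, o = "OE2", h = "HE2"))) {
    h <- at[at$residue_id == spec$res_id & at$name == spec$h, ]
    o <- at[at$residue_id == spec$res_id & at$name == spec$o, ]
    expect_equal(nrow(h), 1L)
    d <- sqrt(sum((unlist(h[, c("x", "y", "z")]) -
                     unlist(o[, c("x", "y", "z")]))^2))
    expect_equal(d, 0.97, tolerance = 1e-6 / 0.97)
    expect_true(any(res$system$bonds$i == o$index &
                      res$system$bonds$j == h$index) ||
                  any(res$system$bonds$j == o$index &
                        res$system$bonds$i == h$index))
  }

  # each edited residue's partial charges now sum to exactly zero
  for (r in c(2L, 4L, 5L, 7L)) {
    expect_lt(abs(sum(at$charge[at$residue_id == r])), 1e-12)
  }
  # formal charge delta bookkeeping: one unit per edit
  expect_setequal(res$edits$formal_charge_delta, c(-1L, 1L, 1L, -1L))
})

test_that("ion-paired residues are exempt under the pairing rule", {
  fx <- generate_fixture(fixture_spec(4, c("ALA", "ARG", "ASP", "ALA"),
                                      geometry = "linear", seed = 8),
                         with_terms = FALSE)
  at <- fx$system$atoms
  # drag the ASP side chain next to the ARG guanidinium to form the pair
  nh2 <- unlist(at[at$residue_id == 2L & at$name == "NH2",
                   c("x", "y", "z")])
  od1 <- unlist(at[at$residue_id == 3L & at$name == "OD1",
                   c("x", "y", "z")])
  shift <- nh2 + c(0, 2.8, 0) - od1
  side3 <- at$residue_id == 3L & !at$name %in% c("N", "H", "CA", "HA",
                                                 "C", "O")
  at$x[side3] <- at$x[side3] + shift[1]
  at$y[side3] <- at$y[side3] + shift[2]
  at$z[side3] <- at$z[side3] + shift[3]
  paired_sys <- build_system(at, fx$system$bonds, fx$system$residues)

  res <- neutralize_exposed_charges(paired_sys, c(2L, 3L),
                                    pairing_rule = TRUE)
  expect_equal(nrow(res$edits), 0L)
  expect_identical(res$system$residues$formal_charge,
                   fx$system$residues$formal_charge)

  # and without the rule both are edited
  res2 <- neutralize_exposed_charges(paired_sys, c(2L, 3L),
                                     pairing_rule = FALSE)
  expect_equal(nrow(res2$edits), 2L)
})

test_that("neutralization rejects wrong types and warns on neutral residues", {
  fx <- generate_fixture(fixture_spec(2, c("ALA", "ARG"), seed = 1),
                         with_terms = FALSE)
  expect_error(neutralize_exposed_charges(fx$system, 1L),
               "not a neutralizable type")
  neutral <- fx$system
  neutral$residues$formal_charge[2] <- 0L
  expect_warning(res <- neutralize_exposed_charges(neutral, 2L),
                 "already neutral")
  expect_equal(nrow(res$edits), 0L)
})

test_that("region reports count atoms, residues, waters, junctions, charge", {
  fx <- generate_fixture(fixture_spec(4, c("ALA", "ARG", "HOH", "ASP"),
                                      seed = 3), with_terms = FALSE)
  at <- fx$system$atoms
  empty <- region_report(fx$system, integer(0))
  expect_equal(unlist(empty), c(n_atoms = 0, n_residues = 0, n_waters = 0,
                                n_junctions = 0, net_formal_charge = 0))
  full <- region_report(fx$system, at$index)
  expect_equal(full$n_atoms, nrow(at))
  expect_equal(full$n_residues, 4L)
  expect_equal(full$n_waters, 1L)
  expect_equal(full$n_junctions, 0L)
  expect_equal(full$net_formal_charge, 0L)

  base <- at$index[at$residue_id == 2L]
  # base next to the N-terminus: relocation legitimately hits the chain end
  r1 <- region_report(fx$system, suppressWarnings(
    select_bigqm(fx$system, bigqm_spec(2, base)))$atoms)
  r2 <- region_report(fx$system, suppressWarnings(
    select_bigqm(fx$system, bigqm_spec(8, base)))$atoms)
  expect_true(all(unlist(r2[, 1:4]) >= unlist(r1[, 1:4])))
})
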