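test_that("surrogate backend: analytic external Coulomb, determinism, ESP", {
  sys <- build_system(tibble::tibble(
    index = 0L, name = "A", element = "C", residue_id = 1L,
    residue_name = "UNK", x = 0, y = 0, z = 0, charge = 0.4
  ))
  terms <- ff_terms(lj = tibble::tibble(index = 0L, eps = 0, sigma = 1))
  be <- surrogate_backend(sys, terms)
  geom <- qm_geometry(sys, region_partition(sys, 0L))
  ext <- tibble::tibble(x = 0, y = 0, z = 2, charge = -0.25)
  res <- be$evaluate(geom, external = ext, want_esp = TRUE)
  expect_equal(res$energy, 1389.35458 * 0.4 * (-0.25) / 2,
               tolerance = 1e-12)
  expect_equal(res$esp, 0.4)
  expect_identical(res$energy, be$evaluate(geom, external = ext)$energy)
  expect_equal(be$evaluate(geom)$energy, 0)  # empty external: vacuum only
})

test_that("additive and subtractive ME agree on every junction fixture", {
  kinds <- c("single_cut", "two_cuts_same_residue", "ring_adjacent",
             "water_in_qm")
  for (kind in kinds) {
    case <- make_junction_case(kind)
    a <- assemble_me_additive(case$system, case$terms, case$partition)
    s <- assemble_me_subtractive(case$system, case$terms, case$partition)
    expect_lt(abs(a$total - s$total), 1e-9)
  }
  for (seed in 1:6) {
    f <- random_junction_fixture(seed)
    a <- assemble_me_additive(f$system, f$terms, f$partition)
    s <- assemble_me_subtractive(f$system, f$terms, f$partition)
    expect_lt(abs(a$total - s$total), 1e-9)
    # same identity with a supplied ESP charge set on the QM side
    esp <- tibble::tibble(
      index = f$partition$qm,
      charge = withr::with_seed(seed, {
        stats::runif(length(f$partition$qm), -0.4, 0.4)
      }))
    a2 <- assemble_me_additive(f$system, f$terms, f$partition,
                               charge_source = "supplied_esp",
                               esp_charges = esp)
    s2 <- assemble_me_subtractive(f$system, f$terms, f$partition,
                                  charge_source = "supplied_esp",
                                  esp_charges = esp)
    expect_lt(abs(a2$total - s2$total), 1e-9)
  }
})

test_that("every report's total recomputes from its own components", {
  case <- make_junction_case("single_cut")
  reports <- list(
    assemble_me_additive(case$system, case$terms, case$partition),
    assemble_me_subtractive(case$system, case$terms, case$partition),
    assemble_ee_subtractive(case$system, case$terms, case$partition),
    assemble_ee_additive(case$system, case$terms, case$partition),
    assemble_bigqm(case$system, case$terms, case$partition$qm)
  )
  for (r in reports) expect_lt(abs(r$total - audit_total(r)), 1e-9)
})

test_that("EE totals under two schemes differ by the model-difference Coulomb", {
  case <- make_junction_case("single_cut")
  jns <- find_junctions(case$system, case$partition)
  geom <- qm_geometry(case$system, case$partition, jns)
  live <- geom[geom$charge != 0, ]
  models <- lapply(scheme_ids, function(s)
    apply_scheme(case$system, case$partition, jns, s))
  names(models) <- scheme_ids
  totals <- vapply(scheme_ids, function(s)
    assemble_ee_subtractive(case$system, case$terms, case$partition,
                            scheme = s)$total, 0)
  for (a in c("Z0", "Z1", "RCD")) {
    for (b in c("CS", "DZ2", "ZZ2")) {
      diff_model <- dplyr::bind_rows(
        tibble::as_tibble(models[[a]]),
        dplyr::mutate(tibble::as_tibble(models[[b]]), charge = -charge))
      expected <- oracle_cross_coulomb(live, diff_model)
      expect_lt(abs((totals[[a]] - totals[[b]]) - expected), 1e-9)
    }
  }
})

test_that("degenerate partitions collapse every formulation to the backend energy", {
  case <- make_junction_case("single_cut")
  part_all <- region_partition(case$system, case$system$atoms$index)
  be <- surrogate_backend(case$system, case$terms)
  e_backend <- be$evaluate(qm_geometry(case$system, part_all))$energy

  expect_equal(assemble_me_additive(case$system, case$terms,
                                    part_all)$total, e_backend,
               tolerance = 1e-12)
  expect_equal(assemble_me_subtractive(case$system, case$terms,
                                       part_all)$total, e_backend,
               tolerance = 1e-12)
  expect_equal(assemble_ee_subtractive(case$system, case$terms,
                                       part_all)$total, e_backend,
               tolerance = 1e-12)
  expect_equal(assemble_ee_additive(case$system, case$terms,
                                    part_all)$total, e_backend,
               tolerance = 1e-12)
  expect_equal(assemble_bigqm(case$system, case$terms,
                              case$system$atoms$index)$total, e_backend,
               tolerance = 1e-12)
  expect_error(region_partition(case$system, integer(0)), "nonempty")
})

test_that("without junctions all schemes and both EE formulations coincide", {
  fx <- generate_fixture(fixture_spec(3, c("ALA", "ALA", "HOH"), seed = 2))
  at <- fx$system$atoms
  part <- region_partition(fx$system, at$index[at$residue_id == 3L])
  totals <- vapply(scheme_ids, function(s)
    assemble_ee_subtractive(fx$system, fx$terms, part, scheme = s)$total, 0)
  expect_equal(max(totals) - min(totals), 0)
  add <- assemble_ee_additive(fx$system, fx$terms, part)
  expect_lt(abs(add$total - totals[[1]]), 1e-9)
})

test_that("DLB/DLAD flags change the EE-additive total by exactly the named terms", {
  case <- make_junction_case("single_cut")
  # shift the equilibria so cross-boundary bonded terms are nonzero
  case$terms$bonds$r0 <- case$terms$bonds$r0 - 0.05
  case$terms$angles$theta0 <- case$terms$angles$theta0 - 0.05
  base <- assemble_ee_additive(case$system, case$terms, case$partition)
  dlb <- assemble_ee_additive(case$system, case$terms, case$partition,
                              link_bond = TRUE)
  dlad <- assemble_ee_additive(case$system, case$terms, case$partition,
                               link_bond = TRUE,
                               link_angles_torsions = TRUE)
  e_bond <- qmmm_interaction_mm(case$system, case$terms, case$partition,
                                elec = FALSE, lj = FALSE,
                                link_bond = TRUE,
                                link_angles_torsions = FALSE)
  e_ang_tor <- qmmm_interaction_mm(case$system, case$terms, case$partition,
                                   elec = FALSE, lj = FALSE,
                                   link_bond = FALSE,
                                   link_angles_torsions = TRUE)
  expect_equal(dlb$total - base$total, e_bond, tolerance = 1e-12)
  expect_equal(dlad$total - dlb$total, e_ang_tor, tolerance = 1e-12)
  expect_gt(abs(e_bond), 0)
})

test_that("big-QM assembly reduces to EE subtractive and stays deterministic", {
  case <- make_junction_case("single_cut")
  ee <- assemble_ee_subtractive(case$system, case$terms, case$partition)
  bq <- assemble_bigqm(case$system, case$terms, case$partition$qm)
  expect_lt(abs(bq$total - ee$total), 1e-9)
  expect_identical(bq$components, assemble_bigqm(case$system, case$terms,
                                                 case$partition$qm)$components)
})

test_that("subtractive ME demands MM parameters for the QM region", {
  case <- make_junction_case("single_cut")
  terms2 <- case$terms
  terms2$lj <- terms2$lj[-match(case$partition$qm[1], terms2$lj$index), ]
  expect_error(assemble_me_subtractive(case$system, terms2,
                                       case$partition),
               "MM \\(LJ\\) parameters")
})

test_that("tidy/glance expose components and variant metadata", {
  case <- make_junction_case("single_cut")
  r <- assemble_ee_subtractive(case$system, case$terms, case$partition,
                               scheme = "RCD")
  td <- tidy(r)
  expect_setequal(td$component,
                  c("e_qm1_ptch2_hl", "e_mm12_q1zero_cl", "e_mm1_q1zero_hl"))
  gl <- glance(r)
  expect_equal(gl$scheme, "RCD")
  expect_equal(gl$total, r$total)
  p <- ggplot2::ggplot_build(autoplot(r))
  expect_s3_class(p$plot, "ggplot")
})
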