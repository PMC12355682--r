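# Total QM/MM energy assembly in the four bookkeeping variants:
#   ME additive:     E = E_QM^1 + E_MM^2 + E_QM/MM^1-2
#   ME subtractive:  E = E_QM^1 + E_MM^12 - E_MM^1
#   EE subtractive:  E = E_QM1+ptch2^HL + E_MM12,q1=0^CL - E_MM1,q1=0^HL
#   EE additive:     E = E_QM1+ptch2^HL + E_MM^2 + cross LJ (+ DLB/DLAD)
# The big-QM assembly is the EE-subtractive expression with the enlarged
# region. The QM side is a pluggable backend; the shipped surrogate is a
# classical stand-in (MM internal energy + analytic point-charge Coulomb)
# that makes every identity exactly testable.

#' Classical surrogate QM backend
#'
#' Implements the QM-backend contract with force-field physics: the
#' "QM" energy of an HL-capped geometry is its MM internal energy (link
#' hydrogens carry hydrogen LJ parameters and zero charge) plus the
#' analytic Coulomb interaction of the region's force-field charges with
#' the external point-charge model. The self-energy of the external charges
#' is never included. ESP-charge requests return the force-field charges.
#' Deterministic: identical inputs give bit-identical energies.
#'
#' @param system A `qmmm_system`.
#' @param terms A [ff_terms()] table covering the region atoms.
#' @return A `qmmm_backend` with an `evaluate(geometry, external, ...)`
#'   function returning `list(energy, esp)` (kJ/mol; e).
#' @export
surrogate_backend <- function(system, terms) {
  ev <- function(geometry, external = NULL, total_charge = NULL,
                 multiplicity = NULL, want_esp = FALSE) {
    junctions <- attr(geometry, "junctions")
    if (is.null(junctions)) junctions <- list()
    variant <- mm_variant(
      link_substitution = if (length(junctions) > 0) "HL" else "CL",
      junctions = junctions
    )
    internal <- mm_energy(system, terms, subset = geometry$index,
                          variant = variant)
    ext <- 0
    if (!is.null(external) && nrow(external) > 0) {
      live <- geometry$charge != 0
      if (any(live)) {
        g <- geometry[live, , drop = FALSE]
        dx <- outer(g$x, external$x, `-`)
        dy <- outer(g$y, external$y, `-`)
        dz <- outer(g$z, external$z, `-`)
        qq <- outer(g$charge, external$charge)
        ext <- k_coulomb * sum(qq / sqrt(dx^2 + dy^2 + dz^2))
      }
    }
    list(energy = internal + ext,
         esp = if (want_esp) geometry$charge else NULL)
  }
  structure(list(name = "surrogate", evaluate = ev), class = "qmmm_backend")
}

.energy_report <- function(components, total, variant) {
  structure(list(components = components, total = total, variant = variant),
            class = "qmmm_energy")
}

#' @export
print.qmmm_energy <- function(x, ...) {
  cat(sprintf("<qmmm_energy> %s / %s%s: total %.6f kJ/mol\n",
              x$variant$embedding, x$variant$formulation,
              if (!is.null(x$variant$scheme))
                paste0(" (", x$variant$scheme, ")") else "",
              x$total))
  for (nm in names(x$components)) {
    cat(sprintf("  %-22s %16.6f\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

#' Recompute an energy report's total from its own components
#'
#' Definition audit: every assembly's total must equal the stated
#' combination of its labeled components.
#'
#' @param report A `qmmm_energy`.
#' @return The recomputed total, kJ/mol.
#' @export
audit_total <- function(report) {
  cp <- report$components
  switch(report$variant$formulation,
    me_additive = cp[["e_qm1"]] + cp[["e_mm2"]] + cp[["e_int12"]],
    me_subtractive = cp[["e_qm1"]] + cp[["e_mm12"]] - cp[["e_mm1"]],
    ee_additive = cp[["e_qm1_ptch2_hl"]] + cp[["e_mm2"]] + cp[["e_int12"]],
    ee_subtractive = ,
    bigqm = cp[["e_qm1_ptch2_hl"]] + cp[["e_mm12_q1zero_cl"]] -
      cp[["e_mm1_q1zero_hl"]]
  )
}

.default_backend <- function(backend, system, terms) {
  if (is.null(backend)) surrogate_backend(system, terms) else backend
}

#' Mechanical-embedding QM/MM energy, additive formulation
#'
#' Total = E_QM^1 (vacuum, HL-capped) + E_MM^2 + E_QM/MM^1-2, where the
#' interaction term is evaluated classically with either force-field
#' charges (MEA) or supplied ESP charges (MEE) on the QM side.
#'
#' @param system A `qmmm_system`.
#' @param terms A [ff_terms()] table.
#' @param partition A [region_partition()].
#' @param junctions Junction list; `NULL` detects them with `rule`.
#' @param charge_source `"force_field"` (MEA) or `"supplied_esp"` (MEE).
#' @param esp_charges Tibble (`index`, `charge`) for MEE.
#' @param backend A QM backend; `NULL` uses [surrogate_backend()].
#' @param rule A [link_rule()].
#' @return A `qmmm_energy` report.
#' @export
assemble_me_additive <- function(system, terms, partition, junctions = NULL,
                                 charge_source = "force_field",
                                 esp_charges = NULL, backend = NULL,
                                 rule = link_rule()) {
  backend <- .default_backend(backend, system, terms)
  if (is.null(junctions)) junctions <- find_junctions(system, partition, rule)
  geom <- qm_geometry(system, partition, junctions)
  e_qm1 <- backend$evaluate(geom)$energy
  e_mm2 <- mm_energy(system, terms, subset = partition$mm)
  e_int12 <- qmmm_interaction_mm(system, terms, partition,
                                 charge_source = charge_source,
                                 esp_charges = esp_charges)
  comps <- c(e_qm1 = e_qm1, e_mm2 = e_mm2, e_int12 = e_int12)
  .energy_report(comps, sum(comps),
                 list(embedding = "ME", formulation = "me_additive",
                      charge_source = charge_source,
                      backend = backend$name))
}

#' Mechanical-embedding QM/MM energy, subtractive formulation
#'
#' Total = E_QM^1 + E_MM^12 - E_MM^1. Requires MM parameters for the
#' QM-region atoms (the scheme's known cost). With a pairwise MM evaluator
#' and a consistent charge source this is algebraically identical to the
#' additive formulation.
#'
#' @inheritParams assemble_me_additive
#' @return A `qmmm_energy` report.
#' @export
assemble_me_subtractive <- function(system, terms, partition,
                                    junctions = NULL,
                                    charge_source = "force_field",
                                    esp_charges = NULL, backend = NULL,
                                    rule = link_rule()) {
  backend <- .default_backend(backend, system, terms)
  if (!all(partition$qm %in% terms$lj$index)) {
    rlang::abort("subtractive ME requires MM (LJ) parameters for every QM-region atom")
  }
  if (is.null(junctions)) junctions <- find_junctions(system, partition, rule)
  override <- NULL
  if (charge_source == "supplied_esp") {
    if (is.null(esp_charges)) {
      rlang::abort("supplied_esp requires esp_charges (index, charge)")
    }
    override <- esp_charges
  }
  geom <- qm_geometry(system, partition, junctions)
  e_qm1 <- backend$evaluate(geom)$energy
  v <- mm_variant(charge_override = override)
  e_mm12 <- mm_energy(system, terms, variant = v)
  e_mm1 <- mm_energy(system, terms, subset = partition$qm, variant = v)
  comps <- c(e_qm1 = e_qm1, e_mm12 = e_mm12, e_mm1 = e_mm1)
  .energy_report(comps, e_qm1 + e_mm12 - e_mm1,
                 list(embedding = "ME", formulation = "me_subtractive",
                      charge_source = charge_source,
                      backend = backend$name))
}

#' Electrostatic-embedding QM/MM energy, subtractive formulation
#'
#' The ComQum-style expression
#' E = E_QM1+ptch2^HL + E_MM12,q1=0^CL - E_MM1,q1=0^HL:
#' the HL-capped region embedded in the scheme's point-charge model, plus
#' the classical energy of everything with QM charges zeroed and real (CL)
#' atoms, minus the classical energy of the HL-capped region without
#' electrostatics. Using CL atoms in the "12" term but HL atoms in the "1"
#' term is what carries the van der Waals link-atom correction.
#'
#' @inheritParams assemble_me_additive
#' @param scheme One of [scheme_ids] (Z1 is the conventional subtractive
#'   default; CS the common additive-code default).
#' @param cs_shift CS pair half-distance, Angstrom.
#' @return A `qmmm_energy` report.
#' @export
assemble_ee_subtractive <- function(system, terms, partition,
                                    junctions = NULL, scheme = "Z1",
                                    backend = NULL, rule = link_rule(),
                                    cs_shift = 0.25) {
  backend <- .default_backend(backend, system, terms)
  if (is.null(junctions)) junctions <- find_junctions(system, partition, rule)
  model <- apply_scheme(system, partition, junctions, scheme, cs_shift)
  geom <- qm_geometry(system, partition, junctions)
  e_qm <- backend$evaluate(geom, external = model)$energy
  m1s <- vapply(junctions, function(j) j$m1, 0L)
  e_mm12 <- mm_energy(system, terms,
                      variant = mm_variant(zero_charges_on = partition$qm))
  e_mm1 <- mm_energy(system, terms, subset = c(partition$qm, m1s),
                     variant = mm_variant(
                       zero_charges_on = c(partition$qm, m1s),
                       link_substitution = "HL", junctions = junctions))
  comps <- c(e_qm1_ptch2_hl = e_qm, e_mm12_q1zero_cl = e_mm12,
             e_mm1_q1zero_hl = e_mm1)
  .energy_report(comps, e_qm + e_mm12 - e_mm1,
                 list(embedding = "EE", formulation = "ee_subtractive",
                      scheme = scheme, cs_shift = cs_shift,
                      backend = backend$name))
}

#' Electrostatic-embedding QM/MM energy, additive formulation
#'
#' Total = E_QM1+ptch2^HL + E_MM^2 + cross-region Lennard-Jones, with the
#' electrostatic cross terms living only inside the QM evaluation (no
#' double counting). `link_bond` (DLB) adds the Q1-M1 bond terms and
#' `link_angles_torsions` (DLAD) the Q2-Q1-M1 angles and Q3-Q2-Q1-M1
#' torsions to the MM part.
#'
#' @inheritParams assemble_ee_subtractive
#' @param link_bond,link_angles_torsions DLB / DLAD bonded-term flags.
#' @return A `qmmm_energy` report.
#' @export
assemble_ee_additive <- function(system, terms, partition, junctions = NULL,
                                 scheme = "CS", backend = NULL,
                                 rule = link_rule(), cs_shift = 0.25,
                                 link_bond = FALSE,
                                 link_angles_torsions = FALSE) {
  backend <- .default_backend(backend, system, terms)
  if (is.null(junctions)) junctions <- find_junctions(system, partition, rule)
  model <- apply_scheme(system, partition, junctions, scheme, cs_shift)
  geom <- qm_geometry(system, partition, junctions)
  e_qm <- backend$evaluate(geom, external = model)$energy
  e_mm2 <- mm_energy(system, terms, subset = partition$mm)
  e_int12 <- qmmm_interaction_mm(system, terms, partition,
                                 elec = FALSE, lj = TRUE,
                                 link_bond = link_bond,
                                 link_angles_torsions = link_angles_torsions)
  comps <- c(e_qm1_ptch2_hl = e_qm, e_mm2 = e_mm2, e_int12 = e_int12)
  .energy_report(comps, sum(comps),
                 list(embedding = "EE", formulation = "ee_additive",
                      scheme = scheme, cs_shift = cs_shift,
                      link_bond = link_bond,
                      link_angles_torsions = link_angles_torsions,
                      backend = backend$name))
}

#' Big-QM single-point energy
#'
#' The EE-subtractive expression evaluated with the enlarged big-QM region
#' as system 1: E = E_bigQM+ptch2^HL + E_MM12,q_bigQM=0^CL -
#' E_MM_bigQM,q_bigQM=0^HL. Shares the [assemble_ee_subtractive()] code
#' path, so with the base region it reduces to the ordinary EE energy and
#' with the whole system it reduces to the bare backend energy.
#'
#' @inheritParams assemble_ee_subtractive
#' @param bigqm_atoms Atom index set of the big-QM region (e.g. from
#'   [select_bigqm()]).
#' @return A `qmmm_energy` report (formulation `"bigqm"`).
#' @export
assemble_bigqm <- function(system, terms, bigqm_atoms, scheme = "Z1",
                           backend = NULL, rule = link_rule(),
                           cs_shift = 0.25) {
  partition <- region_partition(system, bigqm_atoms)
  rep <- assemble_ee_subtractive(system, terms, partition, scheme = scheme,
                                 backend = backend, rule = rule,
                                 cs_shift = cs_shift)
  rep$variant$formulation <- "bigqm"
  rep
}
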