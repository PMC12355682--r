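# Deterministic generator of synthetic peptide-like systems. Geometries are
# chemically plausible but invented (toy helical chain, ~1.5 A backbone
# spacing); the fixtures exist to exercise graph, charge and distance
# logic, not to model real conformers. Identical spec + seed gives
# bit-identical output, and every residue's partial charges sum exactly to
# its formal charge.

.res_templates <- function() {
  # fixed backbone frame; HA joins the rotated side-chain block so the
  # helical twist never sweeps it into the side chain
  bb <- list(
    names = c("N", "H", "CA", "C", "O"),
    elements = c("N", "H", "C", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(-0.45, 0.85, -0.25), c(1.30, 0.65, 0.25),
                c(2.65, 0.05, 0.15), c(2.90, -1.10, 0.50)),
    charges = c(-0.4, 0.3, 0.0, 0.5, -0.5),
    bonds = rbind(c("N", "H"), c("N", "CA"), c("CA", "C"), c("C", "O"))
  )
  ha <- list(name = "HA", element = "H", xyz = c(-0.20, -0.75, 0.70),
             charge = 0.1)
  side <- list(
    ALA = list(
      names = c("CB", "HB1", "HB2", "HB3"),
      elements = c("C", "H", "H", "H"),
      xyz = rbind(c(0, 1.4, 0.6), c(0.9, 1.9, 0.7), c(-0.8, 2.0, 1.0),
                  c(-0.5, 1.9, -0.3)),
      charges = c(-0.3, 0.1, 0.1, 0.1),
      bonds = rbind(c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
                    c("CB", "HB3")),
      formal = 0L
    ),
    ARG = list(
      names = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2", "HH21", "HH22"),
      elements = c("C", "C", "C", "N", "C", "N", "N", "H", "H"),
      xyz = rbind(c(0, 1.5, 0.3), c(0, 2.3, 1.5), c(0, 3.8, 1.3),
                  c(0, 4.5, 2.5), c(0, 5.8, 2.6), c(0, 6.5, 1.5),
                  c(0, 6.4, 3.8), c(0, 5.9, 4.6), c(0, 7.35, 3.9)),
      charges = c(-0.1, 0.0, 0.2, -0.5, 0.8, -0.6, -0.7, 0.45, 0.45),
      bonds = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "NE"), c("NE", "CZ"), c("CZ", "NH1"),
                    c("CZ", "NH2"), c("NH2", "HH21"), c("NH2", "HH22")),
      formal = 1L
    ),
    LYS = list(
      names = c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
      elements = c("C", "C", "C", "C", "N", "H", "H", "H"),
      xyz = rbind(c(0, 1.5, 0.3), c(0, 2.4, 1.4), c(0, 3.8, 1.2),
                  c(0, 4.7, 2.3), c(0, 6.0, 2.0), c(0.6, 6.5, 2.6),
                  c(-0.8, 6.6, 1.9), c(0.3, 6.0, 1.05)),
      charges = c(-0.1, 0.0, 0.1, 0.2, -0.3, 0.35, 0.35, 0.4),
      bonds = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "CE"), c("CE", "NZ"), c("NZ", "HZ1"),
                    c("NZ", "HZ2"), c("NZ", "HZ3")),
      formal = 1L
    ),
    ASP = list(
      names = c("CB", "CG", "OD1", "OD2"),
      elements = c("C", "C", "O", "O"),
      xyz = rbind(c(0, 1.5, 0.3), c(0, 2.3, 1.5), c(0, 3.55, 1.45),
                  c(0, 1.7, 2.6)),
      charges = c(-0.2, 0.6, -0.7, -0.7),
      bonds = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"),
                    c("CG", "OD2")),
      formal = -1L
    ),
    GLU = list(
      names = c("CB", "CG", "CD", "OE1", "OE2"),
      elements = c("C", "C", "C", "O", "O"),
      xyz = rbind(c(0, 1.5, 0.3), c(0, 2.3, 1.5), c(0, 3.8, 1.4),
                  c(0, 4.5, 0.4), c(0, 4.4, 2.6)),
      charges = c(-0.1, 0.0, 0.6, -0.75, -0.75),
      bonds = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "OE1"), c("CD", "OE2")),
      formal = -1L
    ),
    RING = list(
      names = c("CB", "CG", "CD", "CE", "CZ"),
      elements = c("C", "C", "C", "C", "C"),
      xyz = rbind(c(0, 1.5, 0.3), c(0.8, 2.6, 0.9), c(0.3, 3.9, 0.4),
                  c(-1.1, 3.7, 0.0), c(-1.3, 2.2, 0.1)),
      charges = c(-0.1, 0.0, 0.05, 0.05, 0.0),
      bonds = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "CE"), c("CE", "CZ"), c("CZ", "CB")),
      formal = 0L
    )
  )
  list(backbone = bb, ha = ha, side = side)
}

.water_template <- list(
  names = c("O", "H1", "H2"),
  elements = c("O", "H", "H"),
  xyz = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
  charges = c(-0.834, 0.417, 0.417)
)

.lj_by_element <- c(H = 0.0657, C = 0.3598, N = 0.7113, O = 0.8786,
                    S = 1.0460)
.sigma_by_element <- c(H = 2.65, C = 3.40, N = 3.25, O = 3.00, S = 3.56)

.rot_x <- function(a) {
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}

#' Fixture specification
#'
#' @param n_residues Number of chain slots.
#' @param palette Character vector (recycled to `n_residues`) of residue
#'   kinds: `"ALA"` (neutral), `"ARG"`, `"LYS"` (+1), `"ASP"`, `"GLU"`
#'   (-1), `"RING"` (neutral cyclic side chain) or `"HOH"` (free water,
#'   not bonded into the chain).
#' @param geometry `"helical"` (40 degree side-chain twist per residue,
#'   default) or `"linear"`.
#' @param charge_noise Half-width of the seeded uniform perturbation added
#'   to the template partial charges before per-residue renormalization, e.
#' @param seed Integer seed; identical spec + seed reproduces the fixture
#'   bit for bit.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues, palette = "ALA",
                         geometry = c("helical", "linear"),
                         charge_noise = 0.05, seed = 1L) {
  palette <- rep_len(palette, n_residues)
  known <- c(names(.res_templates()$side), "HOH")
  bad <- setdiff(palette, known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown palette entry '%s'", bad[1]))
  }
  structure(list(n_residues = n_residues, palette = palette,
                 geometry = match.arg(geometry),
                 charge_noise = charge_noise, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic peptide-like system with force-field terms
#'
#' Builds a connected polymer with named backbone atoms (N, H, CA, HA, C,
#' O) and palette side chains, peptide bonds between consecutive non-water
#' slots, and waters placed beside the chain. Partial charges are the
#' template values plus seeded noise, renormalized per residue so they sum
#' exactly to the residue's formal charge. Force-field terms are
#' generated from the geometry itself: every bond/angle term has its
#' equilibrium at the built value, torsions get a small threefold barrier,
#' and Lennard-Jones parameters come from a per-element table.
#'
#' @param spec A [fixture_spec()].
#' @param with_terms Derive force-field terms (default); skip for speed
#'   when only the structure is needed.
#' @return List: `system` (a `qmmm_system`) and `terms` (a [ff_terms()],
#'   or `NULL` when skipped).
#' @export
generate_fixture <- function(spec, with_terms = TRUE) {
  tpl <- .res_templates()
  withr::with_seed(spec$seed, {
    rows <- list(); bond_rows <- list(); res_rows <- list()
    idx <- 0L
    prev_c <- NA_integer_
    water_k <- 0
    for (r in seq_len(spec$n_residues)) {
      kind <- spec$palette[r]
      origin <- c(4.05 * (r - 1), 0, 0)
      twist <- if (spec$geometry == "helical") (r - 1) * 40 * pi / 180 else 0
      R <- .rot_x(twist)
      if (kind == "HOH") {
        water_k <- water_k + 1
        worigin <- origin + as.numeric(R %*% c(0.5, -4.0, 2.0 + water_k))
        xyz <- sweep(.water_template$xyz %*% t(R), 2, worigin, `+`)
        q <- .water_template$charges
        q <- q + stats::runif(length(q), -spec$charge_noise,
                              spec$charge_noise)
        q <- q - (sum(q) - 0) / length(q)
        rows[[r]] <- tibble::tibble(
          index = idx + seq_along(q) - 1L, name = .water_template$names,
          element = .water_template$elements, residue_id = r,
          residue_name = "HOH", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          charge = q)
        name_map <- stats::setNames(idx + seq_along(q) - 1L,
                                    .water_template$names)
        bond_rows[[r]] <- tibble::tibble(
          i = rep(name_map[["O"]], 2),
          j = c(name_map[["H1"]], name_map[["H2"]]))
        res_rows[[r]] <- tibble::tibble(residue_id = r,
                                        residue_name = "HOH",
                                        formal_charge = 0L)
        idx <- idx + length(q)
        next
      }
      bb <- tpl$backbone
      sd <- tpl$side[[kind]]
      names_r <- c(bb$names, tpl$ha$name, sd$names)
      elements_r <- c(bb$elements, tpl$ha$element, sd$elements)
      ca_local <- bb$xyz[match("CA", bb$names), ]
      rot_block <- rbind(tpl$ha$xyz, sd$xyz)
      xyz_local <- rbind(bb$xyz,
                         sweep(rot_block %*% t(R), 2, ca_local, `+`))
      xyz <- sweep(xyz_local, 2, origin, `+`)
      q <- c(bb$charges, tpl$ha$charge, sd$charges)
      q <- q + stats::runif(length(q), -spec$charge_noise, spec$charge_noise)
      q <- q - (sum(q) - sd$formal) / length(q)
      name_map <- stats::setNames(idx + seq_along(q) - 1L, names_r)
      rows[[r]] <- tibble::tibble(
        index = unname(name_map), name = names_r, element = elements_r,
        residue_id = r, residue_name = kind,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = q)
      bpairs <- rbind(bb$bonds, c("CA", "HA"), sd$bonds)
      br <- tibble::tibble(i = unname(name_map[bpairs[, 1]]),
                           j = unname(name_map[bpairs[, 2]]))
      if (!is.na(prev_c)) {
        br <- dplyr::bind_rows(br, tibble::tibble(
          i = prev_c, j = unname(name_map[["N"]])))
      }
      bond_rows[[r]] <- br
      prev_c <- unname(name_map[["C"]])
      res_rows[[r]] <- tibble::tibble(residue_id = r, residue_name = kind,
                                      formal_charge = sd$formal)
      idx <- idx + length(q)
    }
    atoms <- dplyr::bind_rows(rows)
    bonds <- dplyr::bind_rows(bond_rows)
    residues <- dplyr::bind_rows(res_rows)
    system <- build_system(atoms, bonds, residues)
    list(system = system,
         terms = if (with_terms) fixture_terms(system) else NULL)
  })
}

#' Derive force-field terms from a system's geometry
#'
#' Bonds and angles are harmonic about the as-built geometry, torsions get
#' a uniform threefold barrier, and Lennard-Jones parameters follow a
#' per-element table. Used by the fixture generator; exported so custom
#' systems can be dressed the same way.
#'
#' @param system A `qmmm_system`.
#' @param k_bond,k_angle,v_torsion Force constants (kJ/mol A^-2,
#'   kJ/mol rad^-2, kJ/mol).
#' @return A [ff_terms()] table.
#' @export
fixture_terms <- function(system, k_bond = 1000, k_angle = 300,
                          v_torsion = 2) {
  at <- system$atoms
  p_of <- function(idx) as.matrix(at[match(idx, at$index),
                                     c("x", "y", "z")])
  b <- system$bonds
  bond_terms <- NULL
  if (nrow(b) > 0) {
    r <- sqrt(rowSums((p_of(b$i) - p_of(b$j))^2))
    bond_terms <- tibble::tibble(i = b$i, j = b$j, k = k_bond, r0 = r)
  }
  ang <- list(); tor <- list()
  for (p in seq_len(nrow(at))) {
    jat <- at$index[p]
    nb <- neighbors(system, jat)
    if (length(nb) >= 2) {
      prs <- utils::combn(nb, 2)
      ang[[length(ang) + 1]] <- tibble::tibble(
        i = prs[1, ], j = jat, k = prs[2, ])
    }
  }
  angles <- if (length(ang)) dplyr::bind_rows(ang) else NULL
  if (!is.null(angles)) {
    v1 <- p_of(angles$i) - p_of(angles$j)
    v2 <- p_of(angles$k) - p_of(angles$j)
    ct <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    angles$kt <- k_angle
    angles$theta0 <- acos(pmin(1, pmax(-1, ct)))
  }
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      jat <- b$i[r]; kat <- b$j[r]
      for (iat in setdiff(neighbors(system, jat), kat)) {
        for (lat in setdiff(neighbors(system, kat), c(jat, iat))) {
          tor[[length(tor) + 1]] <- tibble::tibble(
            i = iat, j = jat, k = kat, l = lat)
        }
      }
    }
  }
  torsions <- if (length(tor)) dplyr::bind_rows(tor) else NULL
  if (!is.null(torsions)) {
    torsions$v <- v_torsion
    torsions$n <- 3
    torsions$gamma <- 0
  }
  lj <- tibble::tibble(
    index = at$index,
    eps = .element_lookup(.lj_by_element, at$element, default = 0.3),
    sigma = .element_lookup(.sigma_by_element, at$element, default = 3.2)
  )
  ff_terms(bonds = bond_terms, angles = angles, torsions = torsions, lj = lj)
}

.sidechain_indices <- function(system, residue, from = "CB") {
  at <- system$atoms
  at$index[at$residue_id == residue &
             !at$name %in% BACKBONE_NAMES]
}

#' Canonical junction test cases
#'
#' Deterministic (system, terms, partition) triples guaranteed to produce a
#' named junction topology: `single_cut` (one CA-CB cut),
#' `two_cuts_same_residue` (two peptide cuts whose M1 atoms share a
#' residue, stressing the DZ/ZZ2 per-residue union rules), `ring_adjacent`
#' (a cyclic side chain adjacent to the cut, stressing shell disjointness)
#' and `water_in_qm` (a free water inside the QM region, which must not
#' create a junction).
#'
#' @param kind Case name.
#' @param seed Fixture seed.
#' @return List: `system`, `terms`, `partition`.
#' @export
make_junction_case <- function(kind = c("single_cut",
                                        "two_cuts_same_residue",
                                        "ring_adjacent", "water_in_qm"),
                               seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "single_cut") {
    fx <- generate_fixture(fixture_spec(3, c("ALA", "ARG", "ALA"),
                                        seed = seed))
    mm <- .sidechain_indices(fx$system, 2L)
    part <- region_partition(fx$system,
                             setdiff(fx$system$atoms$index, mm))
  } else if (kind == "two_cuts_same_residue") {
    fx <- generate_fixture(fixture_spec(3, c("ALA", "LYS", "ALA"),
                                        seed = seed))
    at <- fx$system$atoms
    part <- region_partition(fx$system, at$index[at$residue_id != 2L])
  } else if (kind == "ring_adjacent") {
    fx <- generate_fixture(fixture_spec(3, c("ALA", "RING", "ALA"),
                                        seed = seed))
    mm <- .sidechain_indices(fx$system, 2L)
    part <- region_partition(fx$system,
                             setdiff(fx$system$atoms$index, mm))
  } else {
    fx <- generate_fixture(fixture_spec(3, c("ALA", "ALA", "HOH"),
                                        seed = seed))
    at <- fx$system$atoms
    part <- region_partition(fx$system,
                             at$index[at$residue_id %in% c(1L, 3L)])
  }
  list(system = fx$system, terms = fx$terms, partition = part)
}

#' Seeded random junction fixture
#'
#' Draws a 4-6 residue chain from the charged/neutral palette and cuts
#' either a CA-CB bond of a long side chain or a backbone peptide bond, so
#' that every charge-redistribution scheme (including Z3/DZ3) has nonempty
#' shells and at least one retained MM atom in the junction residue.
#'
#' @param seed Integer seed.
#' @param with_terms Also derive force-field terms (skippable for speed
#'   when only the charge model is exercised).
#' @return List: `system`, `terms` (or `NULL`), `partition`, `cut`
#'   (`"cacb"` or `"peptide"`).
#' @export
random_junction_fixture <- function(seed, with_terms = TRUE) {
  withr::with_seed(seed, {
    n <- sample(4:6, 1)
    palette <- sample(c("ALA", "ARG", "LYS", "ASP", "GLU"), n,
                      replace = TRUE)
    long <- which(palette %in% c("ARG", "LYS", "GLU"))
    if (length(long) == 0) {
      palette[2] <- "ARG"
      long <- 2L
    }
    cut <- sample(c("cacb", "peptide"), 1)
    inner_seed <- sample.int(1e6, 1)
  })
  fx <- generate_fixture(fixture_spec(n, palette, seed = inner_seed),
                         with_terms = with_terms)
  at <- fx$system$atoms
  if (cut == "cacb") {
    res <- long[1]
    mm <- .sidechain_indices(fx$system, res)
    part <- region_partition(fx$system, setdiff(at$index, mm))
  } else {
    # QM = residues 1..2, MM = the rest (junction residue 3 always keeps
    # atoms beyond its M3 shell)
    part <- region_partition(fx$system, at$index[at$residue_id <= 2L])
  }
  list(system = fx$system, terms = fx$terms, partition = part, cut = cut)
}
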