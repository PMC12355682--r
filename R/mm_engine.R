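# Minimal pairwise MM evaluator: harmonic bonds and angles, cosine
# torsions, Lennard-Jones (Lorentz-Berthelot) and Coulomb with AMBER-style
# 1-2/1-3 exclusions and 1-4 scaling. No cutoffs, no periodicity: every
# pair interacts, so energies are exactly pairwise-additive.

#' Force-field term table
#'
#' Explicit per-atom-tuple terms, the form the fixture generator emits and
#' [mm_energy()] consumes.
#'
#' @param bonds Tibble `i`, `j`, `k` (kJ mol^-1 A^-2), `r0` (A);
#'   E = k (r - r0)^2.
#' @param angles Tibble `i`, `j`, `k` (central atom `j`), `kt`
#'   (kJ mol^-1 rad^-2), `theta0` (rad); E = kt (theta - theta0)^2.
#' @param torsions Tibble `i`, `j`, `k`, `l`, `v` (kJ mol^-1), `n`
#'   (periodicity), `gamma` (rad); E = v (1 + cos(n phi - gamma)).
#' @param lj Tibble `index`, `eps` (kJ mol^-1), `sigma` (A); pairs combine
#'   by Lorentz-Berthelot rules.
#' @param scale14 List with `elec` and `lj` factors applied to 1-4 pairs;
#'   AMBER conventions (1/1.2 and 1/2) by default.
#' @param hl List `eps`, `sigma`: Lennard-Jones parameters given to a
#'   hydrogen link atom when it replaces M1.
#' @return A `ff_terms` list.
#' @export
ff_terms <- function(bonds = NULL, angles = NULL, torsions = NULL,
                     lj = NULL, scale14 = list(elec = 1 / 1.2, lj = 0.5),
                     hl = list(eps = 0.0657, sigma = 2.65)) {
  empty <- function(x, cols) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) {
      tibble::as_tibble(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    } else tibble::as_tibble(x)
  }
  terms <- list(
    bonds = empty(bonds, c("i", "j", "k", "r0")),
    angles = empty(angles, c("i", "j", "k", "kt", "theta0")),
    torsions = empty(torsions, c("i", "j", "k", "l", "v", "n", "gamma")),
    lj = empty(lj, c("index", "eps", "sigma")),
    scale14 = scale14, hl = hl
  )
  if (any(terms$lj$eps < 0) || any(terms$lj$sigma <= 0)) {
    rlang::abort("LJ parameters must satisfy eps >= 0, sigma > 0")
  }
  structure(terms, class = "ff_terms")
}

#' MM evaluation variant
#'
#' Controls the charge-zeroing and link-atom substitutions that the
#' subtractive energy expressions need: `E_MM12,q1=0^CL` zeroes the
#' QM-region charges but keeps the real (CL) atoms; `E_MM1,q1=0^HL`
#' replaces each M1 by a hydrogen at the HL position with hydrogen LJ
#' parameters and zero charge.
#'
#' @param zero_charges_on Atom indices whose charges are set to 0.
#' @param link_substitution `"CL"` (keep real atoms) or `"HL"` (replace M1
#'   atoms of `junctions` by link hydrogens).
#' @param junctions Junction list (needed for `"HL"`).
#' @param charge_override Optional tibble (`index`, `charge`) replacing
#'   stored charges (e.g. ESP charges for the QM region).
#' @return An `mm_variant` list.
#' @export
mm_variant <- function(zero_charges_on = integer(), link_substitution = "CL",
                       junctions = list(), charge_override = NULL) {
  link_substitution <- match.arg(link_substitution, c("CL", "HL"))
  structure(list(zero_charges_on = as.integer(zero_charges_on),
                 link_substitution = link_substitution,
                 junctions = junctions, charge_override = charge_override),
            class = "mm_variant")
}

# Topological neighbor shells (full graph) for exclusion classification.
.shell123 <- function(system) {
  idx <- system$atoms$index
  lapply(seq_along(idx), function(p) {
    a <- idx[p]
    n1 <- neighbors(system, a)
    n2 <- setdiff(unique(unlist(lapply(n1, neighbors, system = system))),
                  c(a, n1))
    n3 <- setdiff(unique(unlist(lapply(n2, neighbors, system = system))),
                  c(a, n1, n2))
    list(n1 = n1, n2 = n2, n3 = n3)
  })
}

# Scale matrices (elec, lj) for the pair (rows x cols) of atom indices.
.pair_scales <- function(system, rows_idx, cols_idx, scale14) {
  shells <- .shell123(system)
  pos <- match(rows_idx, system$atoms$index)
  se <- matrix(1, length(rows_idx), length(cols_idx))
  sl <- matrix(1, length(rows_idx), length(cols_idx))
  for (r in seq_along(rows_idx)) {
    sh <- shells[[pos[r]]]
    ex <- cols_idx %in% c(sh$n1, sh$n2)
    s14 <- cols_idx %in% sh$n3
    se[r, ex] <- 0; sl[r, ex] <- 0
    se[r, s14] <- scale14$elec; sl[r, s14] <- scale14$lj
  }
  list(elec = se, lj = sl)
}

# Apply an mm_variant to per-atom state vectors; returns a state list.
.atom_state <- function(system, terms, variant) {
  at <- system$atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  q <- at$charge
  ljrow <- match(at$index, terms$lj$index)
  eps <- terms$lj$eps[ljrow]
  sig <- terms$lj$sigma[ljrow]
  eps[is.na(eps)] <- 0
  sig[is.na(sig)] <- 1
  if (!is.null(variant$charge_override)) {
    ov <- variant$charge_override
    q[match(ov$index, at$index)] <- ov$charge
  }
  if (length(variant$zero_charges_on) > 0) {
    q[at$index %in% variant$zero_charges_on] <- 0
  }
  if (variant$link_substitution == "HL") {
    for (jn in variant$junctions) {
      p <- match(jn$m1, at$index)
      pos[p, ] <- jn$hl_position
      q[p] <- 0
      eps[p] <- terms$hl$eps
      sig[p] <- terms$hl$sigma
    }
  }
  list(pos = pos, q = q, eps = eps, sig = sig, index = at$index)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.bonded_energy <- function(state, terms, subset) {
  p_of <- function(idx) state$pos[match(idx, state$index), , drop = FALSE]
  e_bond <- e_angle <- e_tors <- 0
  b <- terms$bonds
  if (nrow(b) > 0) {
    keep <- b$i %in% subset & b$j %in% subset
    if (any(keep)) {
      b <- b[keep, , drop = FALSE]
      r <- sqrt(rowSums((p_of(b$i) - p_of(b$j))^2))
      missing <- !is.finite(b$k)
      if (any(missing)) {
        rlang::abort(sprintf("missing bond parameter for atoms (%d, %d)",
                             b$i[missing][1], b$j[missing][1]))
      }
      e_bond <- sum(b$k * (r - b$r0)^2)
    }
  }
  a <- terms$angles
  if (nrow(a) > 0) {
    keep <- a$i %in% subset & a$j %in% subset & a$k %in% subset
    if (any(keep)) {
      a <- a[keep, , drop = FALSE]
      v1 <- p_of(a$i) - p_of(a$j)
      v2 <- p_of(a$k) - p_of(a$j)
      ct <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      theta <- acos(pmin(1, pmax(-1, ct)))
      e_angle <- sum(a$kt * (theta - a$theta0)^2)
    }
  }
  t <- terms$torsions
  if (nrow(t) > 0) {
    keep <- t$i %in% subset & t$j %in% subset & t$k %in% subset &
      t$l %in% subset
    if (any(keep)) {
      t <- t[keep, , drop = FALSE]
      b1 <- p_of(t$j) - p_of(t$i)
      b2 <- p_of(t$k) - p_of(t$j)
      b3 <- p_of(t$l) - p_of(t$k)
      n1 <- .cross3(b1, b2)
      n2 <- .cross3(b2, b3)
      m1 <- .cross3(n1, b2 / sqrt(rowSums(b2^2)))
      phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
      e_tors <- sum(t$v * (1 + cos(t$n * phi - t$gamma)))
    }
  }
  c(bond = e_bond, angle = e_angle, torsion = e_tors)
}

.pair_energy <- function(state, terms, system, rows_idx, cols_idx,
                         same_set, elec = TRUE, lj = TRUE) {
  if (length(rows_idx) == 0 || length(cols_idx) == 0) {
    return(c(elec = 0, lj = 0))
  }
  pr <- match(rows_idx, state$index)
  pc <- match(cols_idx, state$index)
  dx <- outer(state$pos[pr, 1], state$pos[pc, 1], `-`)
  dy <- outer(state$pos[pr, 2], state$pos[pc, 2], `-`)
  dz <- outer(state$pos[pr, 3], state$pos[pc, 3], `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  mask <- if (same_set) upper.tri(d) else matrix(TRUE, nrow(d), ncol(d))
  sc <- .pair_scales(system, rows_idx, cols_idx, terms$scale14)
  e_el <- 0
  if (elec) {
    qq <- outer(state$q[pr], state$q[pc])
    e_el <- k_coulomb * sum((sc$elec * qq / d)[mask])
  }
  e_lj <- 0
  if (lj) {
    epsij <- sqrt(outer(state$eps[pr], state$eps[pc]))
    sigij <- outer(state$sig[pr], state$sig[pc], `+`) / 2
    sr6 <- (sigij / d)^6
    e_lj <- sum((sc$lj * 4 * epsij * (sr6^2 - sr6))[mask])
  }
  c(elec = e_el, lj = e_lj)
}

#' MM energy of an atom subset
#'
#' Sum of bonded (terms whose atoms all lie in the subset), Lennard-Jones
#' and Coulomb energies over the subset, with 1-2/1-3 exclusions and 1-4
#' scaling classified on the full covalent graph. No distance cutoff is
#' applied to any term. The variant controls charge zeroing, charge
#' overrides and HL/CL link substitution.
#'
#' @param system A `qmmm_system`.
#' @param terms A [ff_terms()] table.
#' @param subset Atom indices to evaluate; `NULL` means all. With an HL
#'   variant, M1 atoms in the subset are evaluated as link hydrogens.
#' @param variant An [mm_variant()].
#' @param components Return a named breakdown instead of the total.
#' @return Energy in kJ/mol (or a named vector when `components = TRUE`).
#' @export
mm_energy <- function(system, terms, subset = NULL, variant = mm_variant(),
                      components = FALSE) {
  if (is.null(subset)) subset <- system$atoms$index
  subset <- sort(unique(as.integer(subset)))
  state <- .atom_state(system, terms, variant)
  bonded <- .bonded_energy(state, terms, subset)
  pair <- .pair_energy(state, terms, system, subset, subset, same_set = TRUE)
  out <- c(bonded, pair)
  if (components) out else sum(out)
}

#' Cross-region MM interaction energy
#'
#' The additive-scheme interaction term between system 1 and system 2:
#' Coulomb (with force-field or supplied ESP charges on the QM side) and
#' Lennard-Jones across the partition, plus bonded terms that span it.
#' The `link_bond` / `link_angles_torsions` flags reproduce the DLB / DLAD
#' bookkeeping variants (whether the Q1-M1 bonds, and the Q2-Q1-M1 angles
#' plus Q3-Q2-Q1-M1 torsions, enter the MM term).
#'
#' @param system A `qmmm_system`.
#' @param terms A [ff_terms()] table.
#' @param partition A [region_partition()].
#' @param charge_source `"force_field"` (MEA-style) or `"supplied_esp"`
#'   (MEE-style; requires `esp_charges`).
#' @param esp_charges Tibble (`index`, `charge`) covering the QM atoms.
#' @param elec,lj Include the electrostatic / Lennard-Jones cross terms.
#' @param link_bond,link_angles_torsions Include cross-partition bond /
#'   angle+torsion terms.
#' @return Energy in kJ/mol.
#' @export
qmmm_interaction_mm <- function(system, terms, partition,
                                charge_source = c("force_field",
                                                  "supplied_esp"),
                                esp_charges = NULL,
                                elec = TRUE, lj = TRUE,
                                link_bond = TRUE,
                                link_angles_torsions = TRUE) {
  charge_source <- match.arg(charge_source)
  override <- NULL
  if (charge_source == "supplied_esp") {
    if (is.null(esp_charges)) {
      rlang::abort("supplied_esp requires esp_charges (index, charge)")
    }
    override <- esp_charges
  }
  state <- .atom_state(system, terms,
                       mm_variant(charge_override = override))
  pair <- .pair_energy(state, terms, system, partition$qm, partition$mm,
                       same_set = FALSE, elec = elec, lj = lj)

  spans <- function(tab, cols) {
    m <- sapply(cols, function(cl) tab[[cl]] %in% partition$qm)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    rowSums(m) > 0 & rowSums(m) < length(cols)
  }
  e_bonded <- 0
  if (link_bond && nrow(terms$bonds) > 0) {
    keep <- spans(terms$bonds, c("i", "j"))
    if (any(keep)) {
      sub <- unique(c(terms$bonds$i[keep], terms$bonds$j[keep]))
      tt <- terms
      tt$bonds <- terms$bonds[keep, , drop = FALSE]
      tt$angles <- tt$angles[0, ]; tt$torsions <- tt$torsions[0, ]
      e_bonded <- e_bonded + sum(.bonded_energy(state, tt, sub))
    }
  }
  if (link_angles_torsions) {
    if (nrow(terms$angles) > 0) {
      keep <- spans(terms$angles, c("i", "j", "k"))
      if (any(keep)) {
        sub <- unique(unlist(terms$angles[keep, c("i", "j", "k")]))
        tt <- terms
        tt$angles <- terms$angles[keep, , drop = FALSE]
        tt$bonds <- tt$bonds[0, ]; tt$torsions <- tt$torsions[0, ]
        e_bonded <- e_bonded + sum(.bonded_energy(state, tt, sub))
      }
    }
    if (nrow(terms$torsions) > 0) {
      keep <- spans(terms$torsions, c("i", "j", "k", "l"))
      if (any(keep)) {
        sub <- unique(unlist(terms$torsions[keep, c("i", "j", "k", "l")]))
        tt <- terms
        tt$torsions <- terms$torsions[keep, , drop = FALSE]
        tt$bonds <- tt$bonds[0, ]; tt$angles <- tt$angles[0, ]
        e_bonded <- e_bonded + sum(.bonded_energy(state, tt, sub))
      }
    }
  }
  sum(pair) + e_bonded
}
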