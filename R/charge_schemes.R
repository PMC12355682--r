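# The ten charge-redistribution schemes deciding which MM charges near a
# cut bond enter the QM point-charge model, and how deleted charge is
# compensated:
#   Z0       keep every MM atom (including M1, i.e. the CL atom)
#   Z1/Z2/Z3 delete shells M1 / M1+M2 / M1+M2+M3
#   DZ1-DZ3  as Zk, then spread the deleted charge of the junction residue
#            evenly over its remaining MM atoms
#   ZZ2      as Z2, then shift the junction residue's remaining charges by a
#            uniform increment so they sum to exactly zero
#   RCD      redistributed charge and dipole: move the M1 charge onto the
#            M2 atoms and M1-M2 bond midpoints so charge AND bond dipole
#            are both conserved
#   CS       charge shift: move the M1 charge onto the M2 atoms and restore
#            the dipole with a +/- pair straddling each M2 along M1-M2

#' The ten supported scheme identifiers
#' @export
scheme_ids <- c("Z0", "Z1", "Z2", "Z3", "DZ1", "DZ2", "DZ3", "ZZ2",
                "RCD", "CS")

.atom_row <- function(system, idx) match(idx, system$atoms$index)

#' Build the external point-charge model under a charge-redistribution scheme
#'
#' Returns the set of point charges that models the MM region in the QM
#' calculation: one site per retained MM atom plus any virtual sites
#' (RCD bond midpoints, CS shift pairs). Exclusions are unioned across
#' junctions before the DZ/ZZ2 compensations; an atom excluded by one
#' junction is never re-adjusted by another.
#'
#' @param system A `qmmm_system`.
#' @param partition A [region_partition()].
#' @param junctions Junction list from [find_junctions()].
#' @param scheme One of [scheme_ids].
#' @param cs_shift CS pair half-distance d from each M2 atom, Angstrom.
#'   Exposed because the charge-shift construction varies between codes;
#'   recorded in the model's attributes.
#' @return A `qmmm_point_charges` tibble: columns `x`, `y`, `z`, `charge`,
#'   `origin` (`"atom"`, `"midpoint"` or `"shift_pair"`), `source_atom`.
#' @export
apply_scheme <- function(system, partition, junctions, scheme,
                         cs_shift = 0.25) {
  scheme <- match.arg(scheme, scheme_ids)
  at <- system$atoms

  shells <- function(j) {
    switch(scheme,
      Z0 = integer(0),
      Z1 = , DZ1 = , RCD = , CS = j$m1,
      Z2 = , DZ2 = , ZZ2 = c(j$m1, j$m2),
      Z3 = , DZ3 = c(j$m1, j$m2, j$m3)
    )
  }
  excluded <- sort(unique(unlist(lapply(junctions, shells))))

  keep <- setdiff(partition$mm, excluded)
  rows <- .atom_row(system, keep)
  sites <- tibble::tibble(
    x = at$x[rows], y = at$y[rows], z = at$z[rows],
    charge = at$charge[rows], origin = rep("atom", length(rows)),
    source_atom = keep
  )

  res_of <- function(idx) at$residue_id[.atom_row(system, idx)]
  pos_of <- function(idx) unlist(at[.atom_row(system, idx), c("x", "y", "z")])
  q_of <- function(idx) at$charge[.atom_row(system, idx)]

  if (scheme %in% c("DZ1", "DZ2", "DZ3")) {
    for (j in junctions) {
      res <- res_of(j$m1)
      res_atoms <- at$index[at$residue_id == res]
      deleted <- intersect(shells(j), res_atoms)
      remaining <- intersect(setdiff(intersect(partition$mm, res_atoms),
                                     excluded), sites$source_atom)
      if (length(remaining) == 0) {
        rlang::abort(sprintf(
          "%s: junction residue %d retains no MM atoms to receive charge",
          scheme, res))
      }
      add <- sum(q_of(deleted)) / length(remaining)
      hit <- sites$source_atom %in% remaining
      sites$charge[hit] <- sites$charge[hit] + add
    }
  }

  if (scheme == "ZZ2") {
    for (res in unique(vapply(junctions, function(j) res_of(j$m1), 0L))) {
      res_atoms <- at$index[at$residue_id == res]
      remaining <- intersect(intersect(partition$mm, res_atoms),
                             sites$source_atom)
      if (length(remaining) == 0) {
        rlang::abort(sprintf(
          "ZZ2: junction residue %d retains no MM atoms to shift", res))
      }
      hit <- sites$source_atom %in% remaining
      sites$charge[hit] <- sites$charge[hit] - sum(sites$charge[hit]) /
        length(remaining)
    }
  }

  if (scheme %in% c("RCD", "CS")) {
    virt <- list()
    for (j in junctions) {
      n <- length(j$m2)
      if (n == 0) {
        rlang::abort(sprintf("%s: junction at M1=%d has no M2 atoms",
                             scheme, j$m1))
      }
      q0 <- q_of(j$m1)
      rm1 <- pos_of(j$m1)
      for (m2 in j$m2) {
        rm2 <- pos_of(m2)
        hit <- which(sites$source_atom == m2 & sites$origin == "atom")
        if (length(hit) != 1) {
          rlang::abort(sprintf(
            "%s: M2 atom %d was excluded by another junction", scheme, m2))
        }
        if (scheme == "RCD") {
          sites$charge[hit] <- sites$charge[hit] - q0 / n
          mid <- (rm1 + rm2) / 2
          virt[[length(virt) + 1]] <- tibble::tibble(
            x = mid[1], y = mid[2], z = mid[3], charge = 2 * q0 / n,
            origin = "midpoint", source_atom = j$m1)
        } else {
          len <- sqrt(sum((rm2 - rm1)^2))
          nb <- neighbors(system, m2)
          dmin <- min(vapply(nb, function(b)
            sqrt(sum((pos_of(b) - rm2)^2)), 0))
          if (cs_shift >= dmin) {
            rlang::abort("CS: shift pair overlaps neighbor (d >= shortest M2 bond length)")
          }
          sites$charge[hit] <- sites$charge[hit] + q0 / n
          u <- (rm2 - rm1) / len
          delta <- -q0 * len / (2 * n * cs_shift)
          pplus <- rm2 + cs_shift * u
          pminus <- rm2 - cs_shift * u
          virt[[length(virt) + 1]] <- tibble::tibble(
            x = c(pplus[1], pminus[1]), y = c(pplus[2], pminus[2]),
            z = c(pplus[3], pminus[3]), charge = c(delta, -delta),
            origin = "shift_pair", source_atom = m2)
        }
      }
    }
    sites <- dplyr::bind_rows(sites, virt)
  }

  structure(sites, scheme = scheme, cs_shift = cs_shift,
            class = c("qmmm_point_charges", class(tibble::tibble())))
}

#' Summarize a point-charge model
#'
#' @param model A `qmmm_point_charges` tibble.
#' @return One-row tibble: site count, total charge (e) and dipole about
#'   the origin (e Angstrom components and norm).
#' @export
model_summary <- function(model) {
  tibble::tibble(
    n_sites = nrow(model),
    total_charge = sum(model$charge),
    dipole_x = sum(model$charge * model$x),
    dipole_y = sum(model$charge * model$y),
    dipole_z = sum(model$charge * model$z),
    dipole_norm = sqrt(sum(c(sum(model$charge * model$x),
                             sum(model$charge * model$y),
                             sum(model$charge * model$z))^2))
  )
}

#' Electrostatic potential of a point-charge model
#'
#' @param model A `qmmm_point_charges` tibble (or any x/y/z/charge frame).
#' @param points Numeric matrix (n x 3) of probe positions, Angstrom.
#' @return Potential at each probe in kJ mol^-1 e^-1.
#' @export
electrostatic_potential <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(model) == 0) return(rep(0, nrow(points)))
  apply(points, 1, function(p) {
    r <- sqrt((model$x - p[1])^2 + (model$y - p[2])^2 + (model$z - p[3])^2)
    k_coulomb * sum(model$charge / r)
  })
}

#' Local dipole of the replaced boundary set
#'
#' For a junction, the dipole (about `origin`) of all model sites standing
#' in for the original M1 and M2 atoms: retained/adjusted M2 atom sites plus
#' midpoint and shift-pair virtual sites. Used to verify that RCD and CS
#' conserve the local dipole exactly.
#'
#' @param model A `qmmm_point_charges` tibble.
#' @param junction A `qmmm_junction`.
#' @param origin 3-vector origin, Angstrom.
#' @return Numeric 3-vector, e Angstrom.
#' @export
local_dipole <- function(model, junction, origin = c(0, 0, 0)) {
  keep <- (model$origin == "atom" &
             model$source_atom %in% c(junction$m1, junction$m2)) |
    (model$origin == "midpoint" & model$source_atom == junction$m1) |
    (model$origin == "shift_pair" & model$source_atom %in% junction$m2)
  m <- model[keep, , drop = FALSE]
  c(sum(m$charge * (m$x - origin[1])),
    sum(m$charge * (m$y - origin[2])),
    sum(m$charge * (m$z - origin[3])))
}
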