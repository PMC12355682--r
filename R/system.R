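# Molecular system container: atoms, covalent bond graph, residue partition.

#' Build a validated molecular system
#'
#' Assembles atoms, covalent bonds and a residue partition into a
#' `qmmm_system` object, the container every other function in the package
#' consumes. Internal atom indices are 0-based; original PDB serials, when
#' present, are kept in an `pdb_serial` column and written back 1-based.
#'
#' @param atoms A data frame with one row per atom and columns `index`
#'   (unique integer id, 0-based), `name` (PDB-convention atom name),
#'   `element`, `residue_id` (integer), `residue_name`, `x`, `y`, `z`
#'   (coordinates in Angstrom) and `charge` (partial charge in e).
#' @param bonds A data frame with integer columns `i`, `j` giving unordered
#'   covalent bonds between atom indices; may have zero rows.
#' @param residues Optional data frame with columns `residue_id`,
#'   `residue_name` and `formal_charge` (integer, e). When `NULL`, residues
#'   are derived from the atom table with formal charges from
#'   [formal_charge_from_name()].
#'
#' @return A `qmmm_system` object: a list with tibbles `atoms`, `bonds`,
#'   `residues`, plus a precomputed adjacency list.
#'
#' @examples
#' at <- tibble::tibble(
#'   index = 0:2, name = c("O", "H1", "H2"), element = c("O", "H", "H"),
#'   residue_id = 1L, residue_name = "HOH",
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0,
#'   charge = c(-0.834, 0.417, 0.417)
#' )
#' sys <- build_system(at, data.frame(i = c(0, 0), j = c(1, 2)))
#' neighbors(sys, 0)
#' @export
build_system <- function(atoms, bonds = NULL, residues = NULL) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("index", "name", "element", "residue_id", "residue_name",
              "x", "y", "z", "charge")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    rlang::abort(paste0("atoms is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  atoms$index <- as.integer(atoms$index)
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (anyDuplicated(atoms$index) > 0) {
    rlang::abort("duplicate atom index in atoms table")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("non-finite (NaN/Inf) coordinate in atoms table")
  }
  if (!all(is.finite(atoms$charge))) {
    rlang::abort("non-finite partial charge in atoms table")
  }

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)[, c("i", "j")]
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    if (any(bonds$i == bonds$j)) rlang::abort("self-bond in bond list")
    bad <- !(bonds$i %in% atoms$index) | !(bonds$j %in% atoms$index)
    if (any(bad)) {
      rlang::abort(sprintf("dangling bond: (%d, %d) references a missing atom",
                           bonds$i[which(bad)[1]], bonds$j[which(bad)[1]]))
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- dplyr::distinct(dplyr::arrange(bonds, .data$i, .data$j))
  }

  if (is.null(residues)) {
    residues <- atoms |>
      dplyr::distinct(.data$residue_id, .data$residue_name) |>
      dplyr::arrange(.data$residue_id)
    residues$formal_charge <- formal_charge_from_name(residues$residue_name)
  } else {
    residues <- tibble::as_tibble(residues)
    residues$residue_id <- as.integer(residues$residue_id)
    if (!"formal_charge" %in% names(residues)) residues$formal_charge <- 0L
  }
  if (anyDuplicated(residues$residue_id) > 0) {
    rlang::abort("overlapping residues: duplicate residue_id")
  }
  orphan <- setdiff(atoms$residue_id, residues$residue_id)
  if (length(orphan) > 0) {
    rlang::abort(sprintf("atom references unknown residue_id %d", orphan[1]))
  }
  residues <- residues[residues$residue_id %in% atoms$residue_id, , drop = FALSE]

  sys <- structure(
    list(atoms = atoms, bonds = bonds, residues = residues),
    class = "qmmm_system"
  )
  sys$adjacency <- .build_adjacency(sys)
  sys
}

.build_adjacency <- function(sys) {
  n <- nrow(sys$atoms)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(sys$bonds) > 0) {
    pi <- match(sys$bonds$i, sys$atoms$index)
    pj <- match(sys$bonds$j, sys$atoms$index)
    for (k in seq_along(pi)) {
      adj[[pi[k]]] <- c(adj[[pi[k]]], sys$atoms$index[pj[k]])
      adj[[pj[k]]] <- c(adj[[pj[k]]], sys$atoms$index[pi[k]])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' @export
print.qmmm_system <- function(x, ...) {
  cat(sprintf(
    "<qmmm_system> %d atoms, %d bonds, %d residues, net charge %+.4f e (formal %+d e)\n",
    nrow(x$atoms), nrow(x$bonds), nrow(x$residues),
    sum(x$atoms$charge), sum(x$residues$formal_charge)
  ))
  invisible(x)
}

#' Covalently bonded neighbors of an atom
#'
#' @param system A `qmmm_system`.
#' @param index Atom index (0-based).
#' @return Sorted integer vector of neighbor atom indices.
#' @export
neighbors <- function(system, index) {
  pos <- match(index, system$atoms$index)
  if (is.na(pos)) rlang::abort(sprintf("no atom with index %d", index))
  system$adjacency[[pos]]
}

#' Shortest bond-path distance between two atoms
#'
#' Breadth-first search over the covalent bond graph, capped at `max_depth`.
#'
#' @inheritParams neighbors
#' @param from,to Atom indices.
#' @param max_depth Search cap; `Inf` is returned past it.
#' @return Integer number of bonds, or `Inf` if unreachable within the cap.
#' @export
bond_path_distance <- function(system, from, to, max_depth = 10L) {
  if (from == to) return(0L)
  frontier <- from
  seen <- from
  d <- 0L
  while (length(frontier) > 0 && d < max_depth) {
    d <- d + 1L
    frontier <- setdiff(
      unique(unlist(lapply(frontier, function(a) neighbors(system, a)))),
      seen
    )
    if (to %in% frontier) return(d)
    seen <- c(seen, frontier)
  }
  Inf
}

#' Sum of partial charges over an atom subset
#'
#' @param system A `qmmm_system`.
#' @param subset Integer atom indices; `NULL` means all atoms.
#' @return Net partial charge in e.
#' @export
net_charge <- function(system, subset = NULL) {
  if (is.null(subset)) return(sum(system$atoms$charge))
  if (length(subset) == 0) return(0)
  pos <- match(subset, system$atoms$index)
  if (anyNA(pos)) rlang::abort("subset contains an index not in the system")
  sum(system$atoms$charge[pos])
}

#' Infer covalent bonds from interatomic distances
#'
#' A pair (i, j) is bonded iff the distance is at most the sum of the two
#' covalent radii plus `tolerance`. Hydrogen is restricted to a single heavy
#' partner: the closest, with the lexicographically smaller index winning
#' exact ties.
#'
#' @param system A `qmmm_system` (its bond table is ignored).
#' @param tolerance Slack added to the radius sum, Angstrom. Default 0.4 A,
#'   the common heuristic.
#' @return Tibble of bonds (`i`, `j`).
#' @export
infer_bonds_from_distance <- function(system, tolerance = 0.4) {
  at <- system$atoms
  n <- nrow(at)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer()))
  rad <- .element_lookup(.covalent_radius, at$element, default = 0.77)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(rad, rad, `+`) + tolerance
  hit <- d <= cutoff & upper.tri(d)
  idx <- which(hit, arr.ind = TRUE)
  bonds <- tibble::tibble(i = at$index[idx[, 1]], j = at$index[idx[, 2]])

  # one heavy partner per hydrogen: keep the closest (tie -> smaller index)
  is_h <- toupper(at$element) == "H"
  if (any(is_h) && nrow(bonds) > 0) {
    pi <- match(bonds$i, at$index); pj <- match(bonds$j, at$index)
    bonds$dist <- d[cbind(pi, pj)]
    for (h in at$index[is_h]) {
      rows <- which(bonds$i == h | bonds$j == h)
      if (length(rows) <= 1) next
      partner <- ifelse(bonds$i[rows] == h, bonds$j[rows], bonds$i[rows])
      ord <- order(bonds$dist[rows], partner)
      bonds <- bonds[-rows[ord[-1]], , drop = FALSE]
    }
    bonds$dist <- NULL
  }
  lone <- setdiff(at$index, unique(c(bonds$i, bonds$j)))
  if (length(lone) > 0) {
    rlang::warn(sprintf("%d atom(s) with no inferred bonds (ions/waters?)",
                        length(lone)))
  }
  bonds
}

#' Formal charge of standard residue names
#'
#' Small lookup used when no residue table is supplied: ASP/GLU -1,
#' LYS/ARG +1, doubly protonated histidine (HIP) +1, everything else 0.
#' Overridable by passing an explicit residue table to [build_system()].
#'
#' @param residue_name Character vector of 3-letter residue names.
#' @return Integer vector of formal charges in e.
#' @export
formal_charge_from_name <- function(residue_name) {
  up <- toupper(residue_name)
  out <- integer(length(up))
  out[up %in% c("ASP", "GLU")] <- -1L
  out[up %in% c("LYS", "ARG", "HIP")] <- 1L
  out
}

#' Define a QM/MM region partition
#'
#' Splits the atom set into system 1 (the QM region) and system 2 (the MM
#' region). The QM set must be nonempty; the MM set is the complement.
#'
#' @param system A `qmmm_system`.
#' @param qm_atoms Integer indices of the QM-region atoms.
#' @return A `qmmm_partition`: list with sorted integer vectors `qm` and `mm`.
#' @export
region_partition <- function(system, qm_atoms) {
  qm_atoms <- sort(unique(as.integer(qm_atoms)))
  if (length(qm_atoms) == 0) rlang::abort("QM region must be nonempty")
  if (!all(qm_atoms %in% system$atoms$index)) {
    rlang::abort("qm_atoms contains an index not in the system")
  }
  structure(
    list(qm = qm_atoms, mm = sort(setdiff(system$atoms$index, qm_atoms))),
    class = "qmmm_partition"
  )
}

#' @export
print.qmmm_partition <- function(x, ...) {
  cat(sprintf("<qmmm_partition> %d QM atoms / %d MM atoms\n",
              length(x$qm), length(x$mm)))
  invisible(x)
}
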