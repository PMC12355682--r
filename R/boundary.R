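# QM/MM boundary: junction detection, Q/M shell classification, hydrogen
# link-atom (HL) placement. Nomenclature: a junction is a covalent bond
# between Q1 (QM side) and M1 (MM side, the "carbon link" CL atom); Q2/Q3
# and M2/M3 are successive bond-graph shells outward from the cut.

#' Link-atom placement rule
#'
#' The HL hydrogen replaces M1 on the Q1-M1 axis. In `scaled` mode the
#' position is linearly related to Q1 and M1: r_HL = r_Q1 + g (r_M1 - r_Q1).
#' In `fixed_length` mode it sits at a fixed distance from Q1 along the same
#' direction. The default scale g is the ratio of standard bond lengths
#' d0(Q1-H)/d0(Q1-M1) (1.090/1.526 ~ 0.7143 for a C-C cut), a documented
#' choice since only the linear relation itself is prescribed.
#'
#' @param mode `"scaled"` or `"fixed_length"`.
#' @param scale Dimensionless g in (0, 1]; `NULL` means derive it per
#'   junction from the standard-bond-length table.
#' @param fixed_length HL distance from Q1 in Angstrom (fixed mode).
#' @return A `link_rule` list.
#' @export
link_rule <- function(mode = c("scaled", "fixed_length"), scale = NULL,
                      fixed_length = 1.09) {
  mode <- match.arg(mode)
  if (!is.null(scale) && (scale <= 0 || scale > 1)) {
    rlang::abort("link scale g must be in (0, 1]")
  }
  if (fixed_length <= 0) rlang::abort("fixed_length must be positive")
  structure(list(mode = mode, scale = scale, fixed_length = fixed_length),
            class = "link_rule")
}

.shell_out <- function(system, inner, exclude) {
  out <- unique(unlist(lapply(inner, function(a) neighbors(system, a))))
  sort(setdiff(out, exclude))
}

#' Find all junctions of a QM/MM partition
#'
#' One junction per bond crossing the partition, ordered by (q1, m1), with
#' shells classified from the bond graph: q2 = QM neighbors of Q1 except M1,
#' q3 = neighbors of q2 except Q1; m2 = neighbors of M1 except Q1, m3 =
#' neighbors of m2 except M1. Shells are made disjoint by priority
#' (M1 > M2 > M3, Q1 > Q2 > Q3) so ring closures never classify an atom
#' twice. Cutting a bond to hydrogen or through an M1 bonded to two QM
#' atoms is rejected.
#'
#' @param system A `qmmm_system`.
#' @param partition A [region_partition()].
#' @param rule A [link_rule()] for HL placement.
#' @return List of `qmmm_junction` objects (fields `q1`, `m1`, `q2`, `q3`,
#'   `m2`, `m3`, `hl_position`, `g`).
#' @export
find_junctions <- function(system, partition, rule = link_rule()) {
  b <- system$bonds
  in_qm_i <- b$i %in% partition$qm
  in_qm_j <- b$j %in% partition$qm
  cross <- xor(in_qm_i, in_qm_j)
  if (!any(cross)) return(list())
  q1 <- ifelse(in_qm_i[cross], b$i[cross], b$j[cross])
  m1 <- ifelse(in_qm_i[cross], b$j[cross], b$i[cross])
  ord <- order(q1, m1)
  q1 <- q1[ord]; m1 <- m1[ord]

  dup <- m1[duplicated(m1)]
  if (length(dup) > 0) {
    rlang::abort(sprintf(
      "unsupported double junction: MM atom %d is bonded to two QM atoms",
      dup[1]))
  }
  el <- function(i) toupper(system$atoms$element[match(i, system$atoms$index)])
  if (any(el(q1) == "H") || any(el(m1) == "H")) {
    rlang::abort("cut bond involves a hydrogen atom; cut a heavy-atom bond")
  }

  purrr::map2(q1, m1, function(a, m) {
    q2 <- sort(setdiff(intersect(neighbors(system, a), partition$qm), m))
    q3 <- .shell_out(system, q2, exclude = c(a, q2, m))
    m2 <- sort(setdiff(neighbors(system, m), a))
    m3 <- .shell_out(system, m2, exclude = c(m, m2, a))
    jn <- structure(
      list(q1 = a, m1 = m, q2 = q2, q3 = q3, m2 = m2, m3 = m3,
           hl_position = NULL, g = NA_real_),
      class = "qmmm_junction"
    )
    jn$hl_position <- place_link_atom(jn, system, rule)
    jn$g <- attr(jn$hl_position, "g")
    attr(jn$hl_position, "g") <- NULL
    jn
  })
}

#' @export
print.qmmm_junction <- function(x, ...) {
  cat(sprintf(
    "<junction> Q1=%d M1=%d | Q2={%s} Q3={%s} M2={%s} M3={%s} | HL (%.3f, %.3f, %.3f)\n",
    x$q1, x$m1, paste(x$q2, collapse = ","), paste(x$q3, collapse = ","),
    paste(x$m2, collapse = ","), paste(x$m3, collapse = ","),
    x$hl_position[1], x$hl_position[2], x$hl_position[3]))
  invisible(x)
}

#' Tabulate a junction list
#'
#' @param junctions List from [find_junctions()].
#' @return Tibble with one row per junction.
#' @export
junction_table <- function(junctions) {
  purrr::map_dfr(junctions, function(j) {
    tibble::tibble(
      q1 = j$q1, m1 = j$m1,
      q2 = paste(j$q2, collapse = ","), q3 = paste(j$q3, collapse = ","),
      m2 = paste(j$m2, collapse = ","), m3 = paste(j$m3, collapse = ","),
      hl_x = j$hl_position[1], hl_y = j$hl_position[2], hl_z = j$hl_position[3]
    )
  })
}

#' Place the hydrogen link atom of a junction
#'
#' @param junction A `qmmm_junction` (only `q1`, `m1` are used).
#' @param system A `qmmm_system`.
#' @param rule A [link_rule()].
#' @return Numeric 3-vector, Angstrom, with attribute `g` (the scale used).
#' @export
place_link_atom <- function(junction, system, rule = link_rule()) {
  at <- system$atoms
  rq <- unlist(at[match(junction$q1, at$index), c("x", "y", "z")])
  rm_ <- unlist(at[match(junction$m1, at$index), c("x", "y", "z")])
  v <- rm_ - rq
  len <- sqrt(sum(v^2))
  if (len < 0.1) rlang::abort("degenerate junction geometry: |Q1-M1| < 0.1 A")
  if (rule$mode == "scaled") {
    g <- rule$scale
    if (is.null(g)) {
      elq <- at$element[match(junction$q1, at$index)]
      elm <- at$element[match(junction$m1, at$index)]
      d_h <- .standard_bond_length(elq, "H")
      d_qm <- .standard_bond_length(elq, elm)
      g <- if (is.na(d_h) || is.na(d_qm)) 1.090 / 1.526 else d_h / d_qm
    }
    hl <- rq + g * v
  } else {
    g <- rule$fixed_length / len
    hl <- rq + rule$fixed_length * v / len
  }
  structure(unname(hl), g = g)
}

#' Build the HL-capped QM geometry
#'
#' The geometry seen by a QM backend: all QM atoms with their force-field
#' charges plus one hydrogen link atom (charge 0) per junction at its HL
#' position. Link rows keep the M1 index so MM terms can be looked up for
#' the surrogate backend.
#'
#' @param system A `qmmm_system`.
#' @param partition A [region_partition()].
#' @param junctions List from [find_junctions()].
#' @return A `qmmm_geometry` tibble (`index`, `name`, `element`, `x`, `y`,
#'   `z`, `charge`, `is_link`) with the junction list stored as an attribute.
#' @export
qm_geometry <- function(system, partition, junctions = list()) {
  at <- system$atoms
  qm <- at[match(partition$qm, at$index),
           c("index", "name", "element", "x", "y", "z", "charge")]
  qm$is_link <- FALSE
  links <- purrr::map_dfr(junctions, function(j) {
    tibble::tibble(index = j$m1, name = "HL", element = "H",
                   x = j$hl_position[1], y = j$hl_position[2],
                   z = j$hl_position[3], charge = 0, is_link = TRUE)
  })
  geom <- dplyr::bind_rows(tibble::as_tibble(qm), links)
  structure(geom, junctions = junctions, class = c("qmmm_geometry",
                                                   class(geom)))
}
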