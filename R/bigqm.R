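# Big-QM region construction: radius-based selection around a minimal QM
# region, whole-residue completion, backbone spans, buried-charge
# inclusion, junction relocation away from the base region, solvent
# exposure classification (Shrake-Rupley SASA) and neutralization of
# solvent-exposed charged residues.

#' Big-QM region specification
#'
#' @param radius Selection radius r from the base QM region, Angstrom.
#' @param base_qm Atom indices of the minimal QM region.
#' @param backbone_spans Residue ids whose backbone atoms (N, H, CA, HA, C,
#'   O) are always included (the "backbone of a few residues on both sides"
#'   rule).
#' @param include_buried_charges Include buried charged residues whole.
#' @param neutralize_exposed Whether downstream pipelines should neutralize
#'   solvent-exposed charged residues (recorded here; the edit itself is
#'   [neutralize_exposed_charges()]).
#' @param buried_threshold Relative SASA below which a residue counts as
#'   buried (default 0.05).
#' @param exposed_threshold Relative SASA at or above which a charged
#'   residue counts as solvent-exposed (default 0.20).
#' @param completion `"residue"` (any touched residue is included whole,
#'   waters likewise; default, required for the junction-relocation rule)
#'   or `"atom"` (raw distance selection, for comparison).
#' @return A `bigqm_spec` list.
#' @export
bigqm_spec <- function(radius, base_qm, backbone_spans = integer(),
                       include_buried_charges = FALSE,
                       neutralize_exposed = FALSE,
                       buried_threshold = 0.05, exposed_threshold = 0.20,
                       completion = c("residue", "atom")) {
  if (radius <= 0) rlang::abort("radius must be positive")
  if (length(base_qm) == 0) rlang::abort("base_qm must be nonempty")
  structure(list(radius = radius, base_qm = sort(unique(as.integer(base_qm))),
                 backbone_spans = as.integer(backbone_spans),
                 include_buried_charges = include_buried_charges,
                 neutralize_exposed = neutralize_exposed,
                 buried_threshold = buried_threshold,
                 exposed_threshold = exposed_threshold,
                 completion = match.arg(completion)),
            class = "bigqm_spec")
}

BACKBONE_NAMES <- c("N", "H", "CA", "HA", "C", "O")

#' Select a big-QM region
#'
#' Applies, in order: (i) every residue with at least one atom within
#' `radius` of any base-QM atom is included whole (whole water molecules
#' likewise); (ii) `backbone_spans` residues contribute their backbone
#' atoms; (iii) buried charged residues are included whole when requested;
#' (iv) junction relocation: any peptide-bond cut closer than two residues
#' in sequence to a residue of the base region is pushed outward by adding
#' the neighboring residue, until every cut is at least two residues away
#' (or the chain ends, with a warning). Cuts are accepted only at backbone
#' C-N or CA-CB bonds; any other crossing bond pulls in the offending
#' residue whole.
#'
#' @param system A `qmmm_system`.
#' @param spec A [bigqm_spec()].
#' @param exposure Optional precomputed [classify_exposure()] table
#'   (computed on demand when buried charges are requested).
#' @return A `bigqm_region` list: `atoms` (sorted index set), `residues`
#'   (fully included residue ids), `junctions` (junction report tibble).
#' @export
select_bigqm <- function(system, spec, exposure = NULL) {
  at <- system$atoms
  base_pos <- match(spec$base_qm, at$index)
  if (anyNA(base_pos)) rlang::abort("base_qm contains an unknown atom index")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- vapply(seq_len(nrow(at)), function(p) {
    min(colSums((t(xyz[base_pos, , drop = FALSE]) - xyz[p, ])^2))
  }, 0)
  hit <- at$index[d2 <= spec$radius^2]
  hit <- union(hit, spec$base_qm)

  if (spec$completion == "atom") {
    sel <- sort(hit)
    jn <- .crossing_bonds(system, sel)
    return(structure(list(atoms = sel,
                          residues = sort(unique(at$residue_id[match(sel, at$index)])),
                          junctions = jn),
                     class = "bigqm_region"))
  }

  res_whole <- unique(at$residue_id[match(hit, at$index)])
  sel <- at$index[at$residue_id %in% res_whole]

  spans <- setdiff(spec$backbone_spans, res_whole)
  if (length(spans) > 0) {
    bad <- setdiff(spans, system$residues$residue_id)
    if (length(bad) > 0) {
      rlang::abort(sprintf("backbone span references unknown residue %d",
                           bad[1]))
    }
    sel <- union(sel, at$index[at$residue_id %in% spans &
                                 at$name %in% BACKBONE_NAMES])
  }

  if (spec$include_buried_charges) {
    if (is.null(exposure)) exposure <- classify_exposure(system)
    buried <- exposure$residue_id[exposure$rel_sasa < spec$buried_threshold]
    charged <- system$residues$residue_id[system$residues$formal_charge != 0]
    add <- setdiff(intersect(buried, charged), res_whole)
    if (length(add) > 0) {
      res_whole <- union(res_whole, add)
      sel <- union(sel, at$index[at$residue_id %in% add])
    }
  }

  # (iv) relocation: push peptide-bond cuts >= 2 residues from the base
  base_res <- unique(at$residue_id[base_pos])
  all_res <- sort(system$residues$residue_id)
  repeat {
    cb <- .crossing_bonds(system, sel)
    if (nrow(cb) == 0) break
    moved <- FALSE
    for (r in seq_len(nrow(cb))) {
      ri <- at$residue_id[match(cb$inside[r], at$index)]
      ro <- at$residue_id[match(cb$outside[r], at$index)]
      ni <- at$name[match(cb$inside[r], at$index)]
      no <- at$name[match(cb$outside[r], at$index)]
      is_cn <- ri != ro && all(sort(c(ni, no)) == c("C", "N"))
      is_cacb <- ri == ro && all(sort(c(ni, no)) == c("CA", "CB"))
      if (is_cacb) next
      if (!is_cn) {
        # disallowed cut: complete the outside residue
        sel <- union(sel, at$index[at$residue_id == ro])
        res_whole <- union(res_whole, ro)
        moved <- TRUE
        break
      }
      gap <- min(vapply(base_res, function(b)
        min(abs(ri - b), abs(ro - b)), 0))
      if (gap < 2) {
        if (ro %in% c(min(all_res), max(all_res))) {
          rlang::warn("junction relocation reached a chain terminus")
        }
        sel <- union(sel, at$index[at$residue_id == ro])
        res_whole <- union(res_whole, ro)
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }

  sel <- sort(sel)
  structure(list(atoms = sel, residues = sort(res_whole),
                 junctions = .crossing_bonds(system, sel)),
            class = "bigqm_region")
}

.crossing_bonds <- function(system, sel) {
  b <- system$bonds
  ini <- b$i %in% sel
  inj <- b$j %in% sel
  cross <- xor(ini, inj)
  tibble::tibble(
    inside = ifelse(ini[cross], b$i[cross], b$j[cross]),
    outside = ifelse(ini[cross], b$j[cross], b$i[cross])
  )
}

#' @export
print.bigqm_region <- function(x, ...) {
  cat(sprintf("<bigqm_region> %d atoms, %d whole residues, %d junction bond(s)\n",
              length(x$atoms), length(x$residues), nrow(x$junctions)))
  invisible(x)
}

.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.sasa_per_atom <- function(xyz, radii, probe, n_points) {
  n <- nrow(xyz)
  pts <- .fibonacci_sphere(n_points)
  r_ext <- radii + probe
  out <- numeric(n)
  for (a in seq_len(n)) {
    sphere <- sweep(pts * r_ext[a], 2, xyz[a, ], `+`)
    nb <- which(rowSums(sweep(xyz, 2, xyz[a, ])^2) <
                  (r_ext[a] + r_ext)^2 & seq_len(n) != a)
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      d2 <- (sphere[, 1] - xyz[b, 1])^2 + (sphere[, 2] - xyz[b, 2])^2 +
        (sphere[, 3] - xyz[b, 3])^2
      acc <- acc & d2 > r_ext[b]^2
      if (!any(acc)) break
    }
    out[a] <- 4 * pi * r_ext[a]^2 * mean(acc)
  }
  out
}

#' Per-residue relative solvent accessibility
#'
#' Shrake-Rupley SASA with a deterministic Fibonacci-spiral sphere
#' sampling. The relative value divides each residue's SASA in the full
#' system by the SASA of the same residue computed in isolation (same
#' coordinates), so an unoccluded residue scores ~1 regardless of its
#' composition.
#'
#' @param system A `qmmm_system`.
#' @param probe_radius Solvent probe radius, Angstrom (water: 1.4).
#' @param n_sphere_points Sample points per atom (default 960).
#' @return Tibble: `residue_id`, `residue_name`, `formal_charge`, `sasa`,
#'   `sasa_ref` (A^2) and `rel_sasa`.
#' @export
classify_exposure <- function(system, probe_radius = 1.4,
                              n_sphere_points = 960) {
  at <- system$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- .element_lookup(.vdw_radius, at$element, default = 1.7)
  sasa <- .sasa_per_atom(xyz, radii, probe_radius, n_sphere_points)
  per_res <- tapply(sasa, at$residue_id, sum)
  ref <- vapply(names(per_res), function(rid) {
    rows <- which(at$residue_id == as.integer(rid))
    sum(.sasa_per_atom(xyz[rows, , drop = FALSE], radii[rows],
                       probe_radius, n_sphere_points))
  }, 0)
  out <- tibble::tibble(
    residue_id = as.integer(names(per_res)),
    sasa = as.numeric(per_res),
    sasa_ref = as.numeric(ref),
    rel_sasa = as.numeric(per_res) / pmax(as.numeric(ref), 1e-12)
  )
  dplyr::left_join(out, system$residues, by = "residue_id")[,
    c("residue_id", "residue_name", "formal_charge", "sasa", "sasa_ref",
      "rel_sasa")]
}

#' Neutralize solvent-exposed charged residues
#'
#' Applies the standard structural edits: arginine loses HH22, lysine
#' loses HZ3, aspartate gains a proton on OD1 and glutamate on OE2 (the
#' atoms that disturb the hydrogen-bond network the least). The added
#' proton is placed 0.97 A from the oxygen along the in-plane bisector
#' pointing away from the carboxylate carbon and the sibling oxygen.
#' Residues engaged in an ion pair (opposite formal charges with a
#' heavy-atom contact below `pairing_cutoff`) are left untouched when
#' `pairing_rule` is on. After each edit the residue's formal charge is 0
#' and its partial charges are renormalized to sum to exactly 0.
#'
#' @param system A `qmmm_system`.
#' @param residues Residue ids to neutralize (ARG/LYS/ASP/GLU only).
#' @param pairing_rule Exempt ion-paired residues.
#' @param pairing_cutoff Heavy-atom contact distance defining an ion pair,
#'   Angstrom (default 4.0).
#' @return List: `system` (edited) and `edits` (tibble with `residue_id`,
#'   `residue_name`, `action`, `atom_name`, `formal_charge_delta`).
#' @export
neutralize_exposed_charges <- function(system, residues,
                                       pairing_rule = TRUE,
                                       pairing_cutoff = 4.0) {
  residues <- unique(as.integer(residues))
  res_tab <- system$residues
  edits <- list()

  paired <- integer(0)
  if (pairing_rule) {
    charged <- res_tab[res_tab$formal_charge != 0, ]
    at <- system$atoms
    # side-chain heavy atoms only: a backbone peptide bond between
    # sequence neighbors is not an ionic contact
    eligible <- toupper(at$element) != "H" & !at$name %in% BACKBONE_NAMES
    for (r in residues) {
      fc <- res_tab$formal_charge[res_tab$residue_id == r]
      if (length(fc) == 0 || fc == 0) next
      partners <- charged$residue_id[sign(charged$formal_charge) == -sign(fc)]
      for (p in partners) {
        a1 <- as.matrix(at[at$residue_id == r & eligible, c("x", "y", "z")])
        a2 <- as.matrix(at[at$residue_id == p & eligible, c("x", "y", "z")])
        if (nrow(a1) == 0 || nrow(a2) == 0) next
        dmin <- sqrt(max(0, min(outer(rowSums(a1^2), rowSums(a2^2), `+`) -
                                  2 * a1 %*% t(a2))))
        if (dmin < pairing_cutoff) { paired <- c(paired, r); break }
      }
    }
  }

  atoms <- system$atoms
  bonds <- system$bonds
  for (r in setdiff(residues, paired)) {
    row <- which(res_tab$residue_id == r)
    if (length(row) == 0) rlang::abort(sprintf("unknown residue %d", r))
    rname <- toupper(res_tab$residue_name[row])
    if (!rname %in% c("ARG", "LYS", "ASP", "GLU")) {
      rlang::abort(sprintf(
        "residue %d (%s) is not a neutralizable type (ARG/LYS/ASP/GLU)",
        r, rname))
    }
    if (res_tab$formal_charge[row] == 0) {
      rlang::warn(sprintf("residue %d is already neutral; skipping", r))
      next
    }
    in_res <- atoms$residue_id == r
    if (rname %in% c("ARG", "LYS")) {
      target <- if (rname == "ARG") "HH22" else "HZ3"
      hit <- which(in_res & atoms$name == target)
      if (length(hit) == 0) {
        rlang::abort(sprintf("residue %d has no atom named %s", r, target))
      }
      gone <- atoms$index[hit[1]]
      atoms <- atoms[-hit[1], , drop = FALSE]
      bonds <- bonds[bonds$i != gone & bonds$j != gone, , drop = FALSE]
      in_res <- atoms$residue_id == r
      resid_sum <- sum(atoms$charge[in_res])
      atoms$charge[in_res] <- atoms$charge[in_res] -
        resid_sum / sum(in_res)
      delta <- -res_tab$formal_charge[row]
      edits[[length(edits) + 1]] <- tibble::tibble(
        residue_id = r, residue_name = rname, action = "delete_atom",
        atom_name = target, formal_charge_delta = delta)
    } else {
      o_name <- if (rname == "ASP") "OD1" else "OE2"
      c_name <- if (rname == "ASP") "CG" else "CD"
      o2_name <- if (rname == "ASP") "OD2" else "OE1"
      h_name <- if (rname == "ASP") "HD1" else "HE2"
      po <- which(in_res & atoms$name == o_name)
      pc <- which(in_res & atoms$name == c_name)
      po2 <- which(in_res & atoms$name == o2_name)
      if (length(po) == 0 || length(pc) == 0 || length(po2) == 0) {
        rlang::abort(sprintf("residue %d lacks carboxylate atoms %s/%s/%s",
                             r, o_name, c_name, o2_name))
      }
      ro <- unlist(atoms[po[1], c("x", "y", "z")])
      rc <- unlist(atoms[pc[1], c("x", "y", "z")])
      ro2 <- unlist(atoms[po2[1], c("x", "y", "z")])
      d1 <- (ro - rc) / sqrt(sum((ro - rc)^2))
      d2 <- (ro - ro2) / sqrt(sum((ro - ro2)^2))
      w <- d1 + d2
      w <- w / sqrt(sum(w^2))
      hpos <- ro + 0.97 * w
      new_index <- max(atoms$index) + 1L
      q_h <- -sum(atoms$charge[in_res])
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        index = new_index, name = h_name, element = "H", residue_id = r,
        residue_name = atoms$residue_name[po[1]],
        x = hpos[1], y = hpos[2], z = hpos[3], charge = q_h))
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        i = atoms$index[po[1]], j = new_index))
      delta <- -res_tab$formal_charge[row]
      edits[[length(edits) + 1]] <- tibble::tibble(
        residue_id = r, residue_name = rname, action = "add_proton",
        atom_name = o_name, formal_charge_delta = delta)
    }
    res_tab$formal_charge[row] <- 0L
  }

  out <- build_system(atoms, bonds, res_tab)
  list(system = out,
       edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(residue_id = integer(), residue_name = character(),
                        action = character(), atom_name = character(),
                        formal_charge_delta = integer()))
}

#' Counts for an atom region
#'
#' @param system A `qmmm_system`.
#' @param region Atom index set.
#' @return One-row tibble: `n_atoms`, `n_residues` (residues with at least
#'   one atom in the region), `n_waters` (water residues touched),
#'   `n_junctions` (bonds crossing the region boundary) and
#'   `net_formal_charge` (sum over residues fully contained).
#' @export
region_report <- function(system, region) {
  region <- unique(as.integer(region))
  at <- system$atoms
  inr <- at$index %in% region
  res_touch <- unique(at$residue_id[inr])
  waters <- system$residues$residue_id[
    toupper(system$residues$residue_name) %in% c("HOH", "WAT")]
  full <- vapply(res_touch, function(r)
    all(at$index[at$residue_id == r] %in% region), TRUE)
  tibble::tibble(
    n_atoms = sum(inr),
    n_residues = length(res_touch),
    n_waters = length(intersect(res_touch, waters)),
    n_junctions = nrow(.crossing_bonds(system, region)),
    net_formal_charge = sum(system$residues$formal_charge[
      system$residues$residue_id %in% res_touch[full]])
  )
}
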