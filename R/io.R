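# Readers/writers: PDB (via bio3d), AMBER prmtop subset, JSON topology
# dialect, point-charge files.

# AMBER stores charges premultiplied by 18.2223 (sqrt of the Coulomb constant
# in kcal/mol units); dividing restores elementary charges.
PRMTOP_CHARGE_SCALE <- 18.2223

#' Read a PDB structure into a molecular system
#'
#' Parses ATOM/HETATM records through bio3d, applies the altLoc rule (keep
#' the highest-occupancy alternate; exact tie kept for altLoc 'A'), converts
#' CONECT records into bonds, and validates serials. PDB carries no partial
#' charges; they are set to 0 and should be supplied by a topology.
#'
#' @param path PDB file path.
#' @return A [build_system()] object. Original PDB serials are kept in the
#'   `pdb_serial` column, chain identifiers in `chain`; `residue_id` is a
#'   dense integer over (chain, resno) so chains never collide.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) rlang::abort("no ATOM/HETATM records found")
  for (ln in rec) {
    l <- lines[[ln]]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54)))))) {
      rlang::abort(sprintf("malformed ATOM/HETATM record at line %d", ln))
    }
  }
  serials <- as.integer(substr(lines[rec], 7, 11))
  alts <- substr(lines[rec], 17, 17)
  if (anyDuplicated(paste(serials, alts)) > 0) {
    rlang::abort("duplicate atom serial in PDB file")
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- tibble::as_tibble(pdb$atom)
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- "A"

  # altLoc: highest occupancy wins, exact tie -> 'A'
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o),
                   .data$alt != "A", .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$eleno)

  element <- at$elesy
  noel <- is.na(element) | trimws(element) == ""
  element[noel] <- substr(gsub("[^A-Za-z].*", "", at$elety[noel]), 1, 1)
  element <- trimws(element)

  res_key <- paste(at$chain, at$resno, sep = ":")
  residue_id <- match(res_key, unique(res_key))

  atoms <- tibble::tibble(
    index = seq_len(nrow(at)) - 1L,
    name = at$elety,
    element = element,
    residue_id = as.integer(residue_id),
    residue_name = at$resid,
    x = at$x, y = at$y, z = at$z,
    charge = 0,
    pdb_serial = as.integer(at$eleno),
    chain = at$chain
  )

  bonds <- tibble::tibble(i = integer(), j = integer())
  con <- grep("^CONECT", lines, value = TRUE)
  if (length(con) > 0) {
    prs <- purrr::map(con, function(l) {
      f <- as.integer(strsplit(trimws(sub("^CONECT", "", l)), "\\s+")[[1]])
      if (length(f) < 2) return(NULL)
      tibble::tibble(si = f[1], sj = f[-1])
    })
    prs <- dplyr::bind_rows(prs)
    pi <- match(prs$si, atoms$pdb_serial)
    pj <- match(prs$sj, atoms$pdb_serial)
    keep <- !is.na(pi) & !is.na(pj)
    bonds <- tibble::tibble(i = atoms$index[pi[keep]],
                            j = atoms$index[pj[keep]])
  }
  build_system(atoms, bonds)
}

#' Write a molecular system as PDB
#'
#' ATOM records (serials 1-based) via bio3d, followed by CONECT records for
#' every bond and END.
#'
#' @param system A `qmmm_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  at <- system$atoms
  chain <- if ("chain" %in% names(at)) at$chain else rep("A", nrow(at))
  serial <- if ("pdb_serial" %in% names(at)) at$pdb_serial else at$index + 1L
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$residue_id,
    resid = at$residue_name,
    eleno = serial,
    elety = at$name,
    chain = chain,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)),
    elesy = at$element,
    end = FALSE
  )
  con <- character(0)
  if (nrow(system$bonds) > 0) {
    smap <- stats::setNames(serial, at$index)
    con <- sprintf("CONECT%5d%5d",
                   smap[as.character(system$bonds$i)],
                   smap[as.character(system$bonds$j)])
  }
  cat(c(con, "END"), sep = "\n", file = path, append = TRUE)
  invisible(path)
}

.prmtop_section <- function(lines, flag, required = TRUE) {
  pos <- grep(sprintf("^%%FLAG %s\\s*$", flag), lines)
  if (length(pos) == 0) {
    if (required) rlang::abort(sprintf("prmtop is missing %%FLAG %s", flag))
    return(NULL)
  }
  nxt <- grep("^%FLAG ", lines)
  end <- c(nxt[nxt > pos[1]], length(lines) + 1L)[1] - 1L
  body <- lines[(pos[1] + 1L):end]
  fmt <- grep("^%FORMAT", body, value = TRUE)
  body <- body[!grepl("^%", body)]
  list(body = body, format = if (length(fmt)) fmt[1] else "")
}

#' Read the subset of an AMBER prmtop needed for charges, bonds and residues
#'
#' Parses the CHARGE, BONDS_INC_HYDROGEN, BONDS_WITHOUT_HYDROGEN,
#' RESIDUE_POINTER and ATOM_NAME sections. Charges are converted to
#' elementary charges by dividing by 18.2223; bond entries use the prmtop
#' convention of 3*(atom index) and are decoded to 0-based atom pairs.
#' All other sections are ignored.
#'
#' @param path prmtop file path.
#' @return List with `charges` (numeric, e), `bonds` (tibble `i`, `j`,
#'   0-based), `atom_names` (character), `residue_pointer` (1-based start
#'   indices), `residue_labels` (character, if present) and `residue_id`
#'   (per-atom integer).
#' @export
read_prmtop_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)

  num <- function(sec) {
    v <- unlist(strsplit(trimws(paste(sec$body, collapse = " ")), "\\s+"))
    as.numeric(v[nzchar(v)])
  }

  charges <- num(.prmtop_section(lines, "CHARGE")) / PRMTOP_CHARGE_SCALE

  decode_bonds <- function(sec) {
    v <- num(sec)
    if (length(v) == 0) return(tibble::tibble(i = integer(), j = integer()))
    stopifnot(length(v) %% 3 == 0)
    m <- matrix(as.integer(v), ncol = 3, byrow = TRUE)
    tibble::tibble(i = m[, 1] %/% 3L, j = m[, 2] %/% 3L)
  }
  bh <- decode_bonds(.prmtop_section(lines, "BONDS_INC_HYDROGEN"))
  bnh <- decode_bonds(.prmtop_section(lines, "BONDS_WITHOUT_HYDROGEN"))
  bonds <- dplyr::distinct(dplyr::bind_rows(bh, bnh))
  if (nrow(bonds) == 0) rlang::warn("prmtop bond sections are empty")

  names_sec <- .prmtop_section(lines, "ATOM_NAME")
  width <- 4L
  raw <- paste(names_sec$body, collapse = "")
  atom_names <- trimws(substring(raw,
                                 seq(1, nchar(raw), by = width),
                                 seq(width, nchar(raw) + width - 1, by = width)))
  atom_names <- atom_names[seq_along(charges)]

  rp <- as.integer(num(.prmtop_section(lines, "RESIDUE_POINTER")))
  residue_id <- findInterval(seq_along(charges), rp)

  lab_sec <- .prmtop_section(lines, "RESIDUE_LABEL", required = FALSE)
  residue_labels <- if (is.null(lab_sec)) NULL else {
    raw <- paste(lab_sec$body, collapse = "")
    trimws(substring(raw, seq(1, nchar(raw), by = width),
                     seq(width, nchar(raw) + width - 1, by = width)))[seq_along(rp)]
  }

  list(charges = charges, bonds = bonds, atom_names = atom_names,
       residue_pointer = rp, residue_labels = residue_labels,
       residue_id = residue_id)
}

#' Write / read the JSON topology dialect
#'
#' The canonical fixture format of the package: a single JSON object with
#' `atoms` (index, name, element, residue_id, residue_name, position,
#' charge), `bonds` (pairs), `residues` (id, name, formal_charge) and
#' optionally `terms` (force-field terms as produced by the fixture
#' generator). Charges survive a round trip to 1e-10 e and bond sets exactly.
#'
#' @param system A `qmmm_system`.
#' @param path File path.
#' @param terms Optional force-field term list (see [mm_energy()]).
#' @return `write_topology_json()`: `path` invisibly.
#'   `read_topology_json()`: list with `system` and `terms` (or `NULL`).
#' @export
write_topology_json <- function(system, path, terms = NULL) {
  obj <- list(
    format = "qmmmtools-topology-v1",
    atoms = system$atoms,
    bonds = if (nrow(system$bonds)) unname(as.matrix(system$bonds)) else list(),
    residues = system$residues
  )
  if (!is.null(terms)) {
    obj$terms <- list(
      bonds = terms$bonds, angles = terms$angles, torsions = terms$torsions,
      lj = terms$lj, scale14 = terms$scale14, hl = terms$hl
    )
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bonds <- obj$bonds
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer())
  } else {
    bonds <- tibble::tibble(i = as.integer(bonds[, 1]),
                            j = as.integer(bonds[, 2]))
  }
  system <- build_system(tibble::as_tibble(obj$atoms), bonds,
                         tibble::as_tibble(obj$residues))
  terms <- NULL
  if (!is.null(obj$terms)) {
    terms <- ff_terms(
      bonds = tibble::as_tibble(obj$terms$bonds),
      angles = tibble::as_tibble(obj$terms$angles),
      torsions = tibble::as_tibble(obj$terms$torsions),
      lj = tibble::as_tibble(obj$terms$lj),
      scale14 = obj$terms$scale14,
      hl = obj$terms$hl
    )
  }
  list(system = system, terms = terms)
}

#' Write a point-charge model to a text file
#'
#' One whitespace-delimited `x y z q` line per site (Angstrom, e, 10 decimal
#' places), virtual sites included.
#'
#' @param model A point-charge model from [apply_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_point_charges <- function(model, path) {
  if (nrow(model) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  writeLines(sprintf("%.10f %.10f %.10f %.10f",
                     model$x, model$y, model$z, model$charge), path)
  invisible(path)
}

#' @rdname write_point_charges
#' @param strict Error on malformed lines.
#' @export
read_point_charges <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          charge = numeric()))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (strict && (ncol(m) != 4 || anyNA(m))) {
    rlang::abort("malformed point-charge file")
  }
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], charge = m[, 4])
}
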