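# small shared builders

two_charges <- function(q1 = 1, q2 = -1, d = 1) {
  sys <- build_system(tibble::tibble(
    index = 0:1, name = c("A", "B"), element = "C",
    residue_id = 1L, residue_name = "UNK",
    x = c(0, d), y = 0, z = 0, charge = c(q1, q2)
  ))
  terms <- ff_terms(lj = tibble::tibble(index = 0:1, eps = 0, sigma = 1))
  list(system = sys, terms = terms)
}

# miniature AMBER prmtop writer for reader tests
make_mini_prmtop <- function(path, charges_raw, bond_triplets_h,
                             bond_triplets_noh, atom_names, res_ptr,
                             drop_flag = NULL) {
  fmt_num <- function(x) {
    lines <- character(0)
    for (s in seq(1, length(x), by = 5)) {
      lines <- c(lines, paste(sprintf("%16.8E", x[s:min(s + 4, length(x))]),
                              collapse = ""))
    }
    lines
  }
  fmt_int <- function(x) {
    if (length(x) == 0) return(character(0))
    lines <- character(0)
    for (s in seq(1, length(x), by = 10)) {
      lines <- c(lines, paste(sprintf("%8d", x[s:min(s + 9, length(x))]),
                              collapse = ""))
    }
    lines
  }
  secs <- list(
    CHARGE = c("%FORMAT(5E16.8)", fmt_num(charges_raw)),
    ATOM_NAME = c("%FORMAT(20a4)",
                  paste(sprintf("%-4s", atom_names), collapse = "")),
    BONDS_INC_HYDROGEN = c("%FORMAT(10I8)", fmt_int(bond_triplets_h)),
    BONDS_WITHOUT_HYDROGEN = c("%FORMAT(10I8)", fmt_int(bond_triplets_noh)),
    RESIDUE_POINTER = c("%FORMAT(10I8)", fmt_int(res_ptr))
  )
  out <- c("%VERSION  VERSION_STAMP = V0001.000")
  for (nm in setdiff(names(secs), drop_flag)) {
    out <- c(out, paste0("%FLAG ", nm), secs[[nm]])
  }
  writeLines(out, path)
  path
}
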