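# Independent brute-force oracles used to check the vectorized engine.
# Everything here is written as plain double loops over the raw tables,
# deliberately sharing no code path with the package internals.

# graph distance by BFS over the raw bond table (capped)
oracle_graph_dist <- function(bonds, a, b, cap = 3L) {
  if (a == b) return(0L)
  adj <- list()
  add <- function(adj, x, y) {
    k <- as.character(x)
    adj[[k]] <- c(adj[[k]], y)
    adj
  }
  for (r in seq_len(nrow(bonds))) {
    adj <- add(adj, bonds$i[r], bonds$j[r])
    adj <- add(adj, bonds$j[r], bonds$i[r])
  }
  frontier <- a
  seen <- a
  for (d in seq_len(cap)) {
    nxt <- integer(0)
    for (f in frontier) nxt <- c(nxt, adj[[as.character(f)]])
    nxt <- setdiff(unique(nxt), seen)
    if (b %in% nxt) return(d)
    if (length(nxt) == 0) return(Inf)
    frontier <- nxt
    seen <- c(seen, nxt)
  }
  Inf
}

# full MM energy of a subset by naive double loops
oracle_mm <- function(system, terms, subset = NULL) {
  at <- system$atoms
  if (is.null(subset)) subset <- at$index
  p <- function(idx) unlist(at[match(idx, at$index), c("x", "y", "z")])
  q <- function(idx) at$charge[match(idx, at$index)]
  e <- 0
  for (r in seq_len(nrow(terms$bonds))) {
    tb <- terms$bonds[r, ]
    if (tb$i %in% subset && tb$j %in% subset) {
      d <- sqrt(sum((p(tb$i) - p(tb$j))^2))
      e <- e + tb$k * (d - tb$r0)^2
    }
  }
  for (r in seq_len(nrow(terms$angles))) {
    ta <- terms$angles[r, ]
    if (all(c(ta$i, ta$j, ta$k) %in% subset)) {
      v1 <- p(ta$i) - p(ta$j)
      v2 <- p(ta$k) - p(ta$j)
      th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      e <- e + ta$kt * (th - ta$theta0)^2
    }
  }
  for (r in seq_len(nrow(terms$torsions))) {
    tt <- terms$torsions[r, ]
    if (all(c(tt$i, tt$j, tt$k, tt$l) %in% subset)) {
      b1 <- p(tt$j) - p(tt$i)
      b2 <- p(tt$k) - p(tt$j)
      b3 <- p(tt$l) - p(tt$k)
      cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
      n1 <- cr(b1, b2)
      n2 <- cr(b2, b3)
      cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
      sgn <- sign(sum(cr(n1, n2) * b2))
      if (sgn == 0) sgn <- 1
      phi <- sgn * acos(pmin(1, pmax(-1, cosphi)))
      e <- e + tt$v * (1 + cos(tt$n * phi - tt$gamma))
    }
  }
  subset <- sort(subset)
  for (ai in seq_along(subset)) {
    for (bi in seq_along(subset)) {
      if (bi <= ai) next
      a <- subset[ai]; b <- subset[bi]
      gd <- oracle_graph_dist(system$bonds, a, b, cap = 3L)
      if (is.finite(gd) && gd <= 2) next
      s_el <- if (is.finite(gd) && gd == 3) terms$scale14$elec else 1
      s_lj <- if (is.finite(gd) && gd == 3) terms$scale14$lj else 1
      d <- sqrt(sum((p(a) - p(b))^2))
      e <- e + s_el * 1389.35458 * q(a) * q(b) / d
      ra <- match(a, terms$lj$index); rb <- match(b, terms$lj$index)
      epsab <- sqrt(terms$lj$eps[ra] * terms$lj$eps[rb])
      sigab <- (terms$lj$sigma[ra] + terms$lj$sigma[rb]) / 2
      e <- e + s_lj * 4 * epsab * ((sigab / d)^12 - (sigab / d)^6)
    }
  }
  e
}

# random small system: tree-connected atoms with minimum spacing, random
# charges and term parameters
random_small_system <- function(seed, n_max = 25L) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1)
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- runif(3, -1, 1)
    for (k in 2:n) {
      repeat {
        cand <- runif(3, -6, 6)
        d <- sqrt(rowSums(sweep(xyz[seq_len(k - 1), , drop = FALSE], 2,
                                cand)^2))
        if (min(d) > 2.0) break
      }
      xyz[k, ] <- cand
    }
    parent <- c(NA, vapply(2:n, function(k) sample(seq_len(k - 1), 1), 0L))
    bonds <- tibble::tibble(i = (2:n) - 1L, j = parent[-1] - 1L)
    atoms <- tibble::tibble(
      index = 0:(n - 1), name = paste0("X", 1:n),
      element = sample(c("C", "N", "O", "H"), n, replace = TRUE),
      residue_id = 1L, residue_name = "UNK",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = round(runif(n, -0.5, 0.5), 3)
    )
    system <- build_system(atoms, bonds)
    bt <- system$bonds
    p_of <- function(idx) as.matrix(atoms[match(idx, atoms$index),
                                          c("x", "y", "z")])
    r <- sqrt(rowSums((p_of(bt$i) - p_of(bt$j))^2))
    bond_terms <- tibble::tibble(i = bt$i, j = bt$j,
                                 k = runif(nrow(bt), 500, 1500),
                                 r0 = r + runif(nrow(bt), -0.1, 0.1))
    ang <- list()
    for (a in atoms$index) {
      nb <- neighbors(system, a)
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        ang[[length(ang) + 1]] <- tibble::tibble(i = cmb[1, ], j = a,
                                                 k = cmb[2, ])
      }
    }
    angles <- NULL
    if (length(ang)) {
      angles <- dplyr::bind_rows(ang)
      angles$kt <- runif(nrow(angles), 100, 400)
      angles$theta0 <- runif(nrow(angles), 1.5, 2.2)
    }
    tor <- list()
    for (r2 in seq_len(nrow(bt))) {
      for (iat in setdiff(neighbors(system, bt$i[r2]), bt$j[r2])) {
        for (lat in setdiff(neighbors(system, bt$j[r2]),
                            c(bt$i[r2], iat))) {
          tor[[length(tor) + 1]] <- tibble::tibble(i = iat, j = bt$i[r2],
                                                   k = bt$j[r2], l = lat)
        }
      }
    }
    torsions <- NULL
    if (length(tor)) {
      torsions <- dplyr::bind_rows(tor)
      torsions$v <- runif(nrow(torsions), 0, 5)
      torsions$n <- sample(1:3, nrow(torsions), replace = TRUE)
      torsions$gamma <- sample(c(0, pi), nrow(torsions), replace = TRUE)
    }
    lj <- tibble::tibble(index = atoms$index,
                         eps = runif(n, 0.05, 0.8),
                         sigma = runif(n, 2.6, 3.2))
    list(system = system,
         terms = ff_terms(bonds = bond_terms, angles = angles,
                          torsions = torsions, lj = lj))
  })
}

# direct Coulomb interaction of a charge set with a site set
oracle_cross_coulomb <- function(charges_df, sites_df) {
  e <- 0
  for (a in seq_len(nrow(charges_df))) {
    for (s in seq_len(nrow(sites_df))) {
      d <- sqrt((charges_df$x[a] - sites_df$x[s])^2 +
                  (charges_df$y[a] - sites_df$y[s])^2 +
                  (charges_df$z[a] - sites_df$z[s])^2)
      e <- e + 1389.35458 * charges_df$charge[a] * sites_df$charge[s] / d
    }
  }
  e
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

rotate_system <- function(system, R, shift = c(0, 0, 0)) {
  at <- system$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  build_system(at, system$bonds, system$residues)
}
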