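# Fixtures are built in code; no binary data anywhere.

# Random pair table over n_atoms labels; density < 1 leaves pairs absent so
# sparse-table semantics get exercised.
random_pair_table <- function(n_atoms = 8L, density = 1,
                              elements = c("C", "H", "N", "O", "Li")) {
  el <- sample(elements, n_atoms, replace = TRUE)
  lab <- paste0(el, seq_len(n_atoms))
  idx <- utils::combn(n_atoms, 2L)
  keep <- stats::runif(ncol(idx)) <= density
  idx <- idx[, keep, drop = FALSE]
  list(labels = lab,
       pairs = new_pair_table(lab[idx[1L, ]], lab[idx[2L, ]],
                              Vcl = stats::rnorm(ncol(idx), 0, 40),
                              VXC = -abs(stats::rnorm(ncol(idx), 20, 10))))
}

# Split a label universe into k disjoint random blocks (a partition).
random_partition <- function(labels, k = 3L) {
  block <- sample(rep_len(seq_len(k), length(labels)))
  lapply(seq_len(k), function(i) labels[block == i])
}

# Independent oracle: exhaustive double loop over member pairs.
brute_interfragment <- function(pairs, mem_a, mem_b, term = "total") {
  tot <- 0; n <- 0L
  for (x in mem_a) for (y in mem_b) {
    rec <- pair_lookup(pairs, x, y)
    if (!is.null(rec)) {
      tot <- tot + switch(term, total = rec$Vcl + rec$VXC,
                          cl = rec$Vcl, xc = rec$VXC)
      n <- n + 1L
    }
  }
  list(value = tot, n = n)
}

brute_intrafragment <- function(pairs, mem, term = "total") {
  tot <- 0
  if (length(mem) >= 2L) {
    cmb <- utils::combn(mem, 2L)
    for (j in seq_len(ncol(cmb))) {
      rec <- pair_lookup(pairs, cmb[1L, j], cmb[2L, j])
      if (!is.null(rec)) {
        tot <- tot + switch(term, total = rec$Vcl + rec$VXC,
                            cl = rec$Vcl, xc = rec$VXC)
      }
    }
  }
  tot
}

random_structure <- function(n = 6L, elements = c("C", "N", "O", "H")) {
  new_structure(sample(elements, n, replace = TRUE),
                stats::rnorm(n, 0, 3), stats::rnorm(n, 0, 3),
                stats::rnorm(n, 0, 3), label = "random")
}

# Apply a random rigid motion (proper rotation + translation).
rigid_motion <- function(struct) {
  m <- matrix(stats::rnorm(9L), 3L)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  shift <- stats::rnorm(3L, 0, 10)
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")]) %*% rot
  new_structure(struct$atoms$element,
                xyz[, 1L] + shift[1L], xyz[, 2L] + shift[2L],
                xyz[, 3L] + shift[3L],
                label = struct$label, serial = struct$atoms$serial)
}

# Random planted multi-step pathway on a 2^-10 fixed-point grid (so the
# generator's bit-exact recovery property is checkable).
random_planted_pathway <- function(pathway = "RP-X", n_mid = 1L,
                                   grid = 1024) {
  roles <- c("reactant_set", "adduct",
             rep(c("ts", "intermediate"), n_mid), "product")
  n <- length(roles)
  vals_e <- round(stats::runif(n, -40, 40) * grid) / grid
  vals_g <- round(stats::runif(n, -40, 40) * grid) / grid
  vals_e[1L] <- 0
  vals_g[1L] <- 0
  data.frame(label = paste0(pathway, "-s", seq_len(n)), role = roles,
             pathway = pathway, composition = "1+2",
             E = vals_e, G = vals_g, stringsAsFactors = FALSE)
}
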