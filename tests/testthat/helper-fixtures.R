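# fixtures built in code; nothing here touches the network

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "fodm")
  if (!nzchar(p)) stop("missing fixture: ", name)
  p
}

# hand-built unit from bare coordinates + residue letters
make_unit <- function(xyz, aa, level = "chain", chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  fodm:::new_structural_unit(
    data.frame(chain_id = chain, seq_id = seq_len(nrow(xyz)), ins = "",
               aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    level = level)
}

# deterministic spherical-shell fixture: every residue at the same radius
# (near-uniform T), one maximally hydrophobic outlier at position 1
shell_outlier_unit <- function(n = 60, radius = 10, base_aa = "G",
                               outlier_aa = "F") {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * (i - 0.5)
  xyz <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  aa <- rep(base_aa, n)
  aa[1] <- outlier_aa
  make_unit(xyz, aa)
}

# random compact unit for oracle-equivalence checks
rand_unit <- function(n = 30, seed = 1) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = 6), ncol = 3)
  aa <- sample(names(fodm:::AA_THREE_TO_ONE), n, replace = TRUE)
  make_unit(xyz, unname(fodm:::AA_THREE_TO_ONE[aa]))
}

# apply a seeded random rigid motion (proper rotation + translation)
rigid_motion <- function(unit, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, sd = 30)
  xyz <- unit_coords(unit) %*% R
  xyz <- sweep(xyz, 2, shift, "+")
  unit$residues$x <- xyz[, 1]
  unit$residues$y <- xyz[, 2]
  unit$residues$z <- xyz[, 3]
  unit
}

rand_simplex <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rexp(n)
  x / sum(x)
}

# two-model PDB written in code: model 2 is model 1 shifted +10 A in x
write_multimodel_pdb <- function(path) {
  res <- c("GLY", "ALA", "SER", "VAL")
  block <- function(shift) {
    unlist(lapply(seq_along(res), function(i) {
      sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
              i * 2 - 1:0, c("N", "CA"), res[i], i,
              c(3.8 * i + shift, 3.8 * i + 1.5 + shift), c(0, 1), c(0, 0),
              c("N", "C"))
    }))
  }
  writeLines(c("MODEL     1", block(0), "ENDMDL",
               "MODEL     2", block(10), "ENDMDL", "END"), path)
  path
}

default_scale <- hydro_scale("black_mould")
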