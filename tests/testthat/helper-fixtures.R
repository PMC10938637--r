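# Fixtures are built in code at test time; nothing binary ships with the
# package.

# random bead structure inside a box (nm); one bead per residue
random_structure <- function(n, seed, box = 2) {
  set.seed(seed)
  bead_structure(data.frame(
    index = seq_len(n), name = "BB", residue_index = seq_len(n),
    residue_name = "ALA",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
  ))
}

# independent brute-force O(N^2) recount of elastic-network pairs
oracle_network_pairs <- function(s, cutoff, min_seq_sep) {
  b <- s$beads
  out <- list()
  for (p in seq_len(nrow(b) - 1)) {
    for (q in (p + 1):nrow(b)) {
      d <- sqrt((b$x[p] - b$x[q])^2 + (b$y[p] - b$y[q])^2 +
                  (b$z[p] - b$z[q])^2)
      if (d <= cutoff &&
          abs(b$residue_index[p] - b$residue_index[q]) >= min_seq_sep) {
        out[[length(out) + 1]] <- c(b$index[p], b$index[q])
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# literal transcription of the perturbed-harmonic energy formula,
# independent of the package implementation
oracle_restraint_energy <- function(terms, pos, lam) {
  total <- 0
  for (r in seq_len(nrow(terms))) {
    k <- (1 - lam) * terms$k_A[r] + lam * terms$k_B[r]
    b0 <- (1 - lam) * terms$b0_A[r] + lam * terms$b0_B[r]
    d <- sqrt(sum((pos[terms$i[r], ] - pos[terms$j[r], ])^2))
    total <- total + 0.5 * k * (d - b0)^2
  }
  total
}

# minimal hand-authored topology file with known section counts
write_fixture_itp <- function(path, rubber = TRUE, b_state = FALSE,
                              funct10_angle = TRUE) {
  lines <- c(
    "[ moleculetype ]",
    "fixture 1",
    "",
    "[ atoms ]",
    " 1 P2 1 ALA BB 1 0.0000",
    " 2 SC1 1 ALA SC1 2 0.0000",
    " 3 P2 2 LEU BB 3 0.0000",
    "",
    "[ bonds ]",
    sprintf(" 1 2 1 0.33000 1250.0%s", if (b_state) " 0.35000 1250.0" else ""),
    " 2 3 1 0.35000 1250.0",
    if (rubber) c("; Rubber band", " 1 3 6 0.55000 500.0"),
    "",
    "[ angles ]",
    sprintf(" 1 2 3 %d 120.00000 25.0", if (funct10_angle) 10L else 2L),
    "",
    "[ dihedrals ]",
    " 1 2 3 1 1 0.0 10.0 1"
  )
  writeLines(lines, path)
  path
}

# a topology pair with a known shared/changed/one-sided partition:
# 4 identical, 3 shared-with-changed-parameters, 2 A-only, 1 B-only
mix_fixture_pair <- function() {
  atoms <- data.frame(
    index = 1:8, type = "P2", residue_index = 1:8, residue_name = "ALA",
    bead_name = "BB", charge_group = 1:8, charge = 0, mass = NA_real_,
    stringsAsFactors = FALSE
  )
  mk <- function(pairs, b0, k, tag = "rubber_band") {
    data.frame(ai = pairs[, 1], aj = pairs[, 2],
               ak = rep(NA_integer_, nrow(pairs)), funct = 6L,
               c0 = b0, c1 = k, c2 = rep(NA_real_, nrow(pairs)),
               c3 = rep(NA_real_, nrow(pairs)), section_tag = tag,
               stringsAsFactors = FALSE)
  }
  shared_same <- cbind(c(1, 2, 3, 4), c(3, 4, 5, 6))
  shared_changed <- cbind(c(1, 2, 5), c(4, 5, 7))
  a_only <- cbind(c(1, 3), c(6, 9) - c(0, 1))   # (1,6), (3,8)
  b_only <- cbind(6, 8)
  tA <- topology("fix", atoms, rbind(
    mk(shared_same, 0.50, 500), mk(shared_changed, 0.60, 500),
    mk(a_only, 0.62, 500)
  ))
  tB <- topology("fix", atoms, rbind(
    mk(shared_same, 0.50, 500), mk(shared_changed, 0.70, 600),
    mk(b_only, 0.45, 500)
  ))
  list(A = tA, B = tB,
       n_identical = 4L, n_changed = 3L, n_a_only = 2L, n_b_only = 1L)
}

# random perturbed topology (pair terms only) plus random positions
random_perturbed_system <- function(seed, n_beads = 6, n_terms = 8) {
  set.seed(seed)
  pairs <- t(replicate(n_terms * 3, sort(sample(n_beads, 2))))
  pairs <- unique(pairs)[seq_len(n_terms), , drop = FALSE]
  pert <- data.frame(
    i = pairs[, 1], j = pairs[, 2], funct = 6L,
    b0_A = runif(n_terms, 0.3, 0.9), k_A = runif(n_terms, 0, 800),
    b0_B = runif(n_terms, 0.3, 0.9), k_B = runif(n_terms, 0, 800),
    section_tag = "rubber_band", stringsAsFactors = FALSE
  )
  # ensure the invariant: at least one endpoint k positive
  zero_both <- pert$k_A == 0 & pert$k_B == 0
  pert$k_A[zero_both] <- 100
  atoms <- data.frame(index = seq_len(n_beads), type = "P2",
                      residue_index = seq_len(n_beads), residue_name = "ALA",
                      bead_name = "BB", charge_group = seq_len(n_beads),
                      charge = 0, mass = NA_real_, stringsAsFactors = FALSE)
  pt <- structure(
    list(static = topology("rand", atoms), perturbed = pert,
         provenance = c(A = "rand", B = "rand")),
    class = "perturbed_topology"
  )
  pos <- matrix(runif(n_beads * 3, 0, 1.5), ncol = 3)
  list(pt = pt, pos = pos)
}

swap_roles <- function(pt) {
  p <- pt$perturbed
  pt$perturbed <- transform(p, b0_A = p$b0_B, k_A = p$k_B,
                            b0_B = p$b0_A, k_B = p$k_A)
  pt
}
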