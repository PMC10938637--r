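# Dual-topology construction and lambda-dependent restraint energies.
#
# Two state-specific topologies are merged into one perturbed topology in
# which every harmonic distance term carries both endpoint parameter sets
# (b0_A, k_A, b0_B, k_B). A term present in only one state gets a zero
# force constant at the other endpoint, so it fades in or out along the
# path. All non-harmonic content must be identical between the states and
# is carried over unperturbed.

#' Mix two state topologies into a lambda-perturbed dual topology
#'
#' Harmonic two-body terms (bond function types 1 and 6, whether in the
#' plain `[bonds]` section or the rubber-band block) are matched between
#' states by atom index pair, regardless of which section each sat in:
#'
#' * identical parameters in both states: kept as static content;
#' * both present with differing `b0` and/or `k`: a perturbed term with
#'   both endpoint parameter sets;
#' * present in A only: `k_B = 0`, `b0_B = b0_A` (the dummy endpoint keeps
#'   a physically plausible minimum; with zero force constant it is inert);
#' * present in B only: symmetric, `k_A = 0`.
#'
#' Atom sections must agree (charges included, unless
#' `allow_charge_diff = TRUE` for protonation-state studies, where charge
#' changes belong to the condition change, not the conformational path).
#' Angles and constraints must be identical between the states.
#'
#' @param tA,tB [topology()] objects for states A and B.
#' @param allow_charge_diff permit differing atomic charges.
#' @param k_scale scalar multiplier applied to all elastic-network
#'   (rubber-band) force constants of both states, for restraint-stiffness
#'   sensitivity checks (e.g. 0.5 or 2).
#' @return Object of class `perturbed_topology`: `static` (a [topology()]),
#'   `perturbed` (data frame `i`, `j`, `funct`, `b0_A`, `k_A`, `b0_B`,
#'   `k_B`, `section_tag`) and `provenance`.
#' @export
mix_topologies <- function(tA, tB, allow_charge_diff = FALSE, k_scale = 1) {
  stopifnot(inherits(tA, "topology"), inherits(tB, "topology"))
  if (!is.numeric(k_scale) || k_scale <= 0) {
    abort_enmix("k_scale must be positive", "enmix_parameter_error")
  }
  aA <- tA$atoms; aB <- tB$atoms
  if (nrow(aA) != nrow(aB)) {
    abort_enmix(sprintf("atom sections differ in length (%d vs %d)",
                        nrow(aA), nrow(aB)), "enmix_incompatible_atoms")
  }
  cols <- c("type", "residue_index", "residue_name", "bead_name")
  for (col in cols) {
    div <- which(aA[[col]] != aB[[col]])
    if (length(div)) {
      abort_enmix(sprintf("atom sections diverge at atom %d (%s: %s vs %s)",
                          div[1], col, aA[[col]][div[1]], aB[[col]][div[1]]),
                  "enmix_incompatible_atoms")
    }
  }
  dq <- which(abs(aA$charge - aB$charge) > 1e-9)
  if (length(dq) && !allow_charge_diff) {
    abort_enmix(sprintf(
      "atomic charges differ at atom %d (%.4f vs %.4f); pass allow_charge_diff = TRUE only if the charge change is part of the condition change",
      dq[1], aA$charge[dq[1]], aB$charge[dq[1]]), "enmix_incompatible_atoms")
  }

  is_harm <- function(b) b$section_tag %in% c("bonds", "rubber_band") &
    b$funct %in% c(1L, 6L)
  scale_rubber <- function(b) {
    sel <- b$section_tag == "rubber_band"
    b$c1[sel] <- b$c1[sel] * k_scale
    b
  }
  bA <- scale_rubber(tA$bonded); bB <- scale_rubber(tB$bonded)
  hA <- bA[is_harm(bA), , drop = FALSE]
  hB <- bB[is_harm(bB), , drop = FALSE]
  oA <- bA[!is_harm(bA), , drop = FALSE]
  oB <- bB[!is_harm(bB), , drop = FALSE]

  canon <- function(h) {
    ii <- pmin(h$ai, h$aj); jj <- pmax(h$ai, h$aj)
    data.frame(i = ii, j = jj, funct = h$funct, b0 = h$c0, k = h$c1,
               section_tag = h$section_tag, key = paste(ii, jj),
               stringsAsFactors = FALSE)
  }
  cA <- canon(hA); cB <- canon(hB)
  if (anyDuplicated(cA$key) || anyDuplicated(cB$key)) {
    abort_enmix("duplicate harmonic term for the same atom pair within one state",
                "enmix_validation_error")
  }

  norm_other <- function(o) {
    o <- o[order(o$section_tag, o$ai, o$aj, ifelse(is.na(o$ak), 0L, o$ak),
                 o$funct), , drop = FALSE]
    rownames(o) <- NULL
    o
  }
  oA <- norm_other(oA); oB <- norm_other(oB)
  same_other <- nrow(oA) == nrow(oB) &&
    (nrow(oA) == 0 || isTRUE(all.equal(oA, oB, tolerance = 1e-9,
                                       check.attributes = FALSE)))
  if (!same_other) {
    abort_enmix(
      "non-harmonic bonded terms (angles/constraints) differ between states A and B; only harmonic restraints can be perturbed",
      "enmix_unmixable_term"
    )
  }

  keys <- union(cA$key, cB$key)
  mA <- match(keys, cA$key); mB <- match(keys, cB$key)
  in_A <- !is.na(mA); in_B <- !is.na(mB)
  b0_A <- ifelse(in_A, cA$b0[mA], cB$b0[mB])
  k_A  <- ifelse(in_A, cA$k[mA], 0)
  b0_B <- ifelse(in_B, cB$b0[mB], cA$b0[mA])
  k_B  <- ifelse(in_B, cB$k[mB], 0)
  funct <- ifelse(in_A, cA$funct[mA], cB$funct[mB])
  tag <- ifelse(in_A, cA$section_tag[mA], cB$section_tag[mB])
  i <- ifelse(in_A, cA$i[mA], cB$i[mB])
  j <- ifelse(in_A, cA$j[mA], cB$j[mB])

  same <- in_A & in_B & abs(b0_A - b0_B) <= 1e-9 & abs(k_A - k_B) <= 1e-9
  pert <- data.frame(i = i[!same], j = j[!same], funct = funct[!same],
                     b0_A = b0_A[!same], k_A = k_A[!same],
                     b0_B = b0_B[!same], k_B = k_B[!same],
                     section_tag = tag[!same], stringsAsFactors = FALSE)
  pert <- pert[order(pert$i, pert$j), , drop = FALSE]
  rownames(pert) <- NULL

  ns <- sum(same)
  static_harm <- data.frame(ai = i[same], aj = j[same],
                            ak = rep(NA_integer_, ns),
                            funct = funct[same], c0 = b0_A[same],
                            c1 = k_A[same], c2 = rep(NA_real_, ns),
                            c3 = rep(NA_real_, ns),
                            section_tag = tag[same], stringsAsFactors = FALSE)
  static_bonded <- rbind(static_harm, oA)
  static_bonded <- static_bonded[order(static_bonded$section_tag,
                                       static_bonded$ai, static_bonded$aj), ,
                                 drop = FALSE]
  rownames(static_bonded) <- NULL
  static <- topology(tA$molecule_name, aA, static_bonded, tA$passthrough,
                     tA$nrexcl)

  structure(
    list(static = static, perturbed = pert,
         provenance = c(A = tA$molecule_name, B = tB$molecule_name)),
    class = "perturbed_topology"
  )
}

#' @export
print.perturbed_topology <- function(x, ...) {
  cat(sprintf("<perturbed_topology> %d perturbed terms, %d static bonded terms, %d atoms\n",
              nrow(x$perturbed), nrow(x$static$bonded), nrow(x$static$atoms)))
  invisible(x)
}

interp_params <- function(pt, lam) {
  p <- pt$perturbed
  list(k = (1 - lam) * p$k_A + lam * p$k_B,
       b0 = (1 - lam) * p$b0_A + lam * p$b0_B)
}

pair_distances <- function(p, positions) {
  di <- positions[p$i, , drop = FALSE] - positions[p$j, , drop = FALSE]
  sqrt(rowSums(di^2))
}

#' Restraint energy of a perturbed topology at a given lambda
#'
#' Evaluates the harmonic restraint energy
#' `sum 1/2 k(lambda) (d_ij - b0(lambda))^2` over the perturbed terms with
#' the engine's perturbed-harmonic convention — linear interpolation of
#' the force constant and the minimum, `k(lambda) = (1-lambda) k_A +
#' lambda k_B`, `b0(lambda) = (1-lambda) b0_A + lambda b0_B` — plus the
#' lambda-independent energy of static harmonic bond terms. At the
#' endpoints this reproduces the pure state-A and state-B restraint
#' energies exactly. `mode = "energy"` instead mixes the endpoint
#' energies linearly, `V = (1-lambda) V_A + lambda V_B`, for sensitivity
#' checks.
#'
#' @param pt a [mix_topologies()] result.
#' @param positions coordinate matrix (rows = atoms, nm) or
#'   `bead_structure`.
#' @param lam coupling parameter in \[0, 1\].
#' @param mode `"parameter"` (default) or `"energy"`.
#' @return Energy in kJ/mol.
#' @export
restraint_energy <- function(pt, positions, lam,
                             mode = c("parameter", "energy")) {
  stopifnot(inherits(pt, "perturbed_topology"))
  mode <- match.arg(mode)
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1) {
    abort_enmix("lambda must be a scalar in [0, 1]", "enmix_parameter_error")
  }
  positions <- coords(positions)
  p <- pt$perturbed
  e_pert <- 0
  if (nrow(p) > 0) {
    if (max(p$i, p$j) > nrow(positions)) {
      abort_enmix("positions do not cover all referenced beads",
                  "enmix_index_error")
    }
    d <- pair_distances(p, positions)
    if (mode == "parameter") {
      ip <- interp_params(pt, lam)
      e_pert <- sum(0.5 * ip$k * (d - ip$b0)^2)
    } else {
      eA <- sum(0.5 * p$k_A * (d - p$b0_A)^2)
      eB <- sum(0.5 * p$k_B * (d - p$b0_B)^2)
      e_pert <- (1 - lam) * eA + lam * eB
    }
  }
  b <- pt$static$bonded
  h <- b[b$section_tag %in% c("bonds", "rubber_band") & b$funct %in% c(1L, 6L), ,
         drop = FALSE]
  e_static <- 0
  if (nrow(h) > 0) {
    d <- pair_distances(data.frame(i = h$ai, j = h$aj), positions)
    e_static <- sum(0.5 * h$c1 * (d - h$c0)^2)
  }
  e_pert + e_static
}

#' Derivative of the restraint energy with respect to lambda
#'
#' The thermodynamic-integration integrand `dH/dlambda` for the perturbed
#' terms under the same interpolation convention as [restraint_energy()].
#' Static terms contribute zero.
#'
#' @inheritParams restraint_energy
#' @return dH/dlambda in kJ/mol.
#' @export
restraint_dhdl <- function(pt, positions, lam,
                           mode = c("parameter", "energy")) {
  stopifnot(inherits(pt, "perturbed_topology"))
  mode <- match.arg(mode)
  positions <- coords(positions)
  p <- pt$perturbed
  if (nrow(p) == 0) return(0)
  d <- pair_distances(p, positions)
  if (mode == "parameter") {
    ip <- interp_params(pt, lam)
    dk <- p$k_B - p$k_A
    db0 <- p$b0_B - p$b0_A
    sum(0.5 * dk * (d - ip$b0)^2 - ip$k * (d - ip$b0) * db0)
  } else {
    eA <- 0.5 * p$k_A * (d - p$b0_A)^2
    eB <- 0.5 * p$k_B * (d - p$b0_B)^2
    sum(eB - eA)
  }
}

#' Write a perturbed topology file
#'
#' Perturbed terms are written inside `[bonds]` with both endpoint
#' parameter sets (`i j funct b0_A k_A b0_B k_B`, the standard dual-state
#' column layout); static content is written as in [write_topology()].
#'
#' @param pt a `perturbed_topology`.
#' @param path output path.
#' @param rubber_marker marker comment for the elastic-network block.
#' @export
write_perturbed_topology <- function(pt, path, rubber_marker = "Rubber band") {
  stopifnot(inherits(pt, "perturbed_topology"))
  t <- pt$static
  p <- pt$perturbed
  if (nrow(p) > 0) {
    pb <- data.frame(ai = p$i, aj = p$j, ak = NA_integer_, funct = p$funct,
                     c0 = p$b0_A, c1 = p$k_A, c2 = p$b0_B, c3 = p$k_B,
                     section_tag = ifelse(p$section_tag == "rubber_band",
                                          "rubber_band", "bonds"),
                     stringsAsFactors = FALSE)
    t$bonded <- rbind(t$bonded, pb)
  }
  write_topology(t, path, rubber_marker = rubber_marker)
  invisible(path)
}

#' Read a perturbed topology file
#'
#' Re-parses a file written by [write_perturbed_topology()]: harmonic bond
#' lines carrying four parameters become perturbed terms; two-parameter
#' lines and everything else become static content.
#'
#' @param path file path.
#' @param rubber_marker marker comment for the elastic-network block.
#' @return A `perturbed_topology`.
#' @export
read_perturbed_topology <- function(path, rubber_marker = "Rubber band") {
  t <- parse_topology(path, rubber_marker = rubber_marker)
  b <- t$bonded
  is_pert <- b$section_tag %in% c("bonds", "rubber_band") &
    b$funct %in% c(1L, 6L) & !is.na(b$c2) & !is.na(b$c3)
  p <- b[is_pert, , drop = FALSE]
  pert <- data.frame(i = pmin(p$ai, p$aj), j = pmax(p$ai, p$aj),
                     funct = p$funct, b0_A = p$c0, k_A = p$c1,
                     b0_B = p$c2, k_B = p$c3, section_tag = p$section_tag,
                     stringsAsFactors = FALSE)
  pert <- pert[order(pert$i, pert$j), , drop = FALSE]
  rownames(pert) <- NULL
  t$bonded <- b[!is_pert, , drop = FALSE]
  rownames(t$bonded) <- NULL
  structure(
    list(static = t, perturbed = pert,
         provenance = c(A = t$molecule_name, B = t$molecule_name)),
    class = "perturbed_topology"
  )
}
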